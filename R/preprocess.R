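#' Drop features with too much missingness
#'
#' Removes columns whose missing fraction is strictly greater than `max_frac`
#' (a column missing exactly `max_frac` of its entries survives). Column order
#' of the survivors is preserved.
#'
#' @param table A [feature_table()].
#' @param max_frac Maximum tolerated missing fraction, default 0.20.
#' @return Filtered `feature_table`; dropped column names in attribute
#'   `"dropped"`.
#' @export
filter_missingness <- function(table, max_frac = 0.20) {
  stopifnot(max_frac >= 0, max_frac <= 1)
  frac <- vapply(table$data, function(col) mean(is.na(col)), 0)
  keep <- frac <= max_frac
  out <- feature_table(table$data[, keep, drop = FALSE], table$patient_ids,
                       table$modality)
  attr(out, "dropped") <- names(frac)[!keep]
  out
}

#' Median-impute missing values
#'
#' Numeric columns: missing entries replaced by the median of the observed
#' values. Categorical columns: replaced by the most frequent observed level.
#' When `values` is `NULL` the imputation values are fitted from `table`
#' itself and returned in attribute `"values"`; pass a previously fitted list
#' to replay train-time imputation on new data.
#'
#' @param table A [feature_table()].
#' @param values Optional named list of fitted imputation values.
#' @return Imputed `feature_table` with attribute `"values"`.
#' @export
impute_median <- function(table, values = NULL) {
  dat <- table$data
  fitted <- !is.null(values)
  if (!fitted) values <- list()
  for (nm in names(dat)) {
    col <- dat[[nm]]
    if (!fitted) {
      obs <- col[!is.na(col)]
      if (!length(obs)) {
        stop(sprintf("column '%s' is entirely missing at fit time", nm))
      }
      values[[nm]] <- if (is.numeric(col)) {
        stats::median(obs)
      } else {
        names(sort(table(obs), decreasing = TRUE))[1]
      }
    }
    if (anyNA(col) && !is.null(values[[nm]])) {
      col[is.na(col)] <- values[[nm]]
      dat[[nm]] <- col
    }
  }
  out <- feature_table(dat, table$patient_ids, table$modality)
  attr(out, "values") <- values
  out
}

#' One-hot encode categorical columns
#'
#' Each categorical column with k observed levels becomes k-1 indicator
#' columns named `<col>=<level>`; the reference level is the most frequent
#' level at fit time (ties broken alphabetically), so the dummies are not
#' collinear in downstream Cox fits. A test-time level unseen at fit time
#' yields all-zero indicators.
#'
#' @param table A [feature_table()].
#' @param categorical Character vector of columns to encode (fit mode).
#'   Ignored when `levels_map` is supplied.
#' @param levels_map Optional fitted map: named list, per column, of the level
#'   vector with the reference level first.
#' @return Encoded `feature_table` with attribute `"levels_map"`.
#' @export
one_hot_encode <- function(table, categorical = NULL, levels_map = NULL) {
  dat <- table$data
  if (is.null(levels_map)) {
    if (is.null(categorical)) {
      categorical <- names(dat)[!vapply(dat, is.numeric, logical(1))]
    }
    levels_map <- list()
    for (nm in categorical) {
      tab <- sort(table(as.character(dat[[nm]])), decreasing = TRUE)
      lv <- names(tab)
      # reference = modal level; among equally frequent levels pick the
      # alphabetically first for determinism
      top <- lv[tab == tab[1]]
      ref <- sort(top)[1]
      levels_map[[nm]] <- c(ref, sort(setdiff(lv, ref)))
    }
  }
  out_cols <- list()
  for (nm in names(dat)) {
    if (!nm %in% names(levels_map)) {
      out_cols[[nm]] <- dat[[nm]]
      next
    }
    lv <- levels_map[[nm]]
    x <- as.character(dat[[nm]])
    for (l in lv[-1]) {
      out_cols[[paste0(nm, "=", l)]] <- as.numeric(!is.na(x) & x == l)
    }
  }
  out <- feature_table(data.frame(out_cols, check.names = FALSE,
                                  stringsAsFactors = FALSE),
                       table$patient_ids, table$modality)
  attr(out, "levels_map") <- levels_map
  out
}

#' Z-score normalize numeric columns
#'
#' Standardizes each numeric column with train-time mean and standard
#' deviation. Columns whose fitted sd is zero carry no information and are
#' dropped (recorded in attribute `"dropped_constant"`). The sd convention
#' defaults to the sample sd (denominator n-1); set `sd_type = "population"`
#' for the n denominator.
#'
#' @param table A [feature_table()] with numeric columns only.
#' @param center,scale Optional fitted named numeric vectors; both `NULL`
#'   means fit from `table`.
#' @param sd_type `"sample"` (default) or `"population"`.
#' @return Normalized `feature_table` with attributes `"center"`, `"scale"`,
#'   `"dropped_constant"`.
#' @export
zscore <- function(table, center = NULL, scale = NULL,
                   sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  m <- feature_matrix(table)
  if (is.null(center)) {
    center <- colMeans(m)
    scale <- apply(m, 2, stats::sd)
    if (sd_type == "population") {
      n <- nrow(m)
      scale <- scale * sqrt((n - 1) / n)
    }
  }
  keep <- names(center)[scale > 0]
  dropped <- setdiff(colnames(m), keep)
  z <- sweep(m[, keep, drop = FALSE], 2, center[keep], "-")
  z <- sweep(z, 2, scale[keep], "/")
  out <- feature_table(as.data.frame(z), table$patient_ids, table$modality)
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  attr(out, "dropped_constant") <- dropped
  out
}

#' Greedy Spearman-correlation deduplication
#'
#' Scans columns in their current order; a column is dropped iff its absolute
#' Spearman rank correlation with any previously kept column exceeds
#' `rho_max`. With `signed = TRUE` only positive correlations above the
#' threshold cause a drop.
#'
#' @param table A [feature_table()] with numeric, complete columns.
#' @param rho_max Correlation threshold, default 0.8 (strictly greater
#'   triggers the drop).
#' @param signed Use signed rather than absolute correlation.
#' @param keep Optional fitted character vector of columns to keep (replay
#'   mode; no correlations computed).
#' @return Deduplicated `feature_table`; attribute `"dropped_log"` is a
#'   data.frame (dropped, correlated_with, rho).
#' @export
spearman_dedup <- function(table, rho_max = 0.8, signed = FALSE, keep = NULL) {
  m <- feature_matrix(table)
  if (anyNA(m)) stop("spearman_dedup requires a complete matrix")
  log <- data.frame(dropped = character(), correlated_with = character(),
                    rho = numeric(), stringsAsFactors = FALSE)
  if (is.null(keep)) {
    ranks <- apply(m, 2, rank)  # Spearman = Pearson on (midrank-tied) ranks
    kept_idx <- integer()
    for (j in seq_len(ncol(m))) {
      drop_against <- NA_integer_
      rho_hit <- NA_real_
      for (k in kept_idx) {
        rho <- suppressWarnings(stats::cor(ranks[, j], ranks[, k]))
        if (is.na(rho)) rho <- 0
        val <- if (signed) rho else abs(rho)
        if (val > rho_max) {
          drop_against <- k
          rho_hit <- rho
          break
        }
      }
      if (is.na(drop_against)) {
        kept_idx <- c(kept_idx, j)
      } else {
        log <- rbind(log, data.frame(dropped = colnames(m)[j],
                                     correlated_with = colnames(m)[drop_against],
                                     rho = rho_hit, stringsAsFactors = FALSE))
      }
    }
    keep <- colnames(m)[kept_idx]
  }
  out <- feature_table(table$data[, keep, drop = FALSE], table$patient_ids,
                       table$modality)
  attr(out, "dropped_log") <- log
  out
}

#' Fit the full tabular preprocessing pipeline
#'
#' Missingness filter (> `max_missing` dropped), median imputation, one-hot
#' coding of categorical columns, z-score normalization of numeric columns,
#' then greedy Spearman deduplication on the all-numeric encoded matrix. All
#' statistics are fitted on `table` (the training cohort) and recorded in the
#' returned spec so that [preprocess_apply()] replays them verbatim on unseen
#' data.
#'
#' @param table Training-cohort [feature_table()].
#' @param categorical Columns to one-hot encode (default: all non-numeric).
#' @param max_missing Missingness threshold (default 0.20).
#' @param rho_max Spearman threshold (default 0.8).
#' @param sd_type Passed to [zscore()].
#' @param dedup Apply Spearman deduplication (default TRUE).
#' @return List with `spec` (class `preprocess_spec`) and `table`, the
#'   transformed training table.
#' @export
preprocess_fit <- function(table, categorical = NULL, max_missing = 0.20,
                           rho_max = 0.8, sd_type = "sample", dedup = TRUE) {
  t1 <- filter_missingness(table, max_missing)
  t2 <- impute_median(t1)
  t3 <- one_hot_encode(t2, categorical = categorical)
  # indicators stay on the 0/1 scale; only original numeric columns are
  # standardized (mirrors "categorical -> one-hot, numeric -> z-score")
  lm <- attr(t3, "levels_map")
  onehot_cols <- unlist(lapply(names(lm), function(nm)
    paste0(nm, "=", lm[[nm]][-1])), use.names = FALSE)
  numeric_cols <- setdiff(names(t3$data), onehot_cols)
  tz <- zscore(feature_table(t3$data[, numeric_cols, drop = FALSE],
                             t3$patient_ids, t3$modality),
               sd_type = sd_type)
  final_cols <- setdiff(names(t3$data), attr(tz, "dropped_constant"))
  dat <- t3$data[, final_cols, drop = FALSE]
  dat[names(tz$data)] <- tz$data
  t4 <- feature_table(dat, t3$patient_ids, t3$modality)
  if (dedup) {
    t5 <- spearman_dedup(t4, rho_max = rho_max)
  } else {
    t5 <- t4
    attr(t5, "dropped_log") <- NULL
  }
  spec <- structure(list(
    modality = table$modality,
    kept_after_missingness = names(t1$data),
    impute_values = attr(t2, "values"),
    levels_map = attr(t3, "levels_map"),
    center = attr(tz, "center"),
    scale = attr(tz, "scale"),
    dropped_constant = attr(tz, "dropped_constant"),
    kept_features = names(t5$data),
    dedup_dropped = attr(t5, "dropped_log"),
    sd_type = sd_type, max_missing = max_missing, rho_max = rho_max
  ), class = "preprocess_spec")
  list(spec = spec, table = t5)
}

#' Replay a fitted preprocessing spec on new data
#'
#' @param spec A `preprocess_spec` from [preprocess_fit()].
#' @param table New-cohort [feature_table()] with the original raw columns.
#' @return Transformed `feature_table` whose columns equal
#'   `spec$kept_features`.
#' @export
preprocess_apply <- function(spec, table) {
  miss <- setdiff(spec$kept_after_missingness, names(table$data))
  if (length(miss)) {
    stop("table lacks fitted columns: ", paste(miss, collapse = ", "))
  }
  t1 <- feature_table(table$data[, spec$kept_after_missingness, drop = FALSE],
                      table$patient_ids, table$modality)
  t2 <- impute_median(t1, values = spec$impute_values)
  t3 <- one_hot_encode(t2, levels_map = spec$levels_map)
  numeric_cols <- names(spec$center)[spec$scale[names(spec$center)] > 0]
  tz <- zscore(feature_table(t3$data[, numeric_cols, drop = FALSE],
                             t3$patient_ids, t3$modality),
               center = spec$center, scale = spec$scale)
  dat <- t3$data
  dat[names(tz$data)] <- tz$data
  feature_table(dat[, spec$kept_features, drop = FALSE], t3$patient_ids,
                t3$modality)
}

#' Serialize a preprocessing spec to JSON
#'
#' @param spec A `preprocess_spec`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to file).
#' @export
preprocess_spec_json <- function(spec, path = NULL) {
  payload <- unclass(spec)
  payload$center <- as.list(payload$center)
  payload$scale <- as.list(payload$scale)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Read a preprocessing spec back from JSON
#'
#' @param path File written by [preprocess_spec_json()].
#' @return A `preprocess_spec`.
#' @export
preprocess_spec_from_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$center <- unlist(p$center)
  p$scale <- unlist(p$scale)
  p$impute_values <- as.list(p$impute_values)
  p$levels_map <- lapply(p$levels_map, as.character)
  structure(p, class = "preprocess_spec")
}
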