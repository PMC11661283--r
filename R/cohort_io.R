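#' Survival outcome for one endpoint
#'
#' Container for right-censored follow-up of a set of patients for a single
#' endpoint (overall survival or disease-free survival). Times are follow-up
#' durations in months; `event = 1` marks death (OS) or recurrence/progression
#' (DFS), `event = 0` marks censoring at the recorded time.
#'
#' @param time Non-negative numeric vector, follow-up in months.
#' @param event Vector coercible to 0/1; 1 = event observed, 0 = censored.
#' @param patient_ids Optional character vector of unique patient identifiers,
#'   aligned with `time`.
#' @param endpoint Endpoint label, e.g. `"OS"` or `"DFS"`.
#' @return An object of class `survival_outcome` with fields `time`, `event`,
#'   `patient_ids`, `endpoint`.
#' @export
survival_outcome <- function(time, event, patient_ids = NULL, endpoint = "OS") {
  time <- as.numeric(time)
  event <- as.integer(event)
  if (length(time) != length(event)) {
    stop("`time` and `event` must have equal length")
  }
  if (anyNA(time) || any(time < 0)) {
    stop("follow-up times must be non-negative and non-missing")
  }
  if (anyNA(event) || !all(event %in% c(0L, 1L))) {
    stop("`event` must be binary (0 = censored, 1 = event)")
  }
  if (is.null(patient_ids)) {
    patient_ids <- as.character(seq_along(time))
  }
  patient_ids <- as.character(patient_ids)
  if (length(patient_ids) != length(time) || anyDuplicated(patient_ids)) {
    stop("`patient_ids` must be unique and aligned with `time`")
  }
  structure(
    list(time = time, event = event, patient_ids = patient_ids,
         endpoint = endpoint),
    class = "survival_outcome"
  )
}

#' @export
print.survival_outcome <- function(x, ...) {
  cat(sprintf("<survival_outcome> endpoint=%s  n=%d  events=%d (%.1f%%)\n",
              x$endpoint, length(x$time), sum(x$event),
              100 * mean(x$event)))
  invisible(x)
}

#' Subset a survival outcome by patient id
#'
#' @param outcome A [survival_outcome()].
#' @param ids Character vector of patient ids to keep, in the requested order.
#' @return A `survival_outcome` restricted (and reordered) to `ids`.
#' @export
outcome_subset <- function(outcome, ids) {
  idx <- match(as.character(ids), outcome$patient_ids)
  if (anyNA(idx)) {
    stop("unknown patient ids: ", paste(ids[is.na(idx)], collapse = ", "))
  }
  survival_outcome(outcome$time[idx], outcome$event[idx],
                   outcome$patient_ids[idx], outcome$endpoint)
}

#' Feature table for one tabular modality
#'
#' Patients x features table for a single modality (clinical, mRNA, miRNA,
#' methylation, ...). Columns may be numeric or categorical (character);
#' missing values are allowed before preprocessing.
#'
#' @param data A data.frame of features (no id column).
#' @param patient_ids Unique patient ids, one per row.
#' @param modality Modality label.
#' @return Object of class `feature_table` with fields `data`, `patient_ids`,
#'   `modality`.
#' @export
feature_table <- function(data, patient_ids, modality = "tabular") {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  patient_ids <- as.character(patient_ids)
  if (nrow(data) != length(patient_ids)) {
    stop("row count must equal number of patient ids")
  }
  if (anyDuplicated(patient_ids)) {
    stop("duplicate patient ids in feature table")
  }
  rownames(data) <- NULL
  structure(list(data = data, patient_ids = patient_ids, modality = modality),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> modality=%s  %d patients x %d features\n",
              x$modality, nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$data)

#' Numeric matrix view of a feature table
#'
#' @param table A [feature_table()] whose columns are all numeric.
#' @return Numeric matrix with patient ids as row names.
#' @export
feature_matrix <- function(table) {
  ok <- vapply(table$data, is.numeric, logical(1))
  if (!all(ok)) {
    stop("non-numeric columns present: ",
         paste(names(table$data)[!ok], collapse = ", "))
  }
  m <- as.matrix(table$data)
  rownames(m) <- table$patient_ids
  m
}

#' Read a delimited feature table
#'
#' Reads a CSV/TSV file with a header row and an id column into a
#' [feature_table()]. Empty cells become missing values. Columns not listed in
#' `categorical` are required to be numeric; a non-numeric cell in a numeric
#' column is an error naming the offending row and column.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file (UTF-8, "." decimal).
#' @param modality Modality label to attach.
#' @param id_col Name of the patient id column (default `"patient_id"`).
#' @param categorical Character vector of column names to keep as categorical.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, modality = "tabular",
                               id_col = "patient_id", categorical = character()) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("", "NA"), stringsAsFactors = FALSE,
                           comment.char = "")
  if (!id_col %in% names(raw)) {
    stop(sprintf("id column '%s' not found in %s", id_col, path))
  }
  ids <- raw[[id_col]]
  if (anyNA(ids) || anyDuplicated(ids)) {
    stop(sprintf("patient ids in '%s' must be present and unique", path))
  }
  feats <- raw[, setdiff(names(raw), id_col), drop = FALSE]
  for (nm in names(feats)) {
    if (nm %in% categorical) next
    col <- feats[[nm]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' in numeric column '%s', row %d (patient %s)",
                   col[bad[1]], nm, bad[1], ids[bad[1]]))
    }
    feats[[nm]] <- num
  }
  feature_table(feats, ids, modality)
}

#' Write a feature table to a delimited file
#'
#' Values are written with 17 significant digits so that write -> read is an
#' exact round trip for doubles.
#'
#' @param table A [feature_table()].
#' @param path Output path; `.csv` gives comma-separated, otherwise tab.
#' @param id_col Name for the id column.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, id_col = "patient_id") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- table$data
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) {
      v <- sprintf("%.17g", out[[nm]])
      v[is.na(out[[nm]])] <- NA
      out[[nm]] <- v
    }
  }
  out <- cbind(stats::setNames(data.frame(table$patient_ids,
                                          stringsAsFactors = FALSE), id_col),
               out)
  utils::write.table(out, path, sep = sep, quote = FALSE, na = "",
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Embedding bag for one patient's slide
#'
#' Variable-length set of patch feature vectors produced by encoding the
#' tissue patches of one whole-slide image.
#'
#' @param patient_id Patient identifier.
#' @param vectors `n_patches x d` numeric matrix of patch embeddings.
#' @param coords Optional `n_patches x 2` integer matrix of patch origins
#'   (level-0 pixels, 0-based).
#' @return Object of class `embedding_bag`.
#' @export
embedding_bag <- function(patient_id, vectors, coords = NULL) {
  vectors <- as.matrix(vectors)
  storage.mode(vectors) <- "double"
  if (nrow(vectors) < 1L) {
    stop(sprintf("embedding bag for patient '%s' is empty", patient_id))
  }
  if (anyNA(vectors) || any(!is.finite(vectors))) {
    stop("embedding vectors must be finite")
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    storage.mode(coords) <- "integer"
    if (nrow(coords) != nrow(vectors) || ncol(coords) != 2L) {
      stop("coords must be n_patches x 2")
    }
  }
  structure(list(patient_id = as.character(patient_id), vectors = vectors,
                 coords = coords),
            class = "embedding_bag")
}

#' @export
print.embedding_bag <- function(x, ...) {
  cat(sprintf("<embedding_bag> patient=%s  %d patches x d=%d\n",
              x$patient_id, nrow(x$vectors), ncol(x$vectors)))
  invisible(x)
}

#' Write embedding bags to a plain-text bag store
#'
#' The bag store is a directory with a `manifest.json` (patient ids, embedding
#' dimension, presence of coordinates) and, per patient, an
#' `<id>.embeddings.tsv` numeric matrix plus an optional `<id>.coords.tsv`.
#' Numbers are written with 17 significant digits, so the store round-trips
#' doubles exactly.
#'
#' @param bags Named list of [embedding_bag()] (names = patient ids) or an
#'   unnamed list; ids are taken from the bags themselves.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_embedding_bags <- function(bags, path) {
  if (!length(bags)) stop("no bags to write")
  bags <- stats::setNames(bags, vapply(bags, function(b) b$patient_id, ""))
  d <- unique(vapply(bags, function(b) ncol(b$vectors), 0L))
  if (length(d) != 1L) {
    stop("all bags must share one embedding dimension; found: ",
         paste(d, collapse = ", "))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (b in bags) {
    ef <- file.path(path, paste0(b$patient_id, ".embeddings.tsv"))
    m <- matrix(sprintf("%.17g", b$vectors), nrow(b$vectors))
    utils::write.table(m, ef, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    if (!is.null(b$coords)) {
      cf <- file.path(path, paste0(b$patient_id, ".coords.tsv"))
      utils::write.table(b$coords, cf, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
  }
  manifest <- list(format = "mmsurv-bag-store", version = 1L,
                   dim = as.integer(d),
                   patients = as.list(names(bags)))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read embedding bags from a bag store directory
#'
#' @param path Directory written by [write_embedding_bags()].
#' @return Named list of [embedding_bag()], one per patient; the shared
#'   embedding dimension is attached as attribute `"embedding_dim"`.
#' @export
read_embedding_bags <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("not a bag store (missing manifest.json): ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  patients <- as.character(manifest$patients)
  bags <- vector("list", length(patients))
  names(bags) <- patients
  d <- NA_integer_
  for (id in patients) {
    ef <- file.path(path, paste0(id, ".embeddings.tsv"))
    if (!file.exists(ef)) stop("missing embeddings for patient ", id)
    m <- as.matrix(utils::read.table(ef, sep = "\t", header = FALSE,
                                     colClasses = "numeric"))
    dimnames(m) <- NULL
    if (nrow(m) < 1L) stop("empty bag for patient ", id)
    if (is.na(d)) d <- ncol(m)
    if (ncol(m) != d) {
      stop(sprintf("embedding dimension mismatch for patient %s: %d != %d",
                   id, ncol(m), d))
    }
    cf <- file.path(path, paste0(id, ".coords.tsv"))
    coords <- NULL
    if (file.exists(cf)) {
      coords <- as.matrix(utils::read.table(cf, sep = "\t", header = FALSE,
                                            colClasses = "integer"))
      dimnames(coords) <- NULL
    }
    bags[[id]] <- embedding_bag(id, m, coords)
  }
  attr(bags, "embedding_dim") <- d
  bags
}

#' Per-patient risk scores from one model
#'
#' @param patient_ids Patient ids.
#' @param scores Finite numeric risk scores (log-partial-hazard scale).
#' @param modality Modality label of the producing model.
#' @param endpoint Endpoint label.
#' @return Object of class `risk_vector`.
#' @export
risk_vector <- function(patient_ids, scores, modality = "model",
                        endpoint = "OS") {
  patient_ids <- as.character(patient_ids)
  scores <- as.numeric(scores)
  if (length(scores) != length(patient_ids)) {
    stop("scores and patient ids must align")
  }
  if (anyNA(scores) || any(!is.finite(scores))) {
    stop("risk scores must be finite")
  }
  if (anyDuplicated(patient_ids)) stop("duplicate patient ids in risk vector")
  structure(list(patient_ids = patient_ids, scores = scores,
                 modality = modality, endpoint = endpoint),
            class = "risk_vector")
}

#' Write risk vectors to CSV
#'
#' Long format with columns `patient_id`, `endpoint`, `modality`, `risk`.
#'
#' @param risks A [risk_vector()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_risk_csv <- function(risks, path) {
  if (inherits(risks, "risk_vector")) risks <- list(risks)
  rows <- lapply(risks, function(r) {
    data.frame(patient_id = r$patient_ids, endpoint = r$endpoint,
               modality = r$modality,
               risk = sprintf("%.17g", r$scores),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Align a multimodal cohort to its complete-case intersection
#'
#' Restricts the cohort to patients that are present in every tabular
#' modality, have a bag if bags are supplied, and have complete follow-up for
#' every endpoint — mirroring the usual multimodal-study exclusion rule
#' ("exclude patients who miss any modality or have incomplete follow-up").
#' Counts of patients dropped per reason are reported via `message()` and kept
#' in the result.
#'
#' @param tables Named list of [feature_table()] (one per modality).
#' @param outcomes Named list of [survival_outcome()] (one per endpoint).
#' @param bags Optional named list of [embedding_bag()] keyed by patient id.
#' @return Object of class `multimodal_bundle` with fields `patients`,
#'   `outcomes`, `tables`, `bags`, `dropped` (named counts per reason).
#' @export
align_cohort <- function(tables, outcomes, bags = NULL) {
  if (!length(tables) && is.null(bags)) stop("at least one modality required")
  universe <- unique(unlist(c(
    lapply(tables, function(t) t$patient_ids),
    lapply(outcomes, function(o) o$patient_ids),
    if (!is.null(bags)) list(names(bags))
  )))
  keep <- universe
  dropped <- c()
  for (m in names(tables)) {
    before <- keep
    keep <- intersect(keep, tables[[m]]$patient_ids)
    dropped[paste0("missing_", m)] <- length(before) - length(keep)
  }
  if (!is.null(bags)) {
    before <- keep
    keep <- intersect(keep, names(bags))
    dropped["missing_bags"] <- length(before) - length(keep)
  }
  for (ep in names(outcomes)) {
    o <- outcomes[[ep]]
    complete <- o$patient_ids[is.finite(o$time) & !is.na(o$event)]
    before <- keep
    keep <- intersect(keep, complete)
    dropped[paste0("incomplete_", ep)] <- length(before) - length(keep)
  }
  if (!length(keep)) stop("no patient is complete in all modalities/endpoints")
  keep <- sort(keep)  # canonical order: invariant to input ordering
  for (nm in names(dropped)) {
    if (dropped[[nm]] > 0) {
      message(sprintf("align_cohort: dropped %d patient(s): %s",
                      dropped[[nm]], nm))
    }
  }
  tables_out <- lapply(tables, function(t) {
    idx <- match(keep, t$patient_ids)
    feature_table(t$data[idx, , drop = FALSE], keep, t$modality)
  })
  outcomes_out <- lapply(outcomes, outcome_subset, ids = keep)
  bags_out <- if (is.null(bags)) NULL else bags[keep]
  structure(list(patients = keep, outcomes = outcomes_out,
                 tables = tables_out, bags = bags_out, dropped = dropped),
            class = "multimodal_bundle")
}

#' @export
print.multimodal_bundle <- function(x, ...) {
  cat(sprintf("<multimodal_bundle> %d patients | tables: %s | bags: %s | endpoints: %s\n",
              length(x$patients),
              paste(names(x$tables), collapse = ", "),
              if (is.null(x$bags)) "none" else length(x$bags),
              paste(names(x$outcomes), collapse = ", ")))
  invisible(x)
}
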