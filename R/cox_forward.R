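#' Random sub-partitions of a training cohort
#'
#' Draws `n` independent random splits of the training cohort into
#' sub-training and sub-validation sets. These repeated splits drive the
#' univariate screen and the forward-selection validation performance.
#'
#' @param ids Character vector of training-cohort patient ids.
#' @param n Number of partitions, default 10.
#' @param val_fraction Fraction held out as sub-validation, default 0.2
#'   (an 80/20 split).
#' @param seed Integer seed.
#' @return Object of class `subpartition_set`: list of `n` elements, each
#'   with `sub_train` and `sub_val` id vectors; plus the parameters.
#' @export
make_subpartitions <- function(ids, n = 10, val_fraction = 0.2, seed = 1) {
  ids <- as.character(ids)
  if (length(ids) < 5L) stop("cohort too small to sub-partition (< 5)")
  stopifnot(n >= 1, val_fraction > 0, val_fraction < 1)
  n_val <- max(1L, min(length(ids) - 1L, round(val_fraction * length(ids))))
  set.seed(seed)
  parts <- lapply(seq_len(n), function(i) {
    val <- sample(ids, n_val)
    list(sub_train = setdiff(ids, val), sub_val = val)
  })
  structure(list(partitions = parts, n = n, val_fraction = val_fraction,
                 seed = seed),
            class = "subpartition_set")
}

# Fit a Cox model on a covariate matrix; returns named coefficient vector or
# NULL on failure (non-convergence, non-finite coefficients, degenerate data).
# A mild ridge penalty (default 1e-6) stabilises near-collinear omics columns.
fit_cox <- function(x, time, event, penalty = 1e-6) {
  x <- as.matrix(x)
  df <- as.data.frame(x)
  vnames <- paste0("x", seq_len(ncol(x)))
  names(df) <- vnames
  df$.time <- time
  df$.event <- event
  rhs <- if (penalty > 0) {
    sprintf("ridge(%s, theta = %.17g, scale = FALSE)",
            paste(vnames, collapse = ", "), penalty)
  } else {
    paste(vnames, collapse = " + ")
  }
  f <- stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs))
  # ridge() must resolve even though survival is only imported, not attached
  environment(f) <- asNamespace("survival")
  fit <- tryCatch(
    suppressWarnings(survival::coxph(f, data = df, ties = "efron")),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  beta <- stats::coef(fit)
  if (length(beta) != ncol(x) || anyNA(beta) || any(!is.finite(beta))) {
    return(NULL)
  }
  stats::setNames(as.numeric(beta), colnames(x))
}

# Mean validation C-index of a feature set over the sub-partitions.
# Failed fits contribute 0.5 (uninformative) for that partition.
mean_val_cindex <- function(m, outcome, features, parts, penalty) {
  ids <- rownames(m)
  vals <- vapply(parts$partitions, function(p) {
    tr <- match(p$sub_train, ids)
    va <- match(p$sub_val, ids)
    otr <- outcome_subset(outcome, p$sub_train)
    beta <- fit_cox(m[tr, features, drop = FALSE], otr$time, otr$event,
                    penalty)
    if (is.null(beta)) return(0.5)
    ova <- outcome_subset(outcome, p$sub_val)
    risk <- as.numeric(m[va, features, drop = FALSE] %*% beta)
    tryCatch(harrell_cindex(risk, ova)$point, error = function(e) 0.5)
  }, 0)
  mean(vals)
}

#' Univariate Cox screen over repeated sub-partitions
#'
#' For every feature, fits a single-covariate Cox model on each sub-training
#' set and scores Harrell's C-index on the matching sub-validation set; the
#' feature passes the screen iff its mean validation C-index over the
#' partitions exceeds 0.5. Passed features are ranked by mean C-index,
#' descending. Non-convergent or degenerate fits score 0.5 for that
#' partition, so a feature that never fits is excluded.
#'
#' @param table Preprocessed [feature_table()] (numeric, complete).
#' @param outcome [survival_outcome()] for the training cohort.
#' @param parts A [make_subpartitions()] result.
#' @param penalty Ridge stabiliser for the Cox fits, default 1e-6.
#' @return Object of class `univariate_screen`: data.frame with columns
#'   `feature`, `mean_cindex`, `pass`, `rank` (NA for failing features),
#'   ordered as the input columns.
#' @export
univariate_screen <- function(table, outcome, parts, penalty = 1e-6) {
  m <- feature_matrix(table)
  idx <- match(outcome$patient_ids, rownames(m))
  if (anyNA(idx)) stop("outcome patients missing from table")
  m <- m[idx, , drop = FALSE]
  scores <- vapply(colnames(m), function(f)
    mean_val_cindex(m, outcome, f, parts, penalty), 0)
  res <- data.frame(feature = colnames(m), mean_cindex = unname(scores),
                    pass = unname(scores) > 0.5, stringsAsFactors = FALSE)
  res$rank <- NA_integer_
  passed <- which(res$pass)
  res$rank[passed[order(-res$mean_cindex[passed])]] <-
    seq_along(passed)
  class(res) <- c("univariate_screen", "data.frame")
  res
}

#' Iterative forward feature selection while fitting a Cox model
#'
#' Starts from the top-ranked screened feature; each iteration tries every
#' remaining screened candidate alongside the current optimal set, scores the
#' candidate set by its mean sub-validation C-index over the partitions, and
#' accepts the best candidate only if it strictly improves on the current
#' best. Stops at no improvement or at `max_features`. The final model is
#' refit on the full training cohort with the optimal set; the best mean
#' validation C-index achieved becomes the modality's validation performance
#' `p_val` used later as its fusion weight numerator.
#'
#' @inheritParams univariate_screen
#' @param screen A [univariate_screen()] result.
#' @param max_features Cap on the selected set size, default 20.
#' @return List with `model` (class `fitted_cox_model`: `features`, `beta`,
#'   `p_val`, `ties`, `penalty`, `converged`) and `trace` (data.frame per
#'   iteration: `iteration`, `candidate`, `mean_cindex`, `accepted`).
#' @export
forward_select <- function(table, outcome, screen, parts, max_features = 20,
                           penalty = 1e-6) {
  m <- feature_matrix(table)
  idx <- match(outcome$patient_ids, rownames(m))
  m <- m[idx, , drop = FALSE]
  pool <- screen$feature[screen$pass]
  if (!length(pool)) stop("no feature passed the univariate screen")
  pool <- pool[order(screen$rank[match(pool, screen$feature)])]
  current <- pool[1]
  best <- mean_val_cindex(m, outcome, current, parts, penalty)
  trace <- data.frame(iteration = 1L, candidate = current,
                      mean_cindex = best, accepted = TRUE,
                      stringsAsFactors = FALSE)
  remaining <- setdiff(pool, current)
  it <- 1L
  while (length(remaining) && length(current) < max_features) {
    it <- it + 1L
    cand_scores <- vapply(remaining, function(f)
      mean_val_cindex(m, outcome, c(current, f), parts, penalty), 0)
    # candidates are ordered by screening rank, so which.max prefers the
    # higher-ranked feature on exact ties
    j <- which.max(cand_scores)
    accepted <- cand_scores[j] > best
    trace <- rbind(trace, data.frame(iteration = it,
                                     candidate = remaining[j],
                                     mean_cindex = unname(cand_scores[j]),
                                     accepted = accepted,
                                     stringsAsFactors = FALSE))
    if (!accepted) break
    best <- unname(cand_scores[j])
    current <- c(current, remaining[j])
    remaining <- remaining[-j]
  }
  beta <- fit_cox(m[, current, drop = FALSE], outcome$time, outcome$event,
                  penalty)
  converged <- !is.null(beta)
  if (!converged) {
    # final refit failed: fall back to the top-ranked univariate model
    current <- current[1]
    beta <- fit_cox(m[, current, drop = FALSE], outcome$time, outcome$event,
                    penalty)
    if (is.null(beta)) stop("Cox refit failed even for the top feature")
  }
  model <- structure(list(features = current, beta = beta, p_val = best,
                          ties = "efron", penalty = penalty,
                          converged = converged,
                          modality = table$modality,
                          endpoint = outcome$endpoint),
                     class = "fitted_cox_model")
  list(model = model, trace = trace)
}

#' @export
print.fitted_cox_model <- function(x, ...) {
  cat(sprintf("<fitted_cox_model> %s/%s: %d feature(s), p_val = %.4f\n",
              x$modality, x$endpoint, length(x$features), x$p_val))
  invisible(x)
}

#' Linear Cox risk scores for a cohort
#'
#' `risk_i = sum_j beta_j x_ij`, the log-partial-hazard of the fitted Cox
#' model (no centering; ranks are unaffected).
#'
#' @param model A `fitted_cox_model` from [forward_select()].
#' @param table A [feature_table()] containing all model features.
#' @return A [risk_vector()].
#' @export
predict_risk <- function(model, table) {
  m <- feature_matrix(table)
  miss <- setdiff(model$features, colnames(m))
  if (length(miss)) {
    stop("table lacks model features: ", paste(miss, collapse = ", "))
  }
  scores <- as.numeric(m[, model$features, drop = FALSE] %*%
                         model$beta[model$features])
  risk_vector(table$patient_ids, scores, modality = model$modality,
              endpoint = model$endpoint)
}

#' Serialize a fitted Cox model (with trace) to JSON
#'
#' @param model A `fitted_cox_model`.
#' @param trace Optional forward-selection trace data.frame.
#' @param path Optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
cox_model_json <- function(model, trace = NULL, path = NULL) {
  payload <- list(features = model$features,
                  beta = as.list(model$beta),
                  p_val = model$p_val, ties = model$ties,
                  penalty = model$penalty, modality = model$modality,
                  endpoint = model$endpoint)
  if (!is.null(trace)) payload$trace <- trace
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
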