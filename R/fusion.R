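#' Validation-performance fusion weights
#'
#' Converts per-modality validation performances (C-index scale) into fusion
#' weights by simple normalization: `w_m = p_m_val / sum(p_val)`. Weights are
#' non-negative and sum to one.
#'
#' @param p_val Named numeric vector (or named list) of positive validation
#'   performances, one per modality.
#' @param endpoint Endpoint label.
#' @return Object of class `modality_weights`: `p_val`, `w`, `endpoint`.
#' @export
compute_weights <- function(p_val, endpoint = "OS") {
  p <- unlist(p_val)
  if (is.null(names(p)) || any(names(p) == "")) {
    stop("p_val must be named by modality")
  }
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop("validation performances must be positive and finite")
  }
  w <- p / sum(p)
  structure(list(p_val = p, w = w, endpoint = endpoint),
            class = "modality_weights")
}

#' @export
print.modality_weights <- function(x, ...) {
  cat(sprintf("<modality_weights> %s\n", x$endpoint))
  for (m in names(x$w)) {
    cat(sprintf("  %-12s p_val = %.4f  w = %.4f\n", m, x$p_val[m], x$w[m]))
  }
  invisible(x)
}

check_aligned <- function(risks) {
  ids <- risks[[1]]$patient_ids
  for (r in risks) {
    if (!identical(sort(r$patient_ids), sort(ids))) {
      stop("risk vectors cover different patient sets")
    }
  }
  ids
}

#' Weighted late fusion of per-modality risk scores
#'
#' Per-patient fused risk `r_i = sum_m w_m * r_im`: raw risk scores from
#' independently trained per-modality models are combined linearly with the
#' validation-performance weights. Scores are fused raw by default (the
#' models share the cohort, hence a common baseline hazard); set
#' `standardize = TRUE` to z-score each modality's risks first when scales
#' are known to diverge.
#'
#' @param risks Named list of [risk_vector()], one per modality.
#' @param weights A [compute_weights()] result covering exactly these
#'   modalities.
#' @param standardize Z-score each modality's risks before fusing (default
#'   FALSE).
#' @return Object of class `fused_risk`: `fused` (a [risk_vector()]),
#'   `components`, `weights`.
#' @export
fuse <- function(risks, weights, standardize = FALSE) {
  if (!setequal(names(risks), names(weights$w))) {
    stop("weights must cover exactly the fused modalities")
  }
  ids <- check_aligned(risks)
  total <- rep(0, length(ids))
  for (m in names(risks)) {
    s <- risks[[m]]$scores[match(ids, risks[[m]]$patient_ids)]
    if (standardize) s <- as.numeric(scale(s))
    total <- total + weights$w[[m]] * s
  }
  fused <- risk_vector(ids, total, modality = "fused",
                       endpoint = weights$endpoint)
  structure(list(fused = fused, components = risks, weights = weights),
            class = "fused_risk")
}

#' Uniform-weight late fusion
#'
#' Equivalent to [fuse()] with `w_m = 1/M` for every modality.
#'
#' @inheritParams fuse
#' @param endpoint Endpoint label.
#' @return A `fused_risk` (modality label `"fused_uniform"`).
#' @export
fuse_uniform <- function(risks, endpoint = "OS", standardize = FALSE) {
  w <- compute_weights(stats::setNames(rep(1, length(risks)), names(risks)),
                       endpoint = endpoint)
  out <- fuse(risks, w, standardize = standardize)
  out$fused$modality <- "fused_uniform"
  out
}
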