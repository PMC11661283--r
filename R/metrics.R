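#' Harrell's concordance index
#'
#' Fraction of comparable patient pairs in which the patient with the earlier
#' event carries the higher risk score. A pair (i, j) is comparable iff
#' `time_i < time_j` and patient i had the event; ties in risk score count
#' 0.5. This is the standard censoring-aware rank metric for survival models:
#' 0.5 = random ordering, 1 = perfect.
#'
#' @param risks Numeric risk scores (higher = earlier expected event), or a
#'   [risk_vector()].
#' @param outcome A [survival_outcome()] aligned with `risks`.
#' @return List of class `cindex_result` with `point` and
#'   `n_comparable_pairs` (and, after [bootstrap_cindex()], `replicates` and
#'   `ci`).
#' @export
harrell_cindex <- function(risks, outcome) {
  r <- if (inherits(risks, "risk_vector")) risks$scores else as.numeric(risks)
  t <- outcome$time
  e <- outcome$event
  if (length(r) != length(t)) stop("risks and outcome must align")
  if (length(r) < 2L) stop("need at least two patients")
  n <- length(r)
  num <- 0
  den <- 0
  for (i in which(e == 1L)) {
    later <- which(t > t[i])
    if (!length(later)) next
    den <- den + length(later)
    num <- num + sum(r[i] > r[later]) + 0.5 * sum(r[i] == r[later])
  }
  if (den == 0) stop("no comparable pairs (check events and time spread)")
  structure(list(point = num / den, n_comparable_pairs = den,
                 replicates = NULL, ci = NULL),
            class = "cindex_result")
}

#' Bootstrap confidence interval for the C-index
#'
#' Resamples patients with replacement `B` times, recomputes the C-index on
#' each replicate, and reports the percentile 95% interval. Replicates with
#' no comparable pairs are redrawn (count recorded).
#'
#' @inheritParams harrell_cindex
#' @param B Number of bootstrap replicates, default 1000.
#' @param seed Integer seed for reproducibility.
#' @param conf Confidence level, default 0.95.
#' @return `cindex_result` carrying `point`, `replicates`, `ci`
#'   (length-2), `n_comparable_pairs`, `n_redrawn`.
#' @export
bootstrap_cindex <- function(risks, outcome, B = 1000, seed = 1, conf = 0.95) {
  r <- if (inherits(risks, "risk_vector")) risks$scores else as.numeric(risks)
  base <- harrell_cindex(r, outcome)
  n <- length(r)
  reps <- numeric(B)
  redrawn <- 0L
  set.seed(seed)
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      ok <- tryCatch({
        o <- survival_outcome(outcome$time[idx], outcome$event[idx],
                              endpoint = outcome$endpoint)
        reps[b] <- harrell_cindex(r[idx], o)$point
        TRUE
      }, error = function(e) FALSE)
      if (ok) break
      redrawn <- redrawn + 1L
    }
  }
  alpha <- (1 - conf) / 2
  base$replicates <- reps
  base$ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha)))
  base$n_redrawn <- redrawn
  base
}

#' @export
print.cindex_result <- function(x, ...) {
  cat(sprintf("C-index = %.4f (%d comparable pairs)", x$point,
              x$n_comparable_pairs))
  if (!is.null(x$ci)) cat(sprintf("  95%% CI (%.4f, %.4f)", x$ci[1], x$ci[2]))
  cat("\n")
  invisible(x)
}

#' Compare two bootstrapped C-index distributions
#'
#' Welch's unpaired two-sample t-test on the bootstrap replicate vectors of
#' two models. Degenerate cases are handled explicitly: identical constant
#' replicate vectors give t = 0, p = 1; fully separated constant vectors give
#' p = 0.
#'
#' @param result_a,result_b `cindex_result` objects with replicates (from
#'   [bootstrap_cindex()]).
#' @return List with `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
compare_cindex <- function(result_a, result_b) {
  xa <- result_a$replicates
  xb <- result_b$replicates
  if (is.null(xa) || is.null(xb)) {
    stop("both results must carry bootstrap replicates")
  }
  na <- length(xa); nb <- length(xb)
  va <- stats::var(xa); vb <- stats::var(xb)
  diff <- mean(xa) - mean(xb)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    t <- if (diff == 0) 0 else sign(diff) * Inf
    p <- if (diff == 0) 1 else 0
    df <- NA_real_
  } else {
    t <- diff / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(t), df)
  }
  list(t = t, df = df, p_value = p, mean_a = mean(xa), mean_b = mean(xb))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param outcome A [survival_outcome()].
#' @return Data.frame of class `km_curve` with columns `time`, `n_risk`,
#'   `n_event`, `surv` (right-continuous step function starting at 1).
#' @export
km_estimate <- function(outcome) {
  fit <- survival::survfit(survival::Surv(outcome$time, outcome$event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param curve A `km_curve` from [km_estimate()].
#' @param times Times at which to read off S(t).
#' @return Numeric vector of survival probabilities.
#' @export
km_surv_at <- function(curve, times) {
  vapply(times, function(t) {
    idx <- which(curve$time <= t)
    if (!length(idx)) 1 else curve$surv[max(idx)]
  }, 0)
}

#' Two-group log-rank test
#'
#' Standard log-rank test with hypergeometric variance; the statistic is
#' chi-squared with 1 degree of freedom.
#'
#' @param outcome_a,outcome_b [survival_outcome()] objects for the two groups.
#' @return List with `chisq`, `p_value`, `n` per group, observed and expected
#'   event counts.
#' @export
logrank_test <- function(outcome_a, outcome_b) {
  time <- c(outcome_a$time, outcome_b$time)
  event <- c(outcome_a$event, outcome_b$event)
  if (sum(event) == 0) stop("log-rank test requires at least one event")
  grp <- c(rep(0L, length(outcome_a$time)), rep(1L, length(outcome_b$time)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(chisq = unname(sd$chisq), p_value = p,
       n = unname(sd$n), observed = unname(sd$obs), expected = unname(sd$exp))
}

#' Median-risk stratification into high- and low-risk groups
#'
#' High-risk iff risk strictly exceeds the cohort median; ties at the median
#' fall into the low-risk group. With all risks identical every patient is
#' low-risk (degenerate split, flagged).
#'
#' @param risks Numeric risks or a [risk_vector()].
#' @return List of class `median_split` with `threshold`, `group` (character
#'   "high"/"low"), `degenerate` flag.
#' @export
median_split <- function(risks) {
  r <- if (inherits(risks, "risk_vector")) risks$scores else as.numeric(risks)
  if (length(r) < 2L) stop("need at least two patients")
  thr <- stats::median(r)
  group <- ifelse(r > thr, "high", "low")
  structure(list(threshold = thr, group = group,
                 degenerate = !any(group == "high")),
            class = "median_split")
}

#' Risk stratification with KM curves and log-rank test
#'
#' Applies [median_split()], estimates per-group Kaplan-Meier curves, and
#' tests their separation with the log-rank test.
#'
#' @param risks Numeric risks aligned with `outcome`.
#' @param outcome A [survival_outcome()].
#' @return List of class `stratification_result`: `split`, `km_high`,
#'   `km_low`, `logrank` (NULL when the split is degenerate).
#' @export
risk_stratification <- function(risks, outcome) {
  sp <- median_split(risks)
  hi <- sp$group == "high"
  res <- list(split = sp, km_high = NULL, km_low = NULL, logrank = NULL)
  if (sp$degenerate) {
    message("median_split: all risks identical; degenerate stratification")
    res$km_low <- km_estimate(outcome)
    return(structure(res, class = "stratification_result"))
  }
  oh <- survival_outcome(outcome$time[hi], outcome$event[hi],
                         endpoint = outcome$endpoint)
  ol <- survival_outcome(outcome$time[!hi], outcome$event[!hi],
                         endpoint = outcome$endpoint)
  res$km_high <- km_estimate(oh)
  res$km_low <- km_estimate(ol)
  res$logrank <- logrank_test(oh, ol)
  structure(res, class = "stratification_result")
}

#' Binary labels at a follow-up horizon
#'
#' Converts censored follow-up into time-specific binary labels: positive if
#' the event occurred at or before the horizon, negative if follow-up reaches
#' the horizon event-free, excluded if censored before the horizon (outcome
#' at the horizon unknown).
#'
#' @param outcome A [survival_outcome()].
#' @param horizon Horizon t in months (> 0).
#' @return List of class `timepoint_labels`: `horizon`, `status` (character
#'   "positive"/"negative"/"excluded" per patient), `label` (1/0/NA).
#' @export
label_at_horizon <- function(outcome, horizon) {
  stopifnot(horizon > 0)
  status <- ifelse(outcome$event == 1L & outcome$time <= horizon, "positive",
                   ifelse(outcome$event == 0L & outcome$time < horizon,
                          "excluded", "negative"))
  label <- ifelse(status == "positive", 1L,
                  ifelse(status == "negative", 0L, NA_integer_))
  structure(list(horizon = horizon, status = status, label = label),
            class = "timepoint_labels")
}

delong_components <- function(risks, label) {
  pos <- risks[label == 1L]
  neg <- risks[label == 0L]
  # placement values: V10_i = P-hat(pos_i > neg), V01_j = P-hat(pos > neg_j)
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp), auc = mean(cmp),
       n_pos = length(pos), n_neg = length(neg))
}

#' AUROC with DeLong variance and confidence interval
#'
#' AUC computed as the Mann-Whitney statistic (ties count 0.5) over the
#' non-excluded patients; its variance from DeLong's structural components
#' (sample variances of the placement values), and a normal-approximation
#' 95% CI truncated to [0, 1].
#'
#' @param risks Numeric risks or a [risk_vector()].
#' @param labels A [label_at_horizon()] result, or a 0/1 vector (NA =
#'   excluded).
#' @param conf Confidence level, default 0.95.
#' @return List of class `auroc_result`: `auc`, `var`, `ci`, `n_pos`,
#'   `n_neg`.
#' @export
auroc_delong <- function(risks, labels, conf = 0.95) {
  r <- if (inherits(risks, "risk_vector")) risks$scores else as.numeric(risks)
  lab <- if (inherits(labels, "timepoint_labels")) labels$label else
    as.integer(labels)
  keep <- !is.na(lab)
  r <- r[keep]; lab <- lab[keep]
  if (!any(lab == 1L) || !any(lab == 0L)) {
    stop("need at least one positive and one negative after exclusion")
  }
  cp <- delong_components(r, lab)
  v <- (if (cp$n_pos > 1) stats::var(cp$v10) else 0) / cp$n_pos +
       (if (cp$n_neg > 1) stats::var(cp$v01) else 0) / cp$n_neg
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- pmin(1, pmax(0, cp$auc + c(-1, 1) * z * sqrt(v)))
  structure(list(auc = cp$auc, var = v, ci = ci,
                 n_pos = cp$n_pos, n_neg = cp$n_neg),
            class = "auroc_result")
}

#' Paired DeLong test for two correlated ROC curves
#'
#' Compares the AUCs of two risk vectors evaluated on the same labels,
#' accounting for their correlation through the covariance of the DeLong
#' structural components.
#'
#' @param risks_a,risks_b Two risk vectors on the same patients.
#' @param labels Shared labels (see [auroc_delong()]).
#' @return List with `auc_a`, `auc_b`, `z`, `p_value`, `var_diff`.
#' @export
delong_test <- function(risks_a, risks_b, labels) {
  ra <- if (inherits(risks_a, "risk_vector")) risks_a$scores else
    as.numeric(risks_a)
  rb <- if (inherits(risks_b, "risk_vector")) risks_b$scores else
    as.numeric(risks_b)
  lab <- if (inherits(labels, "timepoint_labels")) labels$label else
    as.integer(labels)
  keep <- !is.na(lab)
  ra <- ra[keep]; rb <- rb[keep]; lab <- lab[keep]
  ca <- delong_components(ra, lab)
  cb <- delong_components(rb, lab)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  vd <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / ca$n_pos +
        (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / ca$n_neg
  diff <- ca$auc - cb$auc
  if (vd <= 0) {
    z <- if (diff == 0) 0 else sign(diff) * Inf
    p <- if (diff == 0) 1 else 0
  } else {
    z <- diff / sqrt(vd)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = ca$auc, auc_b = cb$auc, z = z, p_value = p, var_diff = vd)
}
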