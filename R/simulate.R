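#' Configuration for the synthetic multimodal cohort generator
#'
#' The generator emulates the structure of a multimodal survival cohort:
#' per-modality tabular features with a sparse informative subset and
#' AR(1)-correlated nuisance features, proportional-hazards event times with
#' an exponential baseline, independent right censoring calibrated to a
#' target rate, two coupled endpoints (OS and a DFS whose latent time never
#' exceeds the OS time), and per-patient embedding bags in which the fraction
#' of "signature" patches is a monotone (sigmoid) function of a designated
#' risk component.
#'
#' @param n_patients Cohort size, default 226 (a typical single-site TCGA
#'   cohort scale).
#' @param modalities Named list; each element a list with `n_features`,
#'   `n_informative`, `beta` (length `n_informative`), `rho` (AR(1)
#'   inter-feature correlation).
#' @param baseline_lambda Exponential baseline hazard per month, default 0.02
#'   (median survival of about 35 months at eta = 0).
#' @param censoring_target Target censored fraction for OS, default 0.3.
#' @param dfs_shape Beta(a, b) shape pair coupling the latent DFS time to the
#'   OS time (`dfs = os * Beta(a, b)`), default c(4, 2).
#' @param bag_config `NULL` to skip bags, else a list with `d` (embedding
#'   dim), `patches_range` (length-2 int), `signal_scale` (sigmoid scale
#'   linking risk to signature fraction), `separation` (centroid distance),
#'   `noise_sd`, and `source` (`"eta"` = full linear predictor, or a modality
#'   name whose contribution drives the bag signal), plus optional
#'   `bag_weight` adding an independent bag-specific risk component to eta.
#' @param seed Integer seed.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(
    n_patients = 226,
    modalities = list(
      clinical = list(n_features = 15, n_informative = 3,
                      beta = c(1.0, 0.8, 0.6), rho = 0.2),
      omics = list(n_features = 50, n_informative = 3,
                   beta = c(0.8, -0.6, 0.5), rho = 0.4)
    ),
    baseline_lambda = 0.02,
    censoring_target = 0.3,
    dfs_shape = c(4, 2),
    bag_config = NULL,
    seed = 1) {
  stopifnot(n_patients >= 10, censoring_target >= 0, censoring_target < 1,
            baseline_lambda > 0)
  for (m in modalities) {
    stopifnot(m$n_informative <= m$n_features,
              length(m$beta) == m$n_informative)
  }
  structure(list(n_patients = as.integer(n_patients), modalities = modalities,
                 baseline_lambda = baseline_lambda,
                 censoring_target = censoring_target, dfs_shape = dfs_shape,
                 bag_config = bag_config, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default bag configuration for the generator
#'
#' @param d Embedding dimension, default 32.
#' @param patches_range Bag size range, default c(50, 200).
#' @param signal_scale Sigmoid scale, default 2.
#' @param separation Distance between background and signature centroids,
#'   default 3.
#' @param noise_sd Isotropic patch noise, default 1.
#' @param source Risk component driving the bag signal, default "eta".
#' @param bag_weight Sd of an extra bag-specific component added to eta,
#'   default 0 (bags echo the tabular risk).
#' @return List suitable as `bag_config` in [simulation_config()].
#' @export
bag_config <- function(d = 32, patches_range = c(50L, 200L), signal_scale = 2,
                       separation = 3, noise_sd = 1, source = "eta",
                       bag_weight = 0) {
  list(d = as.integer(d), patches_range = as.integer(patches_range),
       signal_scale = signal_scale, separation = separation,
       noise_sd = noise_sd, source = source, bag_weight = bag_weight)
}

# AR(1) correlated Gaussian design
ar1_design <- function(n, p, rho) {
  z <- matrix(stats::rnorm(n * p), n, p)
  if (rho == 0 || p == 1) return(z)
  x <- z
  for (j in 2:p) x[, j] <- rho * x[, j - 1] + sqrt(1 - rho^2) * z[, j]
  x
}

# Exponential censoring rate hitting the target censored fraction:
# P(C < T | eta) = c / (c + lambda e^eta); bisection on c over the cohort.
calibrate_censoring <- function(eta, lambda, target) {
  if (target == 0) return(0)
  pcens <- function(cr) mean(cr / (cr + lambda * exp(eta)))
  lo <- 1e-10
  hi <- lambda * exp(max(eta)) * 1e6
  if (pcens(hi) < target) stop("infeasible censoring target")
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (pcens(mid) < target) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' Generate embedding bags with planted bag-level risk signal
#'
#' Each bag mixes background patches (isotropic Gaussian noise around a
#' background centroid) with signature patches (noise around a signature
#' centroid); the expected signature fraction is
#' `plogis(signal_scale * risk)`, so higher-risk patients carry more
#' signature patches. Bag sizes are uniform in `patches_range`.
#'
#' @param risks Named numeric vector of per-patient risk (finite).
#' @param cfg A [bag_config()].
#' @param seed Integer seed.
#' @return Named list of [embedding_bag()]; attributes `"signature_centroid"`
#'   and `"signature_fraction"` expose the ground truth.
#' @export
simulate_bags <- function(risks, cfg = bag_config(), seed = 1) {
  stopifnot(all(is.finite(risks)), !is.null(names(risks)))
  set.seed(seed)
  d <- cfg$d
  mu_bg <- rep(0, d)
  dir <- stats::rnorm(d)
  mu_sig <- cfg$separation * dir / sqrt(sum(dir^2))
  frac <- stats::plogis(cfg$signal_scale * risks)
  bags <- lapply(seq_along(risks), function(i) {
    n <- sample(seq(cfg$patches_range[1], cfg$patches_range[2]), 1)
    is_sig <- stats::runif(n) < frac[i]
    base <- matrix(stats::rnorm(n * d, sd = cfg$noise_sd), n, d)
    centers <- outer(as.numeric(is_sig), mu_sig) +
      outer(1 - as.numeric(is_sig), mu_bg)
    embedding_bag(names(risks)[i], base + centers)
  })
  names(bags) <- names(risks)
  attr(bags, "signature_centroid") <- mu_sig
  attr(bags, "signature_fraction") <- frac
  bags
}

#' Simulate a multimodal survival cohort with known ground truth
#'
#' Draws per-modality feature matrices, builds the true linear predictor
#' `eta` from the informative features (plus an optional bag-specific
#' component), samples OS times from the proportional-hazards model
#' `T ~ Exp(lambda * exp(eta))` by inverse sampling, couples a latent DFS
#' time `dfs = os * Beta(a, b)` (so recurrence never follows death), and
#' censors both endpoints with a shared independent exponential censoring
#' time whose rate is calibrated by bisection to the target OS censoring
#' fraction.
#'
#' @param cfg A [simulation_config()].
#' @return List with `bundle` (a `multimodal_bundle`) and `truth` (class
#'   `ground_truth`: `eta`, per-modality informative feature names and
#'   `beta`, realized censoring fraction, bag ground truth when bags are
#'   generated).
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  set.seed(cfg$seed)
  n <- cfg$n_patients
  ids <- sprintf("P%04d", seq_len(n))
  eta <- rep(0, n)
  tables <- list()
  truth_mod <- list()
  eta_parts <- list()
  for (mname in names(cfg$modalities)) {
    m <- cfg$modalities[[mname]]
    x <- ar1_design(n, m$n_features, m$rho)
    colnames(x) <- sprintf("%s_f%03d", mname, seq_len(m$n_features))
    inf_idx <- seq_len(m$n_informative)
    contrib <- as.numeric(x[, inf_idx, drop = FALSE] %*% m$beta)
    eta <- eta + contrib
    eta_parts[[mname]] <- contrib
    tables[[mname]] <- feature_table(as.data.frame(x), ids, mname)
    truth_mod[[mname]] <- list(informative = colnames(x)[inf_idx],
                               beta = m$beta)
  }
  bag_eta <- NULL
  if (!is.null(cfg$bag_config) && cfg$bag_config$bag_weight > 0) {
    bag_eta <- stats::rnorm(n, sd = cfg$bag_config$bag_weight)
    eta <- eta + bag_eta
  }
  lambda <- cfg$baseline_lambda
  t_os <- stats::rexp(n) / (lambda * exp(eta))
  b <- stats::rbeta(n, cfg$dfs_shape[1], cfg$dfs_shape[2])
  t_dfs <- t_os * b
  crate <- calibrate_censoring(eta, lambda, cfg$censoring_target)
  cens <- if (crate > 0) stats::rexp(n, crate) else rep(Inf, n)
  os_time <- pmin(t_os, cens)
  os_event <- as.integer(t_os <= cens)
  dfs_time <- pmin(t_dfs, cens)
  dfs_event <- as.integer(t_dfs <= cens)
  outcomes <- list(
    OS = survival_outcome(os_time, os_event, ids, "OS"),
    DFS = survival_outcome(dfs_time, dfs_event, ids, "DFS")
  )
  bags <- NULL
  bag_truth <- NULL
  if (!is.null(cfg$bag_config)) {
    bc <- cfg$bag_config
    src <- if (bc$source == "eta") eta else eta_parts[[bc$source]]
    if (!is.null(bag_eta)) src <- src + bag_eta
    risks <- stats::setNames(src, ids)
    bags <- simulate_bags(risks, bc, seed = cfg$seed + 7919L)
    bag_truth <- list(signature_centroid = attr(bags, "signature_centroid"),
                      signature_fraction = attr(bags, "signature_fraction"),
                      bag_risk = risks)
  }
  bundle <- suppressMessages(align_cohort(tables, outcomes, bags))
  truth <- structure(list(eta = stats::setNames(eta, ids),
                          modalities = truth_mod,
                          censoring_os = mean(os_event == 0L),
                          bag = bag_truth),
                     class = "ground_truth")
  list(bundle = bundle, truth = truth)
}

#' Write a simulated cohort to disk in the pipeline's file formats
#'
#' Emits one CSV per tabular modality, an outcomes CSV, a bag store directory
#' when bags exist, and a ground-truth JSON.
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  b <- sim$bundle
  for (m in names(b$tables)) {
    write_feature_table(b$tables[[m]], file.path(dir, paste0(m, ".csv")))
  }
  oc <- data.frame(patient_id = b$patients)
  for (ep in names(b$outcomes)) {
    o <- b$outcomes[[ep]]
    oc[[paste0(tolower(ep), "_months")]] <- sprintf("%.17g", o$time)
    oc[[paste0(tolower(ep), "_event")]] <- o$event
  }
  utils::write.table(oc, file.path(dir, "outcomes.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(b$bags)) write_embedding_bags(b$bags, file.path(dir, "bags"))
  tr <- sim$truth
  jsonlite::write_json(
    list(eta = as.list(tr$eta), modalities = tr$modalities,
         censoring_os = tr$censoring_os),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
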