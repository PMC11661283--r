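#' Random cross-validation fold assignment
#'
#' Randomly permutes the cohort and deals patients into `n_folds` near-equal
#' folds (sizes differ by at most 1). Optionally stratifies by event status
#' so each fold carries a similar event fraction.
#'
#' @param ids Patient ids.
#' @param n_folds Number of folds, default 5 (training:test 4:1).
#' @param seed Integer seed.
#' @param stratify_event Optional 0/1 event vector aligned with `ids`.
#' @return Named integer vector mapping each id to a fold in `1..n_folds`.
#' @export
assign_folds <- function(ids, n_folds = 5, seed = 1, stratify_event = NULL) {
  ids <- as.character(ids)
  if (length(ids) < n_folds) stop("fewer patients than folds")
  set.seed(seed)
  if (is.null(stratify_event)) {
    f <- stats::setNames(rep_len(seq_len(n_folds), length(ids)), sample(ids))
  } else {
    f <- stats::setNames(integer(length(ids)), ids)
    for (e in unique(stratify_event)) {
      grp <- sample(ids[stratify_event == e])
      f[grp] <- rep_len(seq_len(n_folds), length(grp))
    }
  }
  f[ids]
}

#' Experiment configuration for the cross-validated multimodal pipeline
#'
#' @param endpoints Endpoints to run, default `c("OS", "DFS")`.
#' @param n_folds Cross-validation folds, default 5.
#' @param seed Master seed; every stage derives its own seed from it.
#' @param categorical Named list: per tabular modality, the categorical
#'   column names (default none).
#' @param max_missing,rho_max Preprocessing thresholds (see
#'   [preprocess_fit()]).
#' @param n_partitions,val_fraction Sub-partition settings for screening and
#'   forward selection (see [make_subpartitions()]).
#' @param max_features,penalty Forward-selection settings (see
#'   [forward_select()]).
#' @param deep `NULL` to skip the bag modality, else a list with optional
#'   `net` (arguments to [milnet_config()] except `input_dim`) and `train`
#'   (arguments to [train_config()] except `seed`).
#' @param horizons AUROC horizons in months, default c(12, 36, 60)
#'   (1/3/5 years).
#' @param bootstrap_B Bootstrap replicates for C-index CIs, default 1000.
#' @param stratify_folds Stratify folds by event status, default FALSE.
#' @param standardize_fusion Z-score per-modality risks before fusing,
#'   default FALSE (raw late fusion).
#' @param out_dir Optional output directory for the JSON/CSV report.
#' @return List of class `run_config`.
#' @export
run_config <- function(endpoints = c("OS", "DFS"), n_folds = 5, seed = 1,
                       categorical = list(), max_missing = 0.20,
                       rho_max = 0.8, n_partitions = 10, val_fraction = 0.2,
                       max_features = 20, penalty = 1e-6, deep = NULL,
                       horizons = c(12, 36, 60), bootstrap_B = 1000,
                       stratify_folds = FALSE, standardize_fusion = FALSE,
                       out_dir = NULL) {
  stopifnot(n_folds >= 2)
  structure(list(endpoints = endpoints, n_folds = as.integer(n_folds),
                 seed = as.integer(seed), categorical = categorical,
                 max_missing = max_missing, rho_max = rho_max,
                 n_partitions = n_partitions, val_fraction = val_fraction,
                 max_features = max_features, penalty = penalty, deep = deep,
                 horizons = horizons, bootstrap_B = bootstrap_B,
                 stratify_folds = stratify_folds,
                 standardize_fusion = standardize_fusion, out_dir = out_dir),
            class = "run_config")
}

table_subset <- function(table, ids) {
  idx <- match(ids, table$patient_ids)
  feature_table(table$data[idx, , drop = FALSE], ids, table$modality)
}

evaluate_risks <- function(risks, outcome, horizons, B, seed) {
  ci <- bootstrap_cindex(risks, outcome, B = B, seed = seed)
  strat <- risk_stratification(risks$scores, outcome)
  aurocs <- list()
  for (h in horizons) {
    lab <- label_at_horizon(outcome, h)
    res <- tryCatch(auroc_delong(risks$scores, lab), error = function(e) NULL)
    if (!is.null(res)) {
      aurocs[[as.character(h)]] <- list(auc = res$auc, ci = res$ci,
                                        n_pos = res$n_pos, n_neg = res$n_neg)
    }
  }
  list(cindex = ci$point, cindex_ci = ci$ci,
       n_comparable_pairs = ci$n_comparable_pairs,
       logrank_chisq = if (is.null(strat$logrank)) NA else strat$logrank$chisq,
       logrank_p = if (is.null(strat$logrank)) NA else strat$logrank$p_value,
       auroc = aurocs)
}

#' Run the cross-validated multimodal ensemble experiment
#'
#' For every endpoint and every fold: fits each tabular modality on the
#' training fold (preprocessing, univariate screen and forward selection all
#' fitted inside the fold), optionally trains the deep bag model, predicts
#' the held-out test fold, computes validation-performance fusion weights
#' from training-side validation only, and fuses the test-fold risks both
#' weighted and uniformly. Test predictions are pooled across folds into one
#' vector per model before evaluation (C-index with bootstrap CI, median-risk
#' stratification with log-rank, time-specific AUROC with DeLong CI).
#'
#' @param bundle A `multimodal_bundle` (see [align_cohort()] /
#'   [simulate_cohort()]).
#' @param cfg A [run_config()].
#' @param keep_models Keep per-fold fitted models in the result (default
#'   TRUE; needed for audit / leakage checks).
#' @return Object of class `experiment_result`: `report` (nested metrics
#'   list), `risks` (pooled [risk_vector()]s per endpoint and model),
#'   `weights` (per endpoint and fold), `folds`, `models` (optional), `cfg`.
#'   When `cfg$out_dir` is set, writes `report.json`, `risks_<endpoint>.csv`
#'   and `weights.json` there.
#' @export
run_experiment <- function(bundle, cfg = run_config(), keep_models = TRUE) {
  patients <- bundle$patients
  has_bags <- !is.null(bundle$bags) && !is.null(cfg$deep)
  folds <- assign_folds(
    patients, cfg$n_folds, seed = cfg$seed,
    stratify_event = if (cfg$stratify_folds)
      bundle$outcomes[[1]]$event else NULL)
  modalities <- names(bundle$tables)
  report <- list(seed = cfg$seed, n_folds = cfg$n_folds,
                 n_patients = length(patients), endpoints = list())
  all_risks <- list()
  all_weights <- list()
  all_models <- list()
  for (ep in cfg$endpoints) {
    outcome <- bundle$outcomes[[ep]]
    if (is.null(outcome)) stop("bundle lacks endpoint ", ep)
    ep_i <- match(ep, cfg$endpoints)
    pooled <- list()
    ep_weights <- list()
    ep_models <- list()
    for (k in seq_len(cfg$n_folds)) {
      train_ids <- patients[folds != k]
      test_ids <- patients[folds == k]
      o_tr <- outcome_subset(outcome, train_ids)
      p_vals <- c()
      fold_risks <- list()
      fold_models <- list()
      for (m in modalities) {
        seed_m <- cfg$seed + 1009L * ep_i + 101L * k +
          7L * match(m, modalities)
        pp <- preprocess_fit(table_subset(bundle$tables[[m]], train_ids),
                             categorical = cfg$categorical[[m]],
                             max_missing = cfg$max_missing,
                             rho_max = cfg$rho_max)
        parts <- make_subpartitions(train_ids, n = cfg$n_partitions,
                                    val_fraction = cfg$val_fraction,
                                    seed = seed_m)
        screen <- univariate_screen(pp$table, o_tr, parts,
                                    penalty = cfg$penalty)
        fs <- forward_select(pp$table, o_tr, screen, parts,
                             max_features = cfg$max_features,
                             penalty = cfg$penalty)
        fs$model$endpoint <- ep
        test_tab <- preprocess_apply(pp$spec,
                                     table_subset(bundle$tables[[m]],
                                                  test_ids))
        fold_risks[[m]] <- predict_risk(fs$model, test_tab)
        p_vals[m] <- fs$model$p_val
        fold_models[[m]] <- list(spec = pp$spec, model = fs$model,
                                 trace = fs$trace)
      }
      if (has_bags) {
        d <- ncol(bundle$bags[[1]]$vectors)
        net_args <- c(list(input_dim = d), cfg$deep$net)
        net_cfg <- do.call(milnet_config, net_args)
        tr_args <- cfg$deep$train
        tr_args$seed <- cfg$seed + 5000L + 17L * k + ep_i
        tcfg <- do.call(train_config, tr_args)
        dm <- train_deep_cph(bundle$bags[train_ids], o_tr, net_cfg, tcfg)
        fold_risks[["wsi"]] <- predict_bag_risk(dm, bundle$bags[test_ids],
                                                endpoint = ep)
        # a deep model whose internal validation is degenerate gets a floor
        # weight instead of aborting the fusion
        p_vals["wsi"] <- if (is.finite(dm$val_cindex) && dm$val_cindex > 0) {
          dm$val_cindex
        } else 1e-6
        fold_models[["wsi"]] <- dm
      }
      w <- compute_weights(p_vals, endpoint = ep)
      fw <- fuse(fold_risks, w, standardize = cfg$standardize_fusion)
      fu <- fuse_uniform(fold_risks, endpoint = ep,
                         standardize = cfg$standardize_fusion)
      ep_weights[[k]] <- w
      if (keep_models) ep_models[[k]] <- fold_models
      for (m in names(fold_risks)) {
        pooled[[m]] <- rbind(pooled[[m]],
                             data.frame(id = fold_risks[[m]]$patient_ids,
                                        score = fold_risks[[m]]$scores))
      }
      pooled[["fused"]] <- rbind(pooled[["fused"]],
                                 data.frame(id = fw$fused$patient_ids,
                                            score = fw$fused$scores))
      pooled[["fused_uniform"]] <- rbind(
        pooled[["fused_uniform"]],
        data.frame(id = fu$fused$patient_ids, score = fu$fused$scores))
    }
    ep_report <- list()
    ep_risks <- list()
    for (m in names(pooled)) {
      df <- pooled[[m]]
      df <- df[match(patients, df$id), ]
      rv <- risk_vector(df$id, df$score, modality = m, endpoint = ep)
      ep_risks[[m]] <- rv
      ep_report[[m]] <- evaluate_risks(rv, outcome, cfg$horizons,
                                       cfg$bootstrap_B,
                                       seed = cfg$seed + 31L * ep_i)
    }
    ep_report$weights <- lapply(ep_weights, function(w) as.list(w$w))
    report$endpoints[[ep]] <- ep_report
    all_risks[[ep]] <- ep_risks
    all_weights[[ep]] <- ep_weights
    if (keep_models) all_models[[ep]] <- ep_models
  }
  res <- structure(list(report = report, risks = all_risks,
                        weights = all_weights, folds = folds,
                        models = if (keep_models) all_models else NULL,
                        cfg = cfg),
                   class = "experiment_result")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    for (ep in names(all_risks)) {
      write_risk_csv(unname(all_risks[[ep]]),
                     file.path(cfg$out_dir,
                               sprintf("risks_%s.csv", ep)))
    }
    jsonlite::write_json(
      lapply(all_weights, function(ws) lapply(ws, function(w) as.list(w$w))),
      file.path(cfg$out_dir, "weights.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d patients, %d folds, seed %d\n",
              x$report$n_patients, x$report$n_folds, x$report$seed))
  for (ep in names(x$report$endpoints)) {
    cat(sprintf("  %s:\n", ep))
    epr <- x$report$endpoints[[ep]]
    for (m in setdiff(names(epr), "weights")) {
      cat(sprintf("    %-14s C-index %.3f (%.3f, %.3f)\n", m,
                  epr[[m]]$cindex, epr[[m]]$cindex_ci[1],
                  epr[[m]]$cindex_ci[2]))
    }
  }
  invisible(x)
}
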