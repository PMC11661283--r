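make_ph_cohort <- function(n, betas, n_noise = 0, seed = 1, cens_rate = 0.45,
                           lambda = 0.02, rho = 0) {
  set.seed(seed)
  p <- length(betas) + n_noise
  x <- matrix(rnorm(n * p), n, p)
  if (rho > 0) for (j in 2:p) x[, j] <- rho * x[, j - 1] +
      sqrt(1 - rho^2) * x[, j]
  colnames(x) <- c(sprintf("sig%d", seq_along(betas)),
                   if (n_noise) sprintf("noise%02d", seq_len(n_noise)))
  eta <- as.numeric(x[, seq_along(betas), drop = FALSE] %*% betas)
  t_ev <- rexp(n) / (lambda * exp(eta))
  cens <- rexp(n, lambda * cens_rate)
  ids <- sprintf("s%04d", seq_len(n))
  list(table = feature_table(as.data.frame(x), ids),
       outcome = survival_outcome(pmin(t_ev, cens),
                                  as.integer(t_ev <= cens), ids),
       ids = ids)
}

test_that("sub-partitions split 80/20, reproducibly, and reject tiny cohorts", {
  ids <- sprintf("p%03d", 1:100)
  parts <- make_subpartitions(ids, n = 10, val_fraction = 0.2, seed = 42)
  expect_length(parts$partitions, 10)
  for (p in parts$partitions) {
    expect_length(p$sub_val, 20)
    expect_length(p$sub_train, 80)
    expect_length(intersect(p$sub_train, p$sub_val), 0)
    expect_setequal(c(p$sub_train, p$sub_val), ids)
  }
  expect_identical(make_subpartitions(ids, seed = 42),
                   make_subpartitions(ids, seed = 42))
  p1 <- make_subpartitions(ids, seed = 1)$partitions
  p2 <- make_subpartitions(ids, seed = 2)$partitions
  expect_false(all(mapply(function(a, b)
    setequal(a$sub_val, b$sub_val), p1, p2)))
  expect_error(make_subpartitions(c("a", "b", "c")), "small")
})

test_that("univariate screen passes planted drivers and excludes degenerate features", {
  ch <- make_ph_cohort(300, betas = 1.5, n_noise = 2, seed = 7)
  ch$table$data$flat <- 1  # zero variance
  parts <- make_subpartitions(ch$ids, seed = 3)
  sc <- univariate_screen(ch$table, ch$outcome, parts)
  expect_gt(sc$mean_cindex[sc$feature == "sig1"], 0.7)
  expect_true(sc$pass[sc$feature == "sig1"])
  expect_equal(sc$rank[sc$feature == "sig1"], 1L)
  expect_equal(sc$mean_cindex[sc$feature == "flat"], 0.5)
  expect_false(sc$pass[sc$feature == "flat"])
  expect_true(is.na(sc$rank[sc$feature == "flat"]))
  # ranks of passing features are a permutation of 1..n_passed
  expect_setequal(sc$rank[sc$pass], seq_len(sum(sc$pass)))
})

test_that("pure-noise features screen near 0.5 and fail about half the time", {
  set.seed(77)
  n <- 300
  t_ev <- rexp(n) / 0.02
  cens <- rexp(n, 0.02 * 0.45)
  ids <- sprintf("n%03d", 1:n)
  oc <- survival_outcome(pmin(t_ev, cens), as.integer(t_ev <= cens), ids)
  noise <- as.data.frame(matrix(rnorm(n * 50), n, 50))
  tab <- feature_table(noise, ids)
  parts <- make_subpartitions(ids, seed = 5)
  sc <- univariate_screen(tab, oc, parts)
  expect_lt(abs(mean(sc$mean_cindex) - 0.5), 0.02)
  expect_gt(mean(sc$pass), 0.2)
  expect_lt(mean(sc$pass), 0.8)
})

test_that("forward selection keeps planted features and traces non-decreasing C", {
  ch <- make_ph_cohort(400, betas = c(1.0, 0.8, 0.6), n_noise = 10, seed = 11)
  parts <- make_subpartitions(ch$ids, seed = 12)
  sc <- univariate_screen(ch$table, ch$outcome, parts)
  fs <- forward_select(ch$table, ch$outcome, sc, parts)
  expect_true(all(c("sig1", "sig2", "sig3") %in% fs$model$features))
  acc <- fs$trace$mean_cindex[fs$trace$accepted]
  expect_true(all(diff(acc) > 0))
  expect_equal(fs$model$p_val, max(acc))
  # repeat run is bit-identical under the same seeds
  fs2 <- forward_select(ch$table, ch$outcome, sc, parts)
  expect_identical(fs$model$beta, fs2$model$beta)
})

test_that("forward selection degenerate modes: single feature and max_features cap", {
  ch <- make_ph_cohort(150, betas = 1.2, seed = 21)
  parts <- make_subpartitions(ch$ids, seed = 22)
  sc <- univariate_screen(ch$table, ch$outcome, parts)
  fs <- forward_select(ch$table, ch$outcome, sc, parts)
  expect_identical(fs$model$features, "sig1")
  expect_equal(nrow(fs$trace), 1L)

  ch2 <- make_ph_cohort(300, betas = c(1.0, 0.9), n_noise = 3, seed = 23)
  parts2 <- make_subpartitions(ch2$ids, seed = 24)
  sc2 <- univariate_screen(ch2$table, ch2$outcome, parts2)
  fs2 <- forward_select(ch2$table, ch2$outcome, sc2, parts2,
                        max_features = 1)
  expect_length(fs2$model$features, 1L)
  expect_equal(fs2$model$features,
               sc2$feature[which(sc2$rank == 1)])
})

test_that("predict_risk is the linear log-partial-hazard", {
  model <- structure(list(features = c("a", "b"),
                          beta = c(a = 1, b = -1), p_val = 0.7,
                          ties = "efron", penalty = 0, converged = TRUE,
                          modality = "clinical", endpoint = "OS"),
                     class = "fitted_cox_model")
  tab <- feature_table(data.frame(a = c(2, 0), b = c(3, 0)), c("p1", "p2"))
  r <- predict_risk(model, tab)
  expect_equal(r$scores, c(-1, 0))
  # adding a constant to one covariate shifts risks by beta * c
  tab2 <- feature_table(data.frame(a = c(2, 0) + 5, b = c(3, 0)),
                        c("p1", "p2"))
  expect_equal(predict_risk(model, tab2)$scores, r$scores + 5)
  expect_error(predict_risk(model, feature_table(data.frame(a = 1), "p1")),
               "lacks")
})

test_that("full-cohort Cox fit recovers planted coefficients", {
  err <- replicate(3, {
    ch <- make_ph_cohort(1000, betas = c(1.0, -0.5),
                         seed = sample.int(1e6, 1))
    beta <- mmsurv:::fit_cox(feature_matrix(ch$table), ch$outcome$time,
                             ch$outcome$event)
    abs(beta - c(1.0, -0.5))
  })
  expect_lt(max(rowMeans(err)), 0.15)
})

test_that("fitted model serializes to JSON with its trace", {
  ch <- make_ph_cohort(150, betas = 1.2, seed = 31)
  parts <- make_subpartitions(ch$ids, seed = 32)
  sc <- univariate_screen(ch$table, ch$outcome, parts)
  fs <- forward_select(ch$table, ch$outcome, sc, parts)
  path <- withr::local_tempfile(fileext = ".json")
  cox_model_json(fs$model, fs$trace, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(unlist(back$beta), fs$model$beta)
  expect_equal(back$p_val, fs$model$p_val)
})
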