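test_that("C-index matches hand fixtures and survival::concordance", {
  o <- survival_outcome(c(2, 4, 6, 8), c(1, 0, 1, 1))
  res <- harrell_cindex(c(0.9, 0.8, 0.2, 0.3), o)
  expect_equal(res$point, 0.75)
  expect_equal(res$n_comparable_pairs, 4)

  # perfect ordering and all-tied risks
  o2 <- survival_outcome(c(1, 2, 3, 4), rep(1, 4))
  expect_equal(harrell_cindex(-c(1, 2, 3, 4), o2)$point, 1)
  expect_equal(harrell_cindex(rep(0.3, 4), o2)$point, 0.5)

  # agreement with survival::concordance on tie-free data
  set.seed(2)
  for (i in 1:10) {
    n <- 30
    time <- runif(n, 1, 50)
    event <- rbinom(n, 1, 0.7)
    if (!sum(event)) event[1] <- 1L
    risk <- rnorm(n)
    ours <- harrell_cindex(risk, survival_outcome(time, event))$point
    ref <- survival::concordance(survival::Surv(time, event) ~ risk,
                                 reverse = TRUE)$concordance
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("C-index is invariant to monotone transforms and flips under negation", {
  set.seed(5)
  for (i in 1:10) {
    o <- random_outcome(25, tie_prob = 0)
    risk <- rnorm(25)
    c1 <- harrell_cindex(risk, o)$point
    expect_equal(harrell_cindex(exp(2 * risk), o)$point, c1)
    expect_equal(harrell_cindex(-risk, o)$point, 1 - c1)
  }
})

test_that("bootstrap C-index CI behaves on degenerate and random data", {
  o <- survival_outcome(c(1, 2, 3, 4, 5), rep(1, 5))
  res <- bootstrap_cindex(-(1:5), o, B = 50, seed = 4)
  expect_equal(unname(res$ci), c(1, 1))
  expect_equal(unique(res$replicates), 1)

  set.seed(9)
  oo <- random_outcome(40)
  r <- rnorm(40)
  a <- bootstrap_cindex(r, oo, B = 100, seed = 11)
  b <- bootstrap_cindex(r, oo, B = 100, seed = 11)
  expect_identical(a$replicates, b$replicates)
  expect_true(a$ci[1] <= a$point + 1e-8 && a$point <= a$ci[2] + 1e-8)
})

test_that("compare_cindex is a Welch t-test with degenerate guards", {
  mk <- function(reps) {
    r <- harrell_cindex(c(2, 1), survival_outcome(c(1, 2), c(1, 1)))
    r$replicates <- reps
    r
  }
  same <- compare_cindex(mk(rep(0.8, 50)), mk(rep(0.8, 50)))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  sep <- compare_cindex(mk(rep(0.9, 50)), mk(rep(0.6, 50)))
  expect_equal(sep$p_value, 0)

  set.seed(3)
  x <- rnorm(200, 0.7, 0.05); y <- rnorm(150, 0.65, 0.04)
  ours <- compare_cindex(mk(x), mk(y))
  ref <- t.test(x, y)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("Kaplan-Meier estimate matches the product-limit fixture and brute force", {
  km <- km_estimate(survival_outcome(c(1, 2, 3), c(1, 1, 0)))
  expect_equal(km_surv_at(km, c(1, 2, 3)), c(2 / 3, 1 / 3, 1 / 3))
  expect_equal(km_surv_at(km, 0.5), 1)

  # no censoring: 1 - ECDF at event times; all censored: S = 1
  t0 <- c(3, 1, 4, 2, 6)
  km2 <- km_estimate(survival_outcome(t0, rep(1, 5)))
  expect_equal(km_surv_at(km2, sort(t0)),
               1 - ecdf(t0)(sort(t0)))
  km3 <- km_estimate(survival_outcome(t0, rep(0, 5)))
  expect_true(all(km3$surv == 1))

  set.seed(10)
  for (i in 1:10) {
    o <- random_outcome(30)
    ours <- km_estimate(o)
    ref <- km_brute(o$time, o$event)
    expect_equal(km_surv_at(ours, ref$time), ref$surv, tolerance = 1e-12)
  }
})

test_that("log-rank test matches the hand fixture and a counting-process oracle", {
  a <- survival_outcome(c(1, 2), c(1, 1))
  b <- survival_outcome(c(3, 4), c(1, 1))
  res <- logrank_test(a, b)
  expect_equal(res$chisq, 49 / 17, tolerance = 1e-9)

  expect_equal(logrank_test(a, a)$chisq, 0, tolerance = 1e-12)
  expect_error(logrank_test(survival_outcome(1, 0), survival_outcome(2, 0)),
               "event")

  set.seed(12)
  for (i in 1:10) {
    o1 <- random_outcome(30)
    o2 <- random_outcome(30)
    ours <- logrank_test(o1, o2)$chisq
    ref <- logrank_brute(o1$time, o1$event, o2$time, o2$event)
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("median split sends ties low and handles degenerate risk vectors", {
  s <- median_split(c(1, 2, 3, 4))
  expect_equal(s$threshold, 2.5)
  expect_identical(s$group, c("low", "low", "high", "high"))
  expect_identical(median_split(c(1, 2, 3))$group, c("low", "low", "high"))
  flat <- median_split(rep(2, 5))
  expect_true(flat$degenerate)
  expect_true(all(flat$group == "low"))
})

test_that("horizon labels implement the exclusion rule and partition the cohort", {
  o <- survival_outcome(c(20, 30, 40, 36), c(1, 0, 1, 0))
  lab <- label_at_horizon(o, 36)
  expect_identical(lab$status,
                   c("positive", "excluded", "negative", "negative"))
  set.seed(14)
  for (i in 1:20) {
    oo <- random_outcome(25)
    ll <- label_at_horizon(oo, runif(1, 2, 18))
    expect_equal(sum(table(ll$status)), 25)
    expect_identical(is.na(ll$label), ll$status == "excluded")
  }
})

test_that("DeLong AUC matches brute force, pROC, and a bootstrap variance", {
  # hand fixture: positives (0.9, 0.4), negatives (0.5, 0.1) -> 3/4
  res <- auroc_delong(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0))
  expect_equal(res$auc, 0.75)
  # perfect separation: AUC 1, zero variance
  sep <- auroc_delong(c(5, 6, 1, 2), c(1, 1, 0, 0))
  expect_equal(sep$auc, 1)
  expect_equal(sep$var, 0)

  set.seed(21)
  for (i in 1:10) {
    n <- 40
    lab <- c(rep(1, 15), rep(0, 25))
    risk <- rnorm(n) + lab
    ours <- auroc_delong(risk, lab)
    expect_equal(ours$auc, auc_brute(risk, lab), tolerance = 1e-12)
    ref <- pROC::roc(lab, risk, quiet = TRUE, direction = "<")
    expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
    expect_equal(ours$var, as.numeric(pROC::var(ref, method = "delong")),
                 tolerance = 1e-10)
  }

  # DeLong variance close to a bootstrap variance on one fixed instance
  set.seed(33)
  lab <- rbinom(100, 1, 0.4)
  lab[1:2] <- c(0, 1)
  risk <- rnorm(100) + 0.8 * lab
  dl <- auroc_delong(risk, lab)
  boot <- replicate(2000, {
    idx <- sample(100, replace = TRUE)
    if (length(unique(lab[idx])) < 2) NA else auc_brute(risk[idx], lab[idx])
  })
  expect_lt(abs(dl$var - var(boot, na.rm = TRUE)) / var(boot, na.rm = TRUE),
            0.2)
})

test_that("paired DeLong test agrees with pROC and detects equality", {
  set.seed(25)
  lab <- c(rep(1, 20), rep(0, 30))
  r1 <- rnorm(50) + lab
  r2 <- 0.5 * r1 + rnorm(50, sd = 0.8)
  ours <- delong_test(r1, r2, lab)
  ref <- pROC::roc.test(pROC::roc(lab, r1, quiet = TRUE, direction = "<"),
                        pROC::roc(lab, r2, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(delong_test(r1, r1, lab)$p_value, 1)

  expect_error(auroc_delong(rnorm(5), rep(1, 5)), "positive and one negative")
})
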