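mk_table <- function(dat, modality = "m") {
  feature_table(dat, sprintf("p%03d", seq_len(nrow(dat))), modality)
}

test_that("missingness filter drops strictly above the threshold", {
  dat <- data.frame(a = c(rep(NA, 5), rnorm(15)),   # 25% missing
                    b = c(rep(NA, 4), rnorm(16)),   # exactly 20%
                    c = rnorm(20))
  out <- filter_missingness(mk_table(dat), max_frac = 0.20)
  expect_identical(names(out$data), c("b", "c"))
  expect_identical(attr(out, "dropped"), "a")
  # no missing values -> identity
  full <- mk_table(data.frame(x = 1:5, y = 6:10))
  expect_identical(filter_missingness(full)$data, full$data)
})

test_that("median imputation fills with train medians and replays on test", {
  tab <- mk_table(data.frame(x = c(1, 2, NA, 4)))
  out <- impute_median(tab)
  expect_equal(out$data$x, c(1, 2, 2, 4))
  expect_equal(attr(out, "values")$x, 2)
  # replay on new data uses the train median, not the test median
  test_tab <- mk_table(data.frame(x = c(100, NA, 200)))
  rep_out <- impute_median(test_tab, values = attr(out, "values"))
  expect_equal(rep_out$data$x, c(100, 2, 200))
  # complete column untouched
  comp <- mk_table(data.frame(x = c(3, 1, 2)))
  expect_identical(impute_median(comp)$data$x, c(3, 1, 2))
  expect_error(impute_median(mk_table(data.frame(x = c(NA_real_, NA)))),
               "entirely missing")
})

test_that("one-hot coding uses k-1 dummies with modal reference", {
  dat <- data.frame(g = c(rep("A", 10), rep("B", 5), rep("C", 5)),
                    stringsAsFactors = FALSE)
  out <- one_hot_encode(mk_table(dat), categorical = "g")
  expect_identical(names(out$data), c("g=B", "g=C"))
  expect_equal(sum(out$data$`g=B`), 5)
  expect_equal(attr(out, "levels_map")$g[1], "A")

  # binary column -> single indicator
  bin <- mk_table(data.frame(s = c("M", "M", "F"), stringsAsFactors = FALSE))
  expect_length(one_hot_encode(bin, categorical = "s")$data, 1L)

  # unseen test level -> all-zero indicators
  test_tab <- mk_table(data.frame(g = c("D", "B"), stringsAsFactors = FALSE))
  rep_out <- one_hot_encode(test_tab, levels_map = attr(out, "levels_map"))
  expect_equal(unlist(rep_out$data[1, ]), c(`g=B` = 0, `g=C` = 0))
  expect_equal(rep_out$data$`g=B`[2], 1)
})

test_that("z-score supports both sd conventions and drops constants", {
  tab <- mk_table(data.frame(x = c(1, 2, 3), k = c(5, 5, 5)))
  pop <- zscore(tab, sd_type = "population")
  expect_equal(pop$data$x, c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  smp <- zscore(tab, sd_type = "sample")
  expect_equal(smp$data$x, c(-1, 0, 1))
  expect_identical(attr(smp, "dropped_constant"), "k")
  expect_false("k" %in% names(smp$data))
  # fitted spec applied to its own training column gives mean 0
  expect_equal(mean(smp$data$x), 0)
})

test_that("spearman dedup matches a brute-force greedy oracle", {
  set.seed(31)
  # monotone duplicate: B = 2A + 1 has rho exactly 1
  tab <- mk_table(data.frame(A = rnorm(50), B = NA, C = rnorm(50)))
  tab$data$B <- 2 * tab$data$A + 1
  out <- spearman_dedup(tab, rho_max = 0.8)
  expect_identical(names(out$data), c("A", "C"))
  log <- attr(out, "dropped_log")
  expect_identical(log$dropped, "B")
  expect_equal(log$rho, 1)

  # two independent standard normals at n = 200 both survive
  ind <- mk_table(as.data.frame(matrix(rnorm(400), 200, 2)))
  expect_length(spearman_dedup(ind)$data, 2L)

  # random matrices agree with the oracle, and no kept pair violates rho_max
  for (rep in 1:5) {
    m <- matrix(rnorm(20 * 8), 20, 8)
    m[, 2] <- m[, 1] + rnorm(20, sd = 0.05)
    m[, 7] <- -m[, 3] + rnorm(20, sd = 0.05)
    colnames(m) <- paste0("f", 1:8)
    got <- spearman_dedup(mk_table(as.data.frame(m)), rho_max = 0.8)
    expect_identical(names(got$data), dedup_brute(m, 0.8))
    kept <- feature_matrix(got)
    rho <- cor(apply(kept, 2, rank))
    diag(rho) <- 0
    expect_lt(max(abs(rho)), 0.8 + 1e-12)
  }
})

test_that("fitted pipeline replays exactly on its own training data", {
  set.seed(8)
  n <- 40
  dat <- data.frame(age = rnorm(n, 60, 8), marker = rexp(n),
                    stage = sample(c("I", "II", "III"), n, replace = TRUE),
                    dup = NA, noise = rnorm(n), stringsAsFactors = FALSE)
  dat$dup <- dat$marker * 3 + 1          # rank-duplicate of marker
  dat$age[sample(n, 3)] <- NA            # a little missingness
  tab <- mk_table(dat, "clinical")
  fit <- preprocess_fit(tab, categorical = "stage")

  # training transform: z-scored numerics have mean 0, sd 1
  num <- fit$table$data[, c("age", "marker", "noise")]
  expect_equal(unname(colMeans(num)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(num, 2, sd)), rep(1, 3), tolerance = 1e-12)
  expect_false("dup" %in% names(fit$table$data))

  # replaying the spec on the same raw table reproduces the fit output
  replay <- preprocess_apply(fit$spec, tab)
  expect_equal(feature_matrix(replay), feature_matrix(fit$table))

  # disjoint test data is transformed with train statistics only
  test_dat <- dat[1:10, ]
  test_dat$age <- test_dat$age + 100
  ttab <- feature_table(test_dat, sprintf("q%02d", 1:10), "clinical")
  tt <- preprocess_apply(fit$spec, ttab)
  expect_identical(names(tt$data), fit$spec$kept_features)
  expect_gt(mean(tt$data$age, na.rm = TRUE), 5)  # not re-centered on test

  # spec serializes to JSON and back without changing the transform
  path <- withr::local_tempfile(fileext = ".json")
  preprocess_spec_json(fit$spec, path)
  spec2 <- preprocess_spec_from_json(path)
  expect_equal(feature_matrix(preprocess_apply(spec2, tab)),
               feature_matrix(fit$table))
})
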