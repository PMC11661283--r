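test_that("Nystrom attention reproduces exact attention when landmarks = tokens", {
  cfg <- milnet_config(8, proj_dim = 16, n_heads = 4, n_landmarks = 16)
  params <- init_deep_cph(cfg, seed = 2)
  set.seed(3)
  x <- matrix(rnorm(16 * 16), 16)
  expect_lt(max(abs(nystrom_attention(x, params, cfg) -
                      exact_mhsa(x, params, 4))), 1e-3)
})

test_that("attention handles a single token and is permutation equivariant", {
  cfg <- milnet_config(8, proj_dim = 16, n_heads = 4, n_landmarks = 16)
  params <- init_deep_cph(cfg, seed = 2)
  set.seed(4)
  x1 <- matrix(rnorm(16), 1)
  # softmax over one element: output is the value projection of the token
  expect_equal(nystrom_attention(x1, params, cfg),
               (x1 %*% params$W_v) %*% params$W_o, tolerance = 1e-12)
  # exact-attention path (n below the landmark count)
  x <- matrix(rnorm(10 * 16), 10)
  perm <- sample(10)
  expect_equal(nystrom_attention(x[perm, ], params, cfg),
               nystrom_attention(x, params, cfg)[perm, ], tolerance = 1e-10)
  # landmarks-equal-tokens Nystrom path: landmarks permute with the tokens
  x16 <- matrix(rnorm(16 * 16), 16)
  perm16 <- sample(16)
  expect_equal(nystrom_attention(x16[perm16, ], params, cfg),
               nystrom_attention(x16, params, cfg)[perm16, ],
               tolerance = 1e-10)
})

test_that("Nystrom error decreases with landmarks on average over seeds", {
  cfg0 <- milnet_config(8, proj_dim = 16, n_heads = 4)
  params <- init_deep_cph(cfg0, seed = 6)
  ms <- c(4, 8, 16, 32, 64)
  errs <- matrix(NA_real_, 10, length(ms))
  for (s in 1:10) {
    set.seed(100 + s)
    # structured tokens (low-rank latent + noise) at moderate scale — the
    # smooth-kernel regime the landmark approximation targets
    lat <- matrix(rnorm(64 * 3), 64) %*% matrix(rnorm(3 * 16), 3)
    x <- 0.5 * (lat + 0.1 * matrix(rnorm(64 * 16), 64))
    ref <- exact_mhsa(x, params, 4)
    for (j in seq_along(ms)) {
      cfg <- milnet_config(8, proj_dim = 16, n_heads = 4, n_landmarks = ms[j])
      errs[s, j] <- mean(abs(nystrom_attention(x, params, cfg) - ref))
    }
  }
  avg <- colMeans(errs)
  expect_true(all(diff(avg) < 0))
  expect_lt(avg[length(ms)], 1e-3)
})

test_that("Cox NLPL loss matches closed forms and is monotone in risk", {
  o2 <- survival_outcome(c(1, 2), c(1, 1))
  expect_equal(cox_nlpl_loss(c(0, 0), o2), log(2) / 2)
  o_cens <- survival_outcome(c(1, 5), c(1, 0))
  for (r in c(-2, 0, 1.3, 4)) {
    expect_equal(cox_nlpl_loss(c(r, 0), o_cens), log(1 + exp(-r)))
  }
  losses <- vapply(c(-1, 0, 1, 2), function(r)
    cox_nlpl_loss(c(r, 0), o_cens), 0)
  expect_true(all(diff(losses) < 0))
  expect_error(cox_nlpl_loss(c(0, 0), survival_outcome(c(1, 2), c(0, 0))),
               "no event")
})

test_that("NLPL gradient matches central finite differences", {
  set.seed(7)
  n <- 20
  o <- survival_outcome(runif(n, 0, 10), rbinom(n, 1, 0.6))
  if (!sum(o$event)) o$event[1] <- 1L
  r <- rnorm(n)
  g <- cox_nlpl_grad(r, o)
  fd <- vapply(seq_len(n), function(i) {
    e <- 1e-6
    rp <- r; rp[i] <- r[i] + e
    rm <- r; rm[i] <- r[i] - e
    (cox_nlpl_loss(rp, o) - cox_nlpl_loss(rm, o)) / (2 * e)
  }, 0)
  expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-8)), 1e-5)
})

test_that("network gradients match finite differences on both attention paths", {
  for (lm in c(4L, 64L)) {  # 4 -> Nystrom path, 64 -> exact fallback
    cfg <- milnet_config(5, proj_dim = 8, dropout = 0, n_heads = 2,
                         n_landmarks = lm)
    params <- init_deep_cph(cfg, seed = 3)
    set.seed(40 + lm)
    x <- matrix(rnorm(12 * 5), 12)
    fw <- mmsurv:::deep_forward_tape(params, x, cfg)
    gr <- mmsurv:::ad_backward(fw$tape, fw$risk_id, 1)
    for (nm in names(params)) {
      i <- which.max(abs(gr[[nm]]))
      e <- 1e-6
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + e
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - e
      fd <- (mmsurv:::deep_forward_tape(p1, x, cfg)$risk -
               mmsurv:::deep_forward_tape(p2, x, cfg)$risk) / (2 * e)
      expect_lt(abs(gr[[nm]][i] - fd) / max(abs(fd), 1e-8), 1e-4)
    }
  }
})

test_that("eval-mode forward obeys pooling and linear-head identities", {
  cfg <- milnet_config(6, proj_dim = 8, n_heads = 2)
  params <- init_deep_cph(cfg, seed = 9)
  model <- structure(list(params = params, net_cfg = cfg),
                     class = "deep_risk_model")
  set.seed(10)
  v <- matrix(rnorm(6), 1)
  rep_bag <- embedding_bag("p", v[rep(1, 7), , drop = FALSE])
  one_bag <- embedding_bag("p", v)
  expect_equal(deep_cph_forward(model, rep_bag),
               deep_cph_forward(model, one_bag), tolerance = 1e-10)

  zeroed <- params
  zeroed$w_head <- zeroed$w_head * 0
  zeroed$b_head <- zeroed$b_head * 0
  mz <- structure(list(params = zeroed, net_cfg = cfg),
                  class = "deep_risk_model")
  expect_equal(deep_cph_forward(mz, embedding_bag("p", matrix(rnorm(30), 5))),
               0)

  bag <- embedding_bag("p", matrix(rnorm(40 * 6), 40))
  expect_identical(deep_cph_forward(model, bag), deep_cph_forward(model, bag))
  expect_error(deep_cph_forward(model, matrix(rnorm(10), 2)), "dimension")
})

test_that("bag risk prediction is aligned, deterministic, duplication-invariant", {
  ch <- make_bag_cohort(n = 20, seed = 15)
  cfg <- milnet_config(8, proj_dim = 8, n_heads = 2)
  model <- structure(list(params = init_deep_cph(cfg, seed = 2),
                          net_cfg = cfg),
                     class = "deep_risk_model")
  rv <- predict_bag_risk(model, ch$bags)
  expect_length(rv$scores, 20)
  expect_identical(rv$patient_ids, names(ch$bags))
  doubled <- lapply(ch$bags, function(b)
    embedding_bag(b$patient_id, rbind(b$vectors, b$vectors)))
  rv2 <- predict_bag_risk(model, doubled)
  expect_equal(rank(rv$scores), rank(rv2$scores))
})

test_that("training reduces the loss on planted bags and is seed-reproducible", {
  ch <- make_bag_cohort(n = 60, d = 8, patches = c(10, 30), seed = 5)
  net <- milnet_config(8, proj_dim = 16, n_heads = 2, dropout = 0.1)
  tc <- train_config(epochs = 6, accumulation_size = 16, seed = 13)
  m <- train_deep_cph(ch$bags, ch$outcome, net, tc)
  expect_lt(m$history$train_loss[5], m$history$train_loss[1])
  expect_lt(tail(m$history$val_loss, 1), m$history$val_loss[1])
  m2 <- train_deep_cph(ch$bags, ch$outcome, net, tc)
  expect_identical(m$history, m2$history)
  expect_identical(m$params, m2$params)
  # checkpoint round trip preserves predictions exactly
  path <- withr::local_tempfile(fileext = ".json")
  save_deep_cph(m, path)
  m3 <- load_deep_cph(path)
  expect_equal(predict_bag_risk(m3, ch$bags)$scores,
               predict_bag_risk(m, ch$bags)$scores, tolerance = 1e-12)
})

test_that("training rejects event-free cohorts", {
  ch <- make_bag_cohort(n = 40, seed = 6)
  oc <- survival_outcome(ch$outcome$time, rep(0L, 40), ch$ids)
  expect_error(train_deep_cph(ch$bags, oc,
                              milnet_config(8, proj_dim = 8, n_heads = 2)),
               "no events")
})
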