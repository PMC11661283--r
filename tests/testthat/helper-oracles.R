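# Independent brute-force oracles used to validate the package's metric and
# attention implementations. These are deliberately naive implementations
# kept separate from the package code paths.

# Harrell C by explicit pair enumeration: comparable iff the earlier time is
# an event; risk ties count 0.5.
cindex_brute <- function(risk, time, event) {
  num <- 0; den <- 0
  n <- length(risk)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (time[i] < time[j] && event[i] == 1) {
        den <- den + 1
        num <- num + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
      }
    }
  }
  num / den
}

# AUC by explicit Mann-Whitney pair enumeration.
auc_brute <- function(risk, label) {
  pos <- risk[label == 1]; neg <- risk[label == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Two-group log-rank chi-square via the counting-process formulation.
logrank_brute <- function(t1, e1, t2, e2) {
  time <- c(t1, t2); event <- c(e1, e2)
  grp <- c(rep(1, length(t1)), rep(2, length(t2)))
  o_minus_e <- 0; v <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == 1)
    d <- sum(event == 1 & time == tt)
    d1 <- sum(event == 1 & time == tt & grp == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Kaplan-Meier product-limit by hand.
km_brute <- function(time, event) {
  ts <- sort(unique(time))
  s <- 1
  out <- data.frame(time = ts, surv = NA_real_)
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n_risk)
    out$surv[i] <- s
  }
  out
}

# Exact multi-head softmax self-attention (reference for the Nystrom module).
exact_mhsa <- function(x, params, n_heads) {
  p <- ncol(x); dh <- p / n_heads
  Q <- x %*% params$W_q; K <- x %*% params$W_k; V <- x %*% params$W_v
  out <- matrix(0, nrow(x), p)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    S <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dh)
    P <- exp(S - apply(S, 1, max)); P <- P / rowSums(P)
    out[, idx] <- P %*% V[, idx, drop = FALSE]
  }
  out %*% params$W_o
}

# Random censored survival data for metric oracle sweeps.
random_outcome <- function(n, p_event = 0.6, tie_prob = 0.3) {
  time <- round(runif(n, 1, 20) * ifelse(runif(n) < tie_prob, 1, 1.0001), 2)
  event <- rbinom(n, 1, p_event)
  if (sum(event) == 0) event[sample(n, 1)] <- 1L
  survival_outcome(time, event)
}

# Greedy Spearman dedup oracle (quadratic, recomputes rho from scratch).
dedup_brute <- function(m, rho_max) {
  kept <- integer()
  for (j in seq_len(ncol(m))) {
    ok <- TRUE
    for (k in kept) {
      if (abs(cor(m[, j], m[, k], method = "spearman")) > rho_max) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, j)
  }
  colnames(m)[kept]
}

# Small planted-signal bag cohort shared by the deep-model tests.
make_bag_cohort <- function(n = 60, d = 8, patches = c(10, 30), seed = 5,
                            scale = 2) {
  set.seed(seed)
  ids <- sprintf("B%03d", seq_len(n))
  eta <- rnorm(n)
  bags <- simulate_bags(stats::setNames(eta, ids),
                        bag_config(d = d, patches_range = patches,
                                   signal_scale = scale),
                        seed = seed + 1)
  t_ev <- rexp(n) / (0.02 * exp(eta))
  cens <- rexp(n, 0.02 * 0.45)
  outcome <- survival_outcome(pmin(t_ev, cens), as.integer(t_ev <= cens), ids)
  list(bags = bags, outcome = outcome, eta = eta, ids = ids)
}
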