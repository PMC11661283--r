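#' Network configuration for the attention-MIL deep Cox model
#'
#' Architecture: each patch embedding is linearly projected to `proj_dim`,
#' passed through ReLU (+ dropout during training), mixed across patches by
#' multi-head self-attention with a Nystrom low-rank approximation, average
#' pooled over patches, and mapped to a scalar risk by a linear head.
#'
#' @param input_dim Embedding dimension d of the patch vectors.
#' @param proj_dim Projection width, default 256.
#' @param dropout Dropout rate after the projection, default 0.25.
#' @param n_heads Attention heads, default 8 (`proj_dim` must be divisible).
#' @param n_landmarks Landmark count m for the Nystrom approximation,
#'   default 256; bags with fewer than `n_landmarks` patches use exact
#'   attention.
#' @param pinv_iterations Newton-Schulz iterations for the approximate
#'   Moore-Penrose pseudo-inverse of the landmark kernel, default 18 (enough
#'   for the landmark-equals-token limit to reproduce exact attention to
#'   numerical precision on well-conditioned kernels).
#' @return List of class `milnet_config`.
#' @export
milnet_config <- function(input_dim, proj_dim = 256, dropout = 0.25,
                          n_heads = 8, n_landmarks = 256,
                          pinv_iterations = 18) {
  stopifnot(input_dim >= 1, proj_dim %% n_heads == 0, n_landmarks >= 1,
            dropout >= 0, dropout < 1, pinv_iterations >= 1)
  structure(list(input_dim = as.integer(input_dim),
                 proj_dim = as.integer(proj_dim), dropout = dropout,
                 n_heads = as.integer(n_heads),
                 n_landmarks = as.integer(n_landmarks),
                 pinv_iterations = as.integer(pinv_iterations)),
            class = "milnet_config")
}

#' Training configuration for the deep Cox model
#'
#' Defaults follow common MIL-survival practice: Adam at learning rate 0.001,
#' 100 epochs, up to 4096 randomly sampled patches per bag per training step
#' (full bags at test time), and plateau learning-rate decay (multiply by
#' `plateau_gamma` when the internal-validation loss has not improved for
#' `plateau_patience` epochs). Bags are scored one at a time; risk scores are
#' accumulated over `accumulation_size` patients before the partial-likelihood
#' loss and gradient step, since the Cox loss needs cross-patient risk sets.
#'
#' @param lr Initial learning rate, default 0.001.
#' @param epochs Training epochs, default 100.
#' @param patches_per_bag_train Patch subsample cap per bag during training,
#'   default 4096 (without replacement; smaller bags are used whole).
#' @param plateau_patience Epochs without validation improvement before decay,
#'   default 5.
#' @param plateau_gamma Decay factor, default 0.1.
#' @param accumulation_size Patients per loss/update, default 32 (>= 2).
#' @param val_fraction Internal validation split for the scheduler, default
#'   0.2, stratified by event.
#' @param seed RNG seed controlling init, splits, subsampling and dropout.
#' @return List of class `train_config`.
#' @export
train_config <- function(lr = 0.001, epochs = 100,
                         patches_per_bag_train = 4096, plateau_patience = 5,
                         plateau_gamma = 0.1, accumulation_size = 32,
                         val_fraction = 0.2, seed = 1) {
  stopifnot(lr > 0, epochs >= 1, patches_per_bag_train >= 1,
            plateau_patience >= 1, plateau_gamma > 0, plateau_gamma <= 1,
            accumulation_size >= 2, val_fraction > 0, val_fraction < 1)
  structure(list(lr = lr, epochs = as.integer(epochs),
                 patches_per_bag_train = as.integer(patches_per_bag_train),
                 plateau_patience = as.integer(plateau_patience),
                 plateau_gamma = plateau_gamma,
                 accumulation_size = as.integer(accumulation_size),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

xavier <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

#' Initialise deep Cox model parameters
#'
#' Xavier-uniform weights, zero biases; reproducible under `seed`.
#'
#' @param net_cfg A [milnet_config()].
#' @param seed Integer seed.
#' @return Named list of parameter matrices (`W_proj`, `b_proj`, `W_q`,
#'   `W_k`, `W_v`, `W_o`, `w_head`, `b_head`).
#' @export
init_deep_cph <- function(net_cfg, seed = 1) {
  set.seed(seed)
  d <- net_cfg$input_dim
  p <- net_cfg$proj_dim
  list(W_proj = xavier(d, p), b_proj = matrix(0, 1, p),
       W_q = xavier(p, p), W_k = xavier(p, p), W_v = xavier(p, p),
       W_o = xavier(p, p),
       w_head = xavier(p, 1), b_head = matrix(0, 1, 1))
}

# Averaging matrix mapping n tokens to m landmark (segment-mean) tokens.
landmark_matrix <- function(n, m) {
  sizes <- rep(n %/% m, m)
  extra <- n %% m
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  S <- matrix(0, m, n)
  pos <- 0L
  for (i in seq_len(m)) {
    S[i, (pos + 1L):(pos + sizes[i])] <- 1 / sizes[i]
    pos <- pos + sizes[i]
  }
  S
}

# Newton-Schulz iterative Moore-Penrose pseudo-inverse of a square kernel,
# on the tape. The initial scaling constant is treated as a stop-gradient.
ad_iterative_pinv <- function(tp, a_id, iters) {
  av <- ad_value(tp, a_id)
  m <- nrow(av)
  s <- 1 / (max(rowSums(abs(av))) * max(colSums(abs(av))))
  I7 <- ad_const(tp, 7 * diag(m))
  I15 <- ad_const(tp, 15 * diag(m))
  I13 <- ad_const(tp, 13 * diag(m))
  z <- ad_scale(tp, ad_transpose(tp, a_id), s)
  for (k in seq_len(iters)) {
    az <- ad_matmul(tp, a_id, z)
    t1 <- ad_matmul(tp, az, ad_sub(tp, I7, az))
    t2 <- ad_matmul(tp, az, ad_sub(tp, I15, t1))
    z <- ad_scale(tp, ad_matmul(tp, z, ad_sub(tp, I13, t2)), 0.25)
  }
  z
}

# One attention head on the tape. Exact softmax attention when the sequence
# is shorter than the landmark count, Nystrom approximation otherwise.
ad_attention_head <- function(tp, q, k, v, cfg) {
  n <- nrow(ad_value(tp, q))
  dh <- ncol(ad_value(tp, q))
  sc <- 1 / sqrt(dh)
  if (n < cfg$n_landmarks) {
    p <- ad_softmax_rows(tp, ad_scale(tp, ad_matmul(tp, q, ad_transpose(tp, k)), sc))
    return(ad_matmul(tp, p, v))
  }
  m <- cfg$n_landmarks
  S <- ad_const(tp, landmark_matrix(n, m))
  ql <- ad_matmul(tp, S, q)
  kl <- ad_matmul(tp, S, k)
  f1 <- ad_softmax_rows(tp, ad_scale(tp, ad_matmul(tp, q, ad_transpose(tp, kl)), sc))
  a <- ad_softmax_rows(tp, ad_scale(tp, ad_matmul(tp, ql, ad_transpose(tp, kl)), sc))
  b <- ad_softmax_rows(tp, ad_scale(tp, ad_matmul(tp, ql, ad_transpose(tp, k)), sc))
  ainv <- ad_iterative_pinv(tp, a, cfg$pinv_iterations)
  ad_matmul(tp, f1, ad_matmul(tp, ainv, ad_matmul(tp, b, v)))
}

ad_mhsa <- function(tp, h, pid, cfg) {
  q <- ad_matmul(tp, h, pid$W_q)
  k <- ad_matmul(tp, h, pid$W_k)
  v <- ad_matmul(tp, h, pid$W_v)
  dh <- cfg$proj_dim / cfg$n_heads
  heads <- lapply(seq_len(cfg$n_heads), function(hh) {
    idx <- ((hh - 1) * dh + 1):(hh * dh)
    ad_attention_head(tp, ad_cols(tp, q, idx), ad_cols(tp, k, idx),
                      ad_cols(tp, v, idx), cfg)
  })
  ad_matmul(tp, ad_cbind(tp, heads), pid$W_o)
}

# Full forward pass on a fresh tape. Returns tape, risk node id and value.
deep_forward_tape <- function(params, x, cfg, train_mode = FALSE) {
  tp <- ad_tape()
  pid <- lapply(params, function(w) NULL)
  for (nm in names(params)) pid[[nm]] <- ad_param(tp, params[[nm]], nm)
  xid <- ad_const(tp, x)
  h <- ad_relu(tp, ad_addrow(tp, ad_matmul(tp, xid, pid$W_proj), pid$b_proj))
  if (train_mode && cfg$dropout > 0) {
    keep <- (matrix(stats::runif(length(ad_value(tp, h))),
                    nrow(ad_value(tp, h))) > cfg$dropout) * 1
    h <- ad_mulconst(tp, h, keep / (1 - cfg$dropout))
  }
  att <- ad_mhsa(tp, h, pid, cfg)
  pooled <- ad_meanrows(tp, att)
  risk <- ad_add(tp, ad_matmul(tp, pooled, pid$w_head), pid$b_head)
  list(tape = tp, risk_id = risk, risk = as.numeric(ad_value(tp, risk)))
}

#' Multi-head self-attention with Nystrom approximation
#'
#' Applies the model's attention layer to a token matrix: the n x n softmax
#' attention kernel is approximated through m landmark tokens (segment means
#' of the sequence), two small softmax kernels, and an iteratively
#' approximated pseudo-inverse of the m x m landmark kernel. Sequences
#' shorter than the landmark count fall back to exact attention. Output shape
#' equals input shape; with no positional encoding the map is permutation
#' equivariant.
#'
#' @param tokens `n x proj_dim` numeric matrix.
#' @param params Parameter list with `W_q`, `W_k`, `W_v`, `W_o` (e.g. from
#'   [init_deep_cph()]).
#' @param config A [milnet_config()] (uses `proj_dim`, `n_heads`,
#'   `n_landmarks`, `pinv_iterations`).
#' @return `n x proj_dim` matrix.
#' @export
nystrom_attention <- function(tokens, params, config) {
  tokens <- as.matrix(tokens)
  stopifnot(ncol(tokens) == config$proj_dim)
  tp <- ad_tape()
  pid <- list(W_q = ad_const(tp, params$W_q), W_k = ad_const(tp, params$W_k),
              W_v = ad_const(tp, params$W_v), W_o = ad_const(tp, params$W_o))
  h <- ad_const(tp, tokens)
  out <- ad_mhsa(tp, h, pid, config)
  ad_value(tp, out)
}

#' Average negative log partial likelihood (Breslow)
#'
#' The Cox partial-likelihood loss over a set of patients:
#' `-(1/n_events) * sum_{i: event} [ r_i - log sum_{j: t_j >= t_i} exp(r_j) ]`
#' with Breslow handling of ties (risk set is every patient still under
#' observation at the event time, inclusive).
#'
#' @param risks Numeric risk scores.
#' @param outcome A [survival_outcome()] aligned with `risks`.
#' @return Scalar loss (finite; errors when the batch has no event).
#' @export
cox_nlpl_loss <- function(risks, outcome) {
  r <- as.numeric(risks)
  t <- outcome$time
  e <- outcome$event
  ev <- which(e == 1L)
  if (!length(ev)) stop("batch contains no event; resample")
  mx <- max(r)
  ll <- vapply(ev, function(i) {
    rs <- r[t >= t[i]]
    r[i] - (log(sum(exp(rs - mx))) + mx)
  }, 0)
  -mean(ll)
}

#' Gradient of the average negative log partial likelihood
#'
#' @inheritParams cox_nlpl_loss
#' @return Numeric vector `d loss / d risks`.
#' @export
cox_nlpl_grad <- function(risks, outcome) {
  r <- as.numeric(risks)
  t <- outcome$time
  e <- outcome$event
  ev <- which(e == 1L)
  if (!length(ev)) stop("batch contains no event; resample")
  mx <- max(r)
  w <- numeric(length(r))
  for (i in ev) {
    inset <- t >= t[i]
    expr <- exp(r - mx) * inset
    w <- w + expr / sum(expr)
  }
  -(as.numeric(e) - w) / length(ev)
}

# Stratified (by event) internal validation split; returns index list.
stratified_val_split <- function(event, val_fraction) {
  idx_e <- which(event == 1L)
  idx_c <- which(event == 0L)
  n_ve <- max(1L, round(val_fraction * length(idx_e)))
  n_vc <- max(1L, round(val_fraction * length(idx_c)))
  if (length(idx_e) - n_ve < 1L) n_ve <- length(idx_e) - 1L
  val <- c(if (n_ve > 0) sample(idx_e, n_ve), sample(idx_c, n_vc))
  list(val = sort(val), train = setdiff(seq_along(event), sort(val)))
}

#' Train the attention-MIL deep Cox model
#'
#' Bags are scored one patient at a time; risk scores accumulate over
#' `accumulation_size` patients, then the Breslow negative log partial
#' likelihood over the accumulated group is backpropagated through every
#' patient's tape and Adam updates the shared parameters. An internal
#' event-stratified validation split drives plateau learning-rate decay.
#' Fully reproducible on CPU under `train_cfg$seed`.
#'
#' @param bags Named list of [embedding_bag()] keyed by patient id.
#' @param outcome A [survival_outcome()] covering those patients.
#' @param net_cfg A [milnet_config()]; `input_dim` must match the bags.
#' @param train_cfg A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return Object of class `deep_risk_model`: `params`, `net_cfg`,
#'   `train_cfg`, `history` (per-epoch train/val loss and lr), `val_ids`,
#'   `val_cindex` (eval-mode C-index on the internal validation split, the
#'   modality's validation performance `p_val`).
#' @export
train_deep_cph <- function(bags, outcome, net_cfg, train_cfg = train_config(),
                           verbose = FALSE) {
  ids <- outcome$patient_ids
  if (!all(ids %in% names(bags))) stop("missing bags for some patients")
  d <- unique(vapply(bags[ids], function(b) ncol(b$vectors), 0L))
  if (length(d) != 1L || d != net_cfg$input_dim) {
    stop("bag dimension does not match net_cfg$input_dim")
  }
  if (sum(outcome$event) == 0L) stop("no events in training data")
  if (length(ids) < train_cfg$accumulation_size) {
    stop("need at least accumulation_size patients")
  }
  set.seed(train_cfg$seed)
  params <- init_deep_cph(net_cfg, seed = train_cfg$seed)
  split <- stratified_val_split(outcome$event, train_cfg$val_fraction)
  tr_ids <- ids[split$train]
  val_ids <- ids[split$val]
  o_tr <- outcome_subset(outcome, tr_ids)
  o_val <- outcome_subset(outcome, val_ids)
  if (sum(o_tr$event) == 0L) stop("no events left in the training split")

  adam_m <- lapply(params, function(w) w * 0)
  adam_v <- lapply(params, function(w) w * 0)
  adam_t <- 0L
  lr <- train_cfg$lr
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best_val <- Inf
  stall <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), lr = numeric())
  eval_risks <- function(pids) {
    vapply(pids, function(id)
      deep_forward_tape(params, bags[[id]]$vectors, net_cfg,
                        train_mode = FALSE)$risk, 0)
  }
  for (epoch in seq_len(train_cfg$epochs)) {
    ord <- sample(tr_ids)
    groups <- split(ord, ceiling(seq_along(ord) / train_cfg$accumulation_size))
    ep_losses <- c()
    for (g in groups) {
      og <- outcome_subset(o_tr, g)
      if (sum(og$event) == 0L) next
      tapes <- vector("list", length(g))
      risks <- numeric(length(g))
      for (k in seq_along(g)) {
        x <- bags[[g[k]]]$vectors
        if (nrow(x) > train_cfg$patches_per_bag_train) {
          x <- x[sample.int(nrow(x), train_cfg$patches_per_bag_train), ,
                 drop = FALSE]
        }
        fw <- deep_forward_tape(params, x, net_cfg, train_mode = TRUE)
        tapes[[k]] <- fw
        risks[k] <- fw$risk
      }
      loss <- cox_nlpl_loss(risks, og)
      ep_losses <- c(ep_losses, loss)
      dr <- cox_nlpl_grad(risks, og)
      grads <- lapply(params, function(w) w * 0)
      for (k in seq_along(g)) {
        pg <- ad_backward(tapes[[k]]$tape, tapes[[k]]$risk_id, seed = dr[k])
        for (nm in names(pg)) grads[[nm]] <- grads[[nm]] + pg[[nm]]
      }
      adam_t <- adam_t + 1L
      for (nm in names(params)) {
        adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * grads[[nm]]
        adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * grads[[nm]]^2
        mhat <- adam_m[[nm]] / (1 - b1^adam_t)
        vhat <- adam_v[[nm]] / (1 - b2^adam_t)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    val_loss <- if (sum(o_val$event) > 0L) {
      cox_nlpl_loss(eval_risks(val_ids), o_val)
    } else NA_real_
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = mean(ep_losses),
                                   val_loss = val_loss, lr = lr))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2g", epoch,
                      mean(ep_losses), val_loss, lr))
    }
    if (is.finite(val_loss) && val_loss < best_val - 1e-8) {
      best_val <- val_loss
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= train_cfg$plateau_patience) {
        lr <- lr * train_cfg$plateau_gamma
        stall <- 0L
      }
    }
  }
  val_ci <- tryCatch(harrell_cindex(eval_risks(val_ids), o_val)$point,
                     error = function(e) NA_real_)
  structure(list(params = params, net_cfg = net_cfg, train_cfg = train_cfg,
                 history = hist, val_ids = val_ids, val_cindex = val_ci,
                 p_val = val_ci),
            class = "deep_risk_model")
}

#' @export
print.deep_risk_model <- function(x, ...) {
  cat(sprintf("<deep_risk_model> d=%d proj=%d heads=%d | %d epochs | val C-index %.3f\n",
              x$net_cfg$input_dim, x$net_cfg$proj_dim, x$net_cfg$n_heads,
              nrow(x$history), x$val_cindex))
  invisible(x)
}

#' Deterministic evaluation-mode forward pass for one bag
#'
#' @param model A `deep_risk_model` (or a bare parameter list with a
#'   `net_cfg` supplied).
#' @param bag An [embedding_bag()] or an `n x d` matrix.
#' @return Scalar risk score.
#' @export
deep_cph_forward <- function(model, bag) {
  x <- if (inherits(bag, "embedding_bag")) bag$vectors else as.matrix(bag)
  if (ncol(x) != model$net_cfg$input_dim) {
    stop("bag dimension does not match the model input dimension")
  }
  deep_forward_tape(model$params, x, model$net_cfg, train_mode = FALSE)$risk
}

#' Predict risks for a set of bags (full bags, eval mode)
#'
#' @param model A `deep_risk_model`.
#' @param bags Named list of [embedding_bag()].
#' @param endpoint Endpoint label for the returned [risk_vector()].
#' @return A [risk_vector()] over `names(bags)`.
#' @export
predict_bag_risk <- function(model, bags, endpoint = "OS") {
  scores <- vapply(bags, function(b) deep_cph_forward(model, b), 0)
  risk_vector(names(bags), scores, modality = "wsi", endpoint = endpoint)
}

#' Save / load a deep Cox model checkpoint
#'
#' Parameters and both configs serialize to a single JSON file (text-only
#' checkpoint; exact double round trip).
#'
#' @param model A `deep_risk_model`.
#' @param path Output JSON path.
#' @return `path` invisibly; `load_deep_cph()` returns the model.
#' @export
save_deep_cph <- function(model, path) {
  payload <- list(
    params = lapply(model$params, function(w)
      list(dim = dim(w), data = as.numeric(w))),
    net_cfg = unclass(model$net_cfg), train_cfg = unclass(model$train_cfg),
    val_cindex = model$val_cindex, val_ids = model$val_ids)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_deep_cph
#' @export
load_deep_cph <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(p$params, function(w) matrix(w$data, w$dim[1], w$dim[2]))
  structure(list(params = params,
                 net_cfg = structure(as.list(p$net_cfg), class = "milnet_config"),
                 train_cfg = structure(as.list(p$train_cfg), class = "train_config"),
                 history = NULL, val_ids = p$val_ids,
                 val_cindex = p$val_cindex, p_val = p$val_cindex),
            class = "deep_risk_model")
}
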