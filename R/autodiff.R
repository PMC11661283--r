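# Minimal tape-based reverse-mode automatic differentiation over real
# matrices. This is the numerical core behind the attention-MIL deep Cox
# model: every forward pass records a tape of matrix operations; backward()
# replays it in reverse, accumulating gradients for named parameter leaves.
# Only the operations the network needs are implemented.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 64L)
  tp$n <- 0L
  tp
}

ad_push <- function(tp, value, parents = integer(), backward = NULL,
                    pname = NULL) {
  # force before reserving an id: evaluating `value` may push nested nodes
  force(value)
  force(parents)
  id <- tp$n + 1L
  if (id > length(tp$nodes)) {
    tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  }
  tp$nodes[[id]] <- list(value = value, parents = parents,
                         backward = backward, pname = pname)
  tp$n <- id
  id
}

ad_value <- function(tp, id) {
  # force the id before touching tp$nodes: evaluating a lazily-passed
  # expression may itself push new nodes onto the tape
  force(id)
  tp$nodes[[id]]$value
}

ad_const <- function(tp, v) ad_push(tp, as.matrix(v))

ad_param <- function(tp, v, name) ad_push(tp, as.matrix(v), pname = name)

ad_matmul <- function(tp, a, b) {
  va <- ad_value(tp, a); vb <- ad_value(tp, b)
  ad_push(tp, va %*% vb, c(a, b), function(g, get) {
    list(g %*% t(get(b)), t(get(a)) %*% g)
  })
}

ad_transpose <- function(tp, a) {
  ad_push(tp, t(ad_value(tp, a)), a, function(g, get) list(t(g)))
}

ad_add <- function(tp, a, b) {
  ad_push(tp, ad_value(tp, a) + ad_value(tp, b), c(a, b),
          function(g, get) list(g, g))
}

ad_sub <- function(tp, a, b) {
  ad_push(tp, ad_value(tp, a) - ad_value(tp, b), c(a, b),
          function(g, get) list(g, -g))
}

# a: n x p, bias: 1 x p broadcast over rows
ad_addrow <- function(tp, a, bias) {
  va <- ad_value(tp, a); vb <- ad_value(tp, bias)
  ad_push(tp, sweep(va, 2, as.numeric(vb), "+"), c(a, bias),
          function(g, get) list(g, matrix(colSums(g), 1L)))
}

ad_scale <- function(tp, a, s) {
  ad_push(tp, s * ad_value(tp, a), a, function(g, get) list(s * g))
}

# elementwise product with a constant matrix (dropout masks etc.)
ad_mulconst <- function(tp, a, m) {
  ad_push(tp, ad_value(tp, a) * m, a, function(g, get) list(g * m))
}

ad_relu <- function(tp, a) {
  va <- ad_value(tp, a)
  mask <- (va > 0) * 1
  ad_push(tp, va * mask, a, function(g, get) list(g * mask))
}

ad_softmax_rows <- function(tp, a) {
  va <- ad_value(tp, a)
  y <- exp(va - apply(va, 1, max))
  y <- y / rowSums(y)
  ad_push(tp, y, a, function(g, get) {
    list(y * (g - rowSums(g * y)))
  })
}

ad_cols <- function(tp, a, idx) {
  va <- ad_value(tp, a)
  nc <- ncol(va)
  ad_push(tp, va[, idx, drop = FALSE], a, function(g, get) {
    out <- matrix(0, nrow(g), nc)
    out[, idx] <- g
    list(out)
  })
}

ad_cbind <- function(tp, ids) {
  vals <- lapply(ids, function(i) ad_value(tp, i))
  widths <- vapply(vals, ncol, 0L)
  ad_push(tp, do.call(cbind, vals), as.integer(ids), function(g, get) {
    ends <- cumsum(widths)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    lapply(seq_along(widths), function(k) g[, starts[k]:ends[k], drop = FALSE])
  })
}

# column means over rows -> 1 x p
ad_meanrows <- function(tp, a) {
  va <- ad_value(tp, a)
  n <- nrow(va)
  ad_push(tp, matrix(colMeans(va), 1L), a, function(g, get) {
    list(matrix(rep(as.numeric(g) / n, each = n), n))
  })
}

# Backward pass from scalar (1x1) node `id` with seed gradient `seed`.
# Returns a named list of gradients for all parameter leaves on the tape.
ad_backward <- function(tp, id, seed = 1) {
  grads <- vector("list", tp$n)
  grads[[id]] <- matrix(seed, nrow(ad_value(tp, id)),
                        ncol(ad_value(tp, id)))
  get <- function(i) tp$nodes[[i]]$value
  pgrads <- list()
  for (i in seq(tp$n, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    node <- tp$nodes[[i]]
    if (!is.null(node$pname)) {
      pgrads[[node$pname]] <- if (is.null(pgrads[[node$pname]])) g else
        pgrads[[node$pname]] + g
    }
    if (is.null(node$backward)) next
    pg <- node$backward(g, get)
    for (k in seq_along(node$parents)) {
      p <- node$parents[k]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
  }
  pgrads
}
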