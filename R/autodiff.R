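# Minimal reverse-mode automatic differentiation over matrices.
#
# The generator networks are small enough that a hand-written tape engine
# in R (backed by BLAS matrix products) trains them at desk scale.  Nodes
# are environments holding a value, an accumulated gradient and a backward
# closure; `ad_backward()` runs a topological traversal from the loss.
#
# Every op is dual-mode: with gradients disabled (`ad_no_grad()`), plain
# matrices flow through the same code paths with no tape overhead, which is
# what sampling uses.

ad_env <- new.env(parent = emptyenv())
ad_env$grad_on <- TRUE
ad_env$id <- 0L

ad_grad_enabled <- function() isTRUE(ad_env$grad_on)

#' Evaluate code with gradient recording disabled
#' @param code Expression to evaluate.
#' @keywords internal
ad_no_grad <- function(code) {
  old <- ad_env$grad_on
  ad_env$grad_on <- FALSE
  on.exit(ad_env$grad_on <- old)
  force(code)
}

is_adnode <- function(x) inherits(x, "adnode")

ad_val <- function(x) if (is_adnode(x)) x$val else x

new_node <- function(val, parents = list(), backfn = NULL, leaf = FALSE) {
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$grad <- NULL
  e$parents <- parents
  e$backfn <- backfn
  e$leaf <- leaf
  ad_env$id <- ad_env$id + 1L
  e$id <- ad_env$id
  class(e) <- "adnode"
  e
}

#' Create a trainable parameter node
#' @param val Initial numeric matrix.
#' @keywords internal
ad_param <- function(val) new_node(as.matrix(val), leaf = TRUE)

.accum <- function(node, g) {
  if (!is_adnode(node)) return(invisible())
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible()
}

# generic wrapper: plain path when gradients are off or no node is involved
.ad_op <- function(val, parents, backfn) {
  if (!ad_grad_enabled() || !any(vapply(parents, is_adnode, TRUE)))
    return(val)
  new_node(val, parents = parents, backfn = backfn)
}

ad_add <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  broadcast <- is.matrix(bv) && nrow(bv) == 1L && nrow(av) > 1L
  val <- if (broadcast) sweep(av, 2, bv, "+") else av + bv
  .ad_op(val, list(a, b), function(g) {
    .accum(a, g)
    .accum(b, if (broadcast) matrix(colSums(g), 1) else g)
  })
}

ad_sub <- function(a, b) {
  val <- ad_val(a) - ad_val(b)
  .ad_op(val, list(a, b), function(g) { .accum(a, g); .accum(b, -g) })
}

ad_mul <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  .ad_op(av * bv, list(a, b), function(g) {
    .accum(a, g * bv); .accum(b, g * av)
  })
}

ad_scale <- function(a, s) {
  .ad_op(ad_val(a) * s, list(a), function(g) .accum(a, g * s))
}

ad_matmul <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  .ad_op(av %*% bv, list(a, b), function(g) {
    .accum(a, g %*% t(bv)); .accum(b, crossprod(av, g))
  })
}

ad_tanh <- function(a) {
  v <- tanh(ad_val(a))
  .ad_op(v, list(a), function(g) .accum(a, g * (1 - v * v)))
}

ad_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-ad_val(a)))
  .ad_op(v, list(a), function(g) .accum(a, g * v * (1 - v)))
}

ad_relu <- function(a) {
  av <- ad_val(a)
  v <- pmax(av, 0)
  .ad_op(v, list(a), function(g) .accum(a, g * (av > 0)))
}

# gather rows of an embedding matrix (idx 1-based); scatter-add backward
ad_rows <- function(W, idx) {
  Wv <- ad_val(W)
  v <- Wv[idx, , drop = FALSE]
  .ad_op(v, list(W), function(g) {
    gw <- matrix(0, nrow(Wv), ncol(Wv))
    gs <- rowsum(g, group = idx)
    gw[as.integer(rownames(gs)), ] <- gs
    .accum(W, gw)
  })
}

ad_cbind <- function(...) {
  args <- list(...)
  vals <- lapply(args, ad_val)
  widths <- vapply(vals, ncol, 0L)
  v <- do.call(cbind, vals)
  .ad_op(v, args, function(g) {
    off <- 0L
    for (i in seq_along(args)) {
      .accum(args[[i]], g[, off + seq_len(widths[i]), drop = FALSE])
      off <- off + widths[i]
    }
  })
}

ad_slice_cols <- function(a, cols) {
  av <- ad_val(a)
  .ad_op(av[, cols, drop = FALSE], list(a), function(g) {
    ga <- matrix(0, nrow(av), ncol(av))
    ga[, cols] <- g
    .accum(a, ga)
  })
}

ad_slice_rows <- function(a, rows) {
  av <- ad_val(a)
  .ad_op(av[rows, , drop = FALSE], list(a), function(g) {
    ga <- matrix(0, nrow(av), ncol(av))
    ga[rows, ] <- ga[rows, ] + g
    .accum(a, ga)
  })
}

ad_rbind <- function(...) {
  args <- list(...)
  vals <- lapply(args, ad_val)
  heights <- vapply(vals, nrow, 0L)
  v <- do.call(rbind, vals)
  .ad_op(v, args, function(g) {
    off <- 0L
    for (i in seq_along(args)) {
      .accum(args[[i]], g[off + seq_len(heights[i]), , drop = FALSE])
      off <- off + heights[i]
    }
  })
}

# row-wise layer normalization with gain/bias (1 x d each)
ad_layernorm <- function(a, gain, bias, eps = 1e-5) {
  av <- ad_val(a); gv <- ad_val(gain); bv <- ad_val(bias)
  d <- ncol(av)
  mu <- rowMeans(av)
  xc <- av - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  v <- sweep(sweep(xhat, 2, gv, "*"), 2, bv, "+")
  .ad_op(v, list(a, gain, bias), function(g) {
    .accum(bias, matrix(colSums(g), 1))
    .accum(gain, matrix(colSums(g * xhat), 1))
    gx <- sweep(g, 2, gv, "*")
    # d xhat / d x backward for per-row normalization
    s1 <- rowMeans(gx)
    s2 <- rowMeans(gx * xhat)
    .accum(a, inv * (gx - s1 - xhat * s2))
  })
}

# fused scaled dot-product multi-head attention over a stacked batch.
# q: (B*Lq) x d, k/v: (B*Lk) x d, d = h * dk.  mask: B x Lk logical
# (TRUE = attend); causal masks j > i (requires Lq == Lk).
ad_attention <- function(q, k, v, B, Lq, Lk, heads, mask = NULL,
                         causal = FALSE) {
  qv <- ad_val(q); kv <- ad_val(k); vv <- ad_val(v)
  d <- ncol(qv)
  stopifnot(d %% heads == 0)
  dk <- d %/% heads
  scale <- 1 / sqrt(dk)
  out <- matrix(0, nrow(qv), d)
  aw <- vector("list", B * heads)
  for (b in seq_len(B)) {
    rq <- (b - 1L) * Lq + seq_len(Lq)
    rk <- (b - 1L) * Lk + seq_len(Lk)
    keep <- if (is.null(mask)) rep(TRUE, Lk) else mask[b, ]
    pen <- ifelse(keep, 0, -1e30)
    for (h in seq_len(heads)) {
      cols <- (h - 1L) * dk + seq_len(dk)
      S <- tcrossprod(qv[rq, cols, drop = FALSE],
                      kv[rk, cols, drop = FALSE]) * scale
      S <- sweep(S, 2, pen, "+")
      if (causal && Lq == Lk) S[upper.tri(S)] <- -1e30
      S <- S - apply(S, 1, max)
      E <- exp(S)
      A <- E / rowSums(E)
      aw[[(b - 1L) * heads + h]] <- A
      out[rq, cols] <- A %*% vv[rk, cols, drop = FALSE]
    }
  }
  .ad_op(out, list(q, k, v), function(g) {
    gq <- matrix(0, nrow(qv), d)
    gk <- matrix(0, nrow(kv), d)
    gv_ <- matrix(0, nrow(vv), d)
    for (b in seq_len(B)) {
      rq <- (b - 1L) * Lq + seq_len(Lq)
      rk <- (b - 1L) * Lk + seq_len(Lk)
      for (h in seq_len(heads)) {
        cols <- (h - 1L) * dk + seq_len(dk)
        A <- aw[[(b - 1L) * heads + h]]
        go <- g[rq, cols, drop = FALSE]
        gv_[rk, cols] <- gv_[rk, cols] + crossprod(A, go)
        gA <- tcrossprod(go, vv[rk, cols, drop = FALSE])
        gS <- A * (gA - rowSums(gA * A))
        gq[rq, cols] <- gq[rq, cols] +
          gS %*% kv[rk, cols, drop = FALSE] * scale
        gk[rk, cols] <- gk[rk, cols] +
          crossprod(gS, qv[rq, cols, drop = FALSE]) * scale
      }
    }
    .accum(q, gq); .accum(k, gk); .accum(v, gv_)
  })
}

# masked mean cross-entropy over rows of a logits matrix.
# targets: 1-based column index per row; weight 0 rows are ignored.
ad_ce_loss <- function(logits, targets, weights = NULL) {
  lv <- ad_val(logits)
  n <- nrow(lv)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  mx <- apply(lv, 1, max)
  ls <- lv - mx
  lse <- log(rowSums(exp(ls)))
  logp <- ls - lse
  pick <- cbind(seq_len(n), targets)
  sumw <- sum(w)
  loss <- -sum(w * logp[pick]) / sumw
  .ad_op(matrix(loss, 1, 1), list(logits), function(g) {
    gs <- as.numeric(g)
    soft <- exp(logp)
    gl <- soft * w
    gl[pick] <- gl[pick] - w
    .accum(logits, gl * gs / sumw)
  })
}

# weighted sum of selected log-probabilities (policy-gradient objective):
# maximizes sum_i w_i * log softmax(logits)_i[target_i]; returns the
# negated objective so the optimizer minimizes as usual.
ad_pg_loss <- function(logits, targets, weights) {
  lv <- ad_val(logits)
  n <- nrow(lv)
  mx <- apply(lv, 1, max)
  ls <- lv - mx
  lse <- log(rowSums(exp(ls)))
  logp <- ls - lse
  pick <- cbind(seq_len(n), targets)
  w <- as.numeric(weights)
  loss <- -sum(w * logp[pick])
  .ad_op(matrix(loss, 1, 1), list(logits), function(g) {
    gs <- as.numeric(g)
    soft <- exp(logp)
    gl <- soft * w
    gl[pick] <- gl[pick] - w
    .accum(logits, gl * gs)
  })
}

ad_sum <- function(a) {
  av <- ad_val(a)
  .ad_op(matrix(sum(av), 1, 1), list(a), function(g)
    .accum(a, matrix(as.numeric(g), nrow(av), ncol(av))))
}

#' Run backpropagation from a scalar loss node
#' @param loss A 1 x 1 `adnode`.
#' @keywords internal
ad_backward <- function(loss) {
  stopifnot(is_adnode(loss))
  # iterative topological sort (post-order DFS)
  topo <- vector("list", 0)
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = loss, stage = 1L))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- fr$node
    key <- as.character(node$id)
    if (fr$stage == 1L) {
      if (exists(key, envir = seen, inherits = FALSE)) next
      assign(key, TRUE, envir = seen)
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents)
        if (is_adnode(p) && !exists(as.character(p$id), envir = seen,
                                    inherits = FALSE))
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
    } else {
      topo[[length(topo) + 1L]] <- node
    }
  }
  loss$grad <- matrix(1, 1, 1)
  for (i in rev(seq_along(topo))) {
    node <- topo[[i]]
    if (!is.null(node$backfn) && !is.null(node$grad)) node$backfn(node$grad)
  }
  invisible(loss)
}

# ---------------------------------------------------------------------------
# Adam optimizer over a flat named list of parameter nodes

adam_init <- function(params) {
  list(m = lapply(params, function(p) p$val * 0),
       v = lapply(params, function(p) p$val * 0),
       t = 0L)
}

#' One Adam update with global-norm gradient clipping
#' @keywords internal
adam_step <- function(opt, params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = 5) {
  gn2 <- 0
  for (p in params) if (!is.null(p$grad)) gn2 <- gn2 + sum(p$grad^2)
  gn <- sqrt(gn2)
  sc <- if (is.finite(gn) && gn > clip) clip / gn else 1
  if (!is.finite(gn)) {
    for (p in params) p$grad <- NULL
    warning("non-finite gradient; update skipped")
    return(opt)
  }
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- if (is.null(p$grad)) p$val * 0 else p$grad * sc
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    p$val <- p$val - lr * (opt$m[[nm]] / bc1) /
      (sqrt(opt$v[[nm]] / bc2) + eps)
    p$grad <- NULL
  }
  opt
}

ad_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}
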