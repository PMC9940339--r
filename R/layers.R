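# Neural building blocks: positional encodings, attention primitives and
# the transformer / LSTM / GRU layer constructors shared by the four
# generator architectures.

#' Sinusoidal positional encoding
#'
#' `PE(p, 2i) = sin(p / 10000^(2i/d_m))`, `PE(p, 2i+1) = cos(p / 10000^(2i/d_m))`
#' (dimensions 0-based).  Values are bounded by 1 in absolute value.
#'
#' @param p Non-negative integer position(s); vectorized.
#' @param d_m Embedding dimension.
#' @return A `length(p)` x `d_m` matrix (a vector's worth per position).
#' @export
#' @examples positional_encoding(0, 8)  # zeros and ones
positional_encoding <- function(p, d_m) {
  stopifnot(all(p >= 0), d_m >= 1)
  i2 <- 2 * (seq_len(ceiling(d_m / 2)) - 1)        # 0, 2, 4, ...
  denom <- 10000^(i2 / d_m)
  out <- matrix(0, length(p), d_m)
  ang <- outer(p, 1 / denom)
  out[, seq(1, d_m, by = 2)] <- sin(ang)
  if (d_m > 1) {
    odd <- seq(2, d_m, by = 2)
    out[, odd] <- cos(ang[, seq_along(odd), drop = FALSE])
  }
  out
}

#' Scaled dot-product attention
#'
#' `Attention(Q, K, V) = softmax(Q K' / sqrt(d_k)) V`.  Each output row is
#' a convex combination of the rows of `V`.
#'
#' @param Q Queries, n_q x d_k.
#' @param K Keys, n_k x d_k.
#' @param V Values, n_k x d_v.
#' @return n_q x d_v matrix.
#' @export
scaled_dot_attention <- function(Q, K, V) {
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V))
  S <- tcrossprod(Q, K) / sqrt(ncol(Q))
  S <- S - apply(S, 1, max)
  E <- exp(S)
  (E / rowSums(E)) %*% V
}

#' Multi-head attention
#'
#' `MultiHead(Q,K,V) = Concat(head_1, ..., head_h) W_O` with
#' `head_i = Attention(Q W_i^Q, K W_i^K, V W_i^V)`.
#'
#' @param Q,K,V Input matrices (rows = positions, columns = model dim).
#' @param proj Projection list: `Wq`, `Wk`, `Wv` are lists of per-head
#'   matrices (d_m x d_k), `Wo` is (h * d_v) x d_m.
#' @return n_q x d_m matrix.
#' @export
multi_head_attention <- function(Q, K, V, proj) {
  h <- length(proj$Wq)
  heads <- lapply(seq_len(h), function(i)
    scaled_dot_attention(Q %*% proj$Wq[[i]], K %*% proj$Wk[[i]],
                         V %*% proj$Wv[[i]]))
  do.call(cbind, heads) %*% proj$Wo
}

# ---------------------------------------------------------------------------
# parameter initialisation helpers

.init_mat <- function(nin, nout) {
  ad_param(matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))),
                  nin, nout))
}
.init_zero <- function(nout) ad_param(matrix(0, 1, nout))
.init_one <- function(nout) ad_param(matrix(1, 1, nout))

# transformer stack parameters -----------------------------------------------

transformer_params <- function(prefix, n_layers, d, dff, cross = FALSE) {
  p <- list()
  for (l in seq_len(n_layers)) {
    nm <- function(s) sprintf("%s_l%d_%s", prefix, l, s)
    p[[nm("Wq")]] <- .init_mat(d, d)
    p[[nm("Wk")]] <- .init_mat(d, d)
    p[[nm("Wv")]] <- .init_mat(d, d)
    p[[nm("Wo")]] <- .init_mat(d, d)
    p[[nm("ln1_g")]] <- .init_one(d); p[[nm("ln1_b")]] <- .init_zero(d)
    if (cross) {
      p[[nm("Xq")]] <- .init_mat(d, d)
      p[[nm("Xk")]] <- .init_mat(d, d)
      p[[nm("Xv")]] <- .init_mat(d, d)
      p[[nm("Xo")]] <- .init_mat(d, d)
      p[[nm("ln2_g")]] <- .init_one(d); p[[nm("ln2_b")]] <- .init_zero(d)
    }
    p[[nm("W1")]] <- .init_mat(d, dff); p[[nm("b1")]] <- .init_zero(dff)
    p[[nm("W2")]] <- .init_mat(dff, d); p[[nm("b2")]] <- .init_zero(d)
    p[[nm("ln3_g")]] <- .init_one(d); p[[nm("ln3_b")]] <- .init_zero(d)
  }
  p
}

# one post-LN transformer layer; x is (B*L) x d stacked
.tf_layer <- function(x, p, prefix, l, B, L, heads, mask = NULL,
                      causal = FALSE, enc = NULL, Lk = NULL,
                      enc_mask = NULL) {
  nm <- function(s) sprintf("%s_l%d_%s", prefix, l, s)
  q <- ad_matmul(x, p[[nm("Wq")]])
  k <- ad_matmul(x, p[[nm("Wk")]])
  v <- ad_matmul(x, p[[nm("Wv")]])
  a <- ad_attention(q, k, v, B, L, L, heads, mask = mask, causal = causal)
  a <- ad_matmul(a, p[[nm("Wo")]])
  x <- ad_layernorm(ad_add(x, a), p[[nm("ln1_g")]], p[[nm("ln1_b")]])
  if (!is.null(enc)) {
    q2 <- ad_matmul(x, p[[nm("Xq")]])
    k2 <- ad_matmul(enc, p[[nm("Xk")]])
    v2 <- ad_matmul(enc, p[[nm("Xv")]])
    a2 <- ad_attention(q2, k2, v2, B, L, Lk, heads, mask = enc_mask)
    a2 <- ad_matmul(a2, p[[nm("Xo")]])
    x <- ad_layernorm(ad_add(x, a2), p[[nm("ln2_g")]], p[[nm("ln2_b")]])
  }
  f <- ad_add(ad_matmul(ad_relu(ad_add(ad_matmul(x, p[[nm("W1")]]),
                                       p[[nm("b1")]])),
                        p[[nm("W2")]]), p[[nm("b2")]])
  ad_layernorm(ad_add(x, f), p[[nm("ln3_g")]], p[[nm("ln3_b")]])
}

tf_encode <- function(x, p, n_layers, B, L, heads, mask) {
  for (l in seq_len(n_layers))
    x <- .tf_layer(x, p, "enc", l, B, L, heads, mask = mask)
  x
}

tf_decode <- function(x, enc, p, n_layers, B, Lq, Lk, heads, enc_mask) {
  for (l in seq_len(n_layers))
    x <- .tf_layer(x, p, "dec", l, B, Lq, heads, causal = TRUE,
                   enc = enc, Lk = Lk, enc_mask = enc_mask)
  x
}

# LSTM ------------------------------------------------------------------------

lstm_params <- function(prefix, n_layers, d_in, d_h) {
  p <- list()
  for (l in seq_len(n_layers)) {
    nin <- if (l == 1) d_in else d_h
    nm <- function(s) sprintf("%s_l%d_%s", prefix, l, s)
    p[[nm("Wx")]] <- .init_mat(nin, 4 * d_h)
    p[[nm("Wh")]] <- .init_mat(d_h, 4 * d_h)
    p[[nm("b")]] <- .init_zero(4 * d_h)
  }
  p
}

# single LSTM step; h/c are B x H
.lstm_step <- function(x, h, c, p, prefix, l) {
  nm <- function(s) sprintf("%s_l%d_%s", prefix, l, s)
  H <- ncol(ad_val(h))
  z <- ad_add(ad_add(ad_matmul(x, p[[nm("Wx")]]),
                     ad_matmul(h, p[[nm("Wh")]])), p[[nm("b")]])
  i <- ad_sigmoid(ad_slice_cols(z, seq_len(H)))
  f <- ad_sigmoid(ad_slice_cols(z, H + seq_len(H)))
  g <- ad_tanh(ad_slice_cols(z, 2 * H + seq_len(H)))
  o <- ad_sigmoid(ad_slice_cols(z, 3 * H + seq_len(H)))
  c2 <- ad_add(ad_mul(f, c), ad_mul(i, g))
  h2 <- ad_mul(o, ad_tanh(c2))
  list(h = h2, c = c2)
}

# run a stacked LSTM over a list of per-step inputs; returns outputs per
# step (top layer) and final states
lstm_run <- function(xs, p, prefix, n_layers, d_h, B, init = NULL) {
  hs <- if (is.null(init)) rep(list(matrix(0, B, d_h)), n_layers) else init$h
  cs <- if (is.null(init)) rep(list(matrix(0, B, d_h)), n_layers) else init$c
  outs <- vector("list", length(xs))
  for (t in seq_along(xs)) {
    x <- xs[[t]]
    for (l in seq_len(n_layers)) {
      st <- .lstm_step(x, hs[[l]], cs[[l]], p, prefix, l)
      hs[[l]] <- st$h; cs[[l]] <- st$c
      x <- st$h
    }
    outs[[t]] <- x
  }
  list(outputs = outs, h = hs, c = cs)
}

# GRU (used by the graph decoder's per-step decision head) -------------------

gru_params <- function(prefix, d_in, d_h) {
  p <- list()
  p[[paste0(prefix, "_Wxz")]] <- .init_mat(d_in, d_h)
  p[[paste0(prefix, "_Whz")]] <- .init_mat(d_h, d_h)
  p[[paste0(prefix, "_bz")]] <- .init_zero(d_h)
  p[[paste0(prefix, "_Wxr")]] <- .init_mat(d_in, d_h)
  p[[paste0(prefix, "_Whr")]] <- .init_mat(d_h, d_h)
  p[[paste0(prefix, "_br")]] <- .init_zero(d_h)
  p[[paste0(prefix, "_Wxn")]] <- .init_mat(d_in, d_h)
  p[[paste0(prefix, "_Whn")]] <- .init_mat(d_h, d_h)
  p[[paste0(prefix, "_bn")]] <- .init_zero(d_h)
  p
}

gru_step <- function(x, h, p, prefix) {
  g <- function(s) p[[paste0(prefix, "_", s)]]
  z <- ad_sigmoid(ad_add(ad_add(ad_matmul(x, g("Wxz")),
                                ad_matmul(h, g("Whz"))), g("bz")))
  r <- ad_sigmoid(ad_add(ad_add(ad_matmul(x, g("Wxr")),
                                ad_matmul(h, g("Whr"))), g("br")))
  n <- ad_tanh(ad_add(ad_add(ad_matmul(x, g("Wxn")),
                             ad_matmul(ad_mul(r, h), g("Whn"))), g("bn")))
  one_minus_z <- ad_scale(ad_sub(z, matrix(1, nrow(ad_val(z)),
                                           ncol(ad_val(z)))), -1)
  ad_add(ad_mul(one_minus_z, n), ad_mul(z, h))
}
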