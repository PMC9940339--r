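# Attention primitives, positional encodings and the autodiff engine.

test_that("positional encoding follows the sine/cosine formula", {
  pe0 <- positional_encoding(0, 8)
  expect_equal(as.numeric(pe0[seq(1, 8, 2)]), rep(0, 4))   # sin(0)
  expect_equal(as.numeric(pe0[seq(2, 8, 2)]), rep(1, 4))   # cos(0)
  for (p in c(1, 7, 123)) {
    pe <- positional_encoding(p, 16)
    expect_equal(pe[1], sin(p))          # denominator 10000^0 = 1
    expect_equal(pe[2], cos(p))
    expect_equal(pe[3], sin(p / 10000^(2 / 16)))
  }
  set.seed(2)
  for (i in 1:5) {
    p <- sample(0:500, 1); d <- 2 * sample(2:40, 1)
    expect_lte(max(abs(positional_encoding(p, d))), 1)
  }
})

test_that("scaled dot-product attention matches its definition", {
  set.seed(3)
  # single key: output is the single value row regardless of Q
  Q <- matrix(rnorm(6), 3, 2); K <- matrix(rnorm(2), 1, 2)
  V <- matrix(c(5, -1), 1, 2)
  out <- scaled_dot_attention(Q, K, V)
  expect_equal(out, matrix(rep(c(5, -1), each = 3), 3, 2))
  # identical keys: output is the column mean of V
  K2 <- matrix(rep(c(1, 2), each = 4), 4, 2)
  V2 <- matrix(rnorm(8), 4, 2)
  out2 <- scaled_dot_attention(Q, K2, V2)
  expect_equal(out2, matrix(rep(colMeans(V2), each = 3), 3, 2))
  # direct computation oracle + convex-combination property
  K3 <- matrix(rnorm(8), 4, 2); V3 <- matrix(rnorm(12), 4, 3)
  S <- Q %*% t(K3) / sqrt(2)
  W <- exp(S) / rowSums(exp(S))
  expect_equal(scaled_dot_attention(Q, K3, V3), W %*% V3)
  expect_true(all(out2 >= min(V2) - 1e-12 & out2 <= max(V2) + 1e-12))
})

test_that("multi-head attention reduces and stays permutation-equivariant", {
  set.seed(4)
  d <- 4
  Q <- matrix(rnorm(3 * d), 3, d); K <- matrix(rnorm(5 * d), 5, d)
  V <- matrix(rnorm(5 * d), 5, d)
  ident <- list(Wq = list(diag(d)), Wk = list(diag(d)), Wv = list(diag(d)),
                Wo = diag(d))
  expect_equal(multi_head_attention(Q, K, V, ident),
               scaled_dot_attention(Q, K, V))
  proj <- list(Wq = lapply(1:2, function(i) matrix(rnorm(d * 2), d, 2)),
               Wk = lapply(1:2, function(i) matrix(rnorm(d * 2), d, 2)),
               Wv = lapply(1:2, function(i) matrix(rnorm(d * 2), d, 2)),
               Wo = matrix(rnorm(4 * d), 4, d))
  out <- multi_head_attention(Q, K, V, proj)
  expect_equal(dim(out), c(3, d))
  perm <- sample(5)
  expect_equal(multi_head_attention(Q, K[perm, ], V[perm, ], proj), out)
})

test_that("autodiff gradients match finite differences", {
  set.seed(1)
  B <- 2; Lq <- 3; d <- 4
  params <- list(
    Wq = ad_param(matrix(rnorm(d * d) * 0.3, d)),
    Wk = ad_param(matrix(rnorm(d * d) * 0.3, d)),
    Wv = ad_param(matrix(rnorm(d * d) * 0.3, d)),
    g = ad_param(matrix(runif(d) + 0.5, 1)),
    b = ad_param(matrix(rnorm(d) * 0.1, 1)),
    E = ad_param(matrix(rnorm(5 * d) * 0.3, 5)))
  idx <- sample(5, B * Lq, replace = TRUE)
  tgt <- sample(d, B * Lq, replace = TRUE)
  wts <- c(1, 1, 0, 1, 1, 1)
  mask <- matrix(c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE), B, Lq, byrow = TRUE)
  f <- function() {
    x <- ad_rows(params$E, idx)
    q <- ad_matmul(x, params$Wq)
    k <- ad_matmul(x, params$Wk)
    v <- ad_matmul(x, params$Wv)
    a <- ad_attention(q, k, v, B, Lq, Lq, 2, mask = mask, causal = TRUE)
    x2 <- ad_layernorm(ad_add(a, x), params$g, params$b)
    ad_ce_loss(ad_relu(x2), tgt, wts)
  }
  ad_backward(f())
  grads <- lapply(params, function(p) p$grad)
  eps <- 1e-5
  for (nm in names(params)) {
    p <- params[[nm]]
    ng <- array(0, dim(p$val))
    for (i in seq_along(p$val)) {
      v0 <- p$val[i]
      p$val[i] <- v0 + eps; lp <- ad_val(ad_no_grad(f()))[1]
      p$val[i] <- v0 - eps; lm <- ad_val(ad_no_grad(f()))[1]
      p$val[i] <- v0
      ng[i] <- (lp - lm) / (2 * eps)
    }
    expect_lt(max(abs(grads[[nm]] - ng)) / max(1e-8, max(abs(ng))), 1e-5)
  }
})

test_that("GRU and LSTM cells backpropagate correctly", {
  set.seed(6)
  B <- 3; din <- 3; H <- 4
  params <- c(gru_params("g", din, H), lstm_params("l", 1, din, H))
  x <- matrix(rnorm(B * din), B, din)
  h0 <- matrix(rnorm(B * H) * 0.2, B, H)
  tgt <- sample(H, 2 * B, replace = TRUE)
  f <- function() {
    hg <- gru_step(x, h0, params, "g")
    st <- scafgen:::.lstm_step(x, h0, h0 * 0, params, "l", 1)
    ad_ce_loss(ad_rbind(hg, st$h), tgt)
  }
  ad_backward(f())
  eps <- 1e-5
  for (nm in c("g_Wxn", "g_Whz", "l_l1_Wx", "l_l1_Wh")) {
    p <- params[[nm]]
    g <- p$grad
    i <- which.max(abs(g))
    v0 <- p$val[i]
    p$val[i] <- v0 + eps; lp <- ad_val(ad_no_grad(f()))[1]
    p$val[i] <- v0 - eps; lm <- ad_val(ad_no_grad(f()))[1]
    p$val[i] <- v0
    expect_equal(g[i], (lp - lm) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("policy-gradient loss weights log-probabilities by reward", {
  set.seed(7)
  W <- ad_param(matrix(c(0.3, -0.2), 1, 2))
  tgt <- c(1L)
  # zero reward: zero gradient
  loss0 <- ad_pg_loss(ad_matmul(matrix(1, 1, 1), W), tgt, 0)
  ad_backward(loss0)
  expect_equal(W$grad, matrix(0, 1, 2))
  W$grad <- NULL
  # reward 1: gradient of -log softmax
  loss1 <- ad_pg_loss(ad_matmul(matrix(1, 1, 1), W), tgt, 1)
  ad_backward(loss1)
  p <- exp(c(0.3, -0.2)) / sum(exp(c(0.3, -0.2)))
  expect_equal(as.numeric(W$grad), c(p[1] - 1, p[2]), tolerance = 1e-10)
})
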