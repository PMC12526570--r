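# Attention primitives: scaled dot-product, multi-head, residual layer norm,
# channel attention, gated fusion.

test_that("attention weights are row-stochastic and reduce correctly", {
  set.seed(1)
  Q <- matrix(rnorm(12), 3); K <- matrix(rnorm(20), 5); V <- matrix(rnorm(10), 5)
  att <- scaled_dot_attention(Q, K, V)
  expect_equal(rowSums(att$weights), rep(1, 3), tolerance = 1e-6)
  expect_equal(dim(att$output), c(3L, 2L))

  # identical keys: uniform weights, output = column means of V
  Kc <- matrix(rep(rnorm(4), each = 5), 5)
  att2 <- scaled_dot_attention(Q, Kc, V)
  for (i in 1:3) expect_equal(att2$output[i, ], colMeans(V), tolerance = 1e-9)

  expect_error(scaled_dot_attention(Q, matrix(0, 5, 3), V), class = "shape_error")
  expect_error(scaled_dot_attention(Q, K, V[1:4, ]), class = "shape_error")
})

test_that("two-key softmax gives sigmoid(1) when scores differ by sqrt(d_k)", {
  dk <- 9
  q <- matrix(1, 1, dk)
  # construct keys with scores s and s + sqrt(dk) after 1/sqrt(dk) scaling
  k1 <- matrix(0.5, 1, dk)
  k2 <- matrix(0.5 + 1 / sqrt(dk), 1, dk)
  att <- scaled_dot_attention(q, rbind(k1, k2), diag(2))
  expect_equal(att$weights[1, 2], 0.7310585786, tolerance = 1e-9)
})

test_that("scaled dot-product attention matches the two-loop oracle", {
  set.seed(2)
  for (i in 1:20) {
    Q <- matrix(rnorm(16), 4); K <- matrix(rnorm(16), 4); V <- matrix(rnorm(16), 4)
    mine <- scaled_dot_attention(Q, K, V)
    ora <- naive_attention(Q, K, V)
    expect_lt(max(abs(mine$output - ora$output)), 1e-8)
    expect_lt(max(abs(mine$weights - ora$weights)), 1e-8)
  }
})

test_that("multi-head attention reduces to single-head and is key-permutation invariant", {
  set.seed(3)
  d <- 6
  Q <- matrix(rnorm(4 * d), 4); K <- matrix(rnorm(5 * d), 5); V <- matrix(rnorm(5 * d), 5)
  w <- mha_weights(d, seed = 4)
  cfg1 <- attention_config(d, heads = 1, dropout = 0)

  # H = 1: equals Eq.1 on the projected inputs followed by W^O
  out <- multi_head_attention(Q, K, V, w, cfg1)
  Qp <- Q %*% w$Wq; Kp <- K %*% w$Wk; Vp <- V %*% w$Wv
  ref <- scaled_dot_attention(Qp, Kp, Vp)$output %*% w$Wo
  expect_equal(out, ref, tolerance = 1e-10)

  # identity projections: equals Eq.1 directly
  wi <- list(Wq = diag(d), bq = numeric(d), Wk = diag(d), bk = numeric(d),
             Wv = diag(d), bv = numeric(d), Wo = diag(d), bo = numeric(d))
  expect_equal(multi_head_attention(Q, K, V, wi, cfg1),
               scaled_dot_attention(Q, K, V)$output, tolerance = 1e-6)

  # joint permutation of key/value rows leaves the output unchanged
  cfg2 <- attention_config(d, heads = 2, dropout = 0)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(multi_head_attention(Q, K, V, w, cfg2),
               multi_head_attention(Q, K[perm, ], V[perm, ], w, cfg2),
               tolerance = 1e-12)
  # and permuting queries permutes the output rows (equivariance)
  qp <- c(4, 1, 3, 2)
  expect_equal(multi_head_attention(Q, K, V, w, cfg2)[qp, ],
               multi_head_attention(Q[qp, ], K, V, w, cfg2),
               tolerance = 1e-12)

  expect_error(attention_config(6, heads = 4), class = "config_error")
})

test_that("residual layer norm normalizes rows and ignores input scale", {
  set.seed(4)
  X <- matrix(rnorm(20), 4)
  S <- matrix(rnorm(20), 4)
  y <- residual_layernorm(X, S)
  expect_equal(rowMeans(y), rep(0, 4), tolerance = 1e-6)
  expect_equal(apply(y, 1, function(r) mean(r^2)), rep(1, 4), tolerance = 1e-3)

  # degenerate sum: LayerNorm(0) is defined and returns the affine bias
  beta <- rnorm(5)
  y0 <- residual_layernorm(X, -X, beta = beta)
  for (i in 1:4) expect_equal(y0[i, ], beta, tolerance = 1e-9)

  # scale invariance: c * (X + S) normalizes to the same rows (up to the
  # epsilon inside the normalizer)
  for (c0 in c(0.1, 3, 100))
    expect_equal(residual_layernorm(c0 * X, c0 * S), y, tolerance = 1e-3)

  expect_error(residual_layernorm(X, S[1:2, ]), class = "shape_error")
})

test_that("channel attention gates channels through a sigmoid bottleneck", {
  set.seed(5)
  f <- matrix(rnorm(80), 10)  # 10 time steps x 8 channels
  w <- channel_attention_weights(8, r = 4, seed = 6)
  ca <- channel_attention(f, w, r = 4)
  expect_true(all(ca$gates > 0 & ca$gates < 1))
  for (j in 1:8)
    expect_lte(sqrt(sum(ca$output[, j]^2)), sqrt(sum(f[, j]^2)))

  expect_equal(channel_attention(matrix(0, 10, 8), w, 4)$output,
               matrix(0, 10, 8))

  # zeroed expansion weights with bias b: every channel scaled by sigmoid(b)
  b <- 0.7
  w0 <- list(W1 = w$W1, b1 = w$b1, W2 = matrix(0, 2, 8), b2 = rep(b, 8))
  ca0 <- channel_attention(f, w0, 4)
  expect_equal(ca0$output, f * (1 / (1 + exp(-b))), tolerance = 1e-12)

  expect_error(channel_attention(f, w, r = 20), class = "config_error")
})

test_that("gated fusion is an elementwise convex combination", {
  set.seed(7)
  a <- matrix(rnorm(24), 4); b <- matrix(rnorm(24), 4)
  gp <- list(W = matrix(rnorm(72, 0, 0.4), 12, 6), b = numeric(6))
  g <- gated_fusion(a, b, gp)
  expect_true(all(g$output >= pmin(a, b) - 1e-12 & g$output <= pmax(a, b) + 1e-12))

  # saturated gate (huge positive bias, zero weights) returns a
  gsat <- gated_fusion(a, b, list(W = matrix(0, 12, 6), b = rep(50, 6)))
  expect_equal(gsat$output, a, tolerance = 1e-12)

  # fixed point: a == b
  expect_equal(gated_fusion(a, a, gp)$output, a, tolerance = 1e-12)

  expect_error(gated_fusion(a, b[1:2, ], gp), class = "shape_error")
})
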