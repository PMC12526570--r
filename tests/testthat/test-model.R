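# Network assembly: residual blocks, branch shapes, determinism, parameter
# counting, and a finite-difference check of the full backward pass.

test_that("residual blocks preserve length and default to the skip path", {
  set.seed(1)
  x <- matrix(rnorm(64), 16)  # 16 time steps x 4 channels
  bp <- ppgfusion:::resblock_weights(4L, 4L, 3L)
  y <- residual_block(x, bp)
  expect_equal(dim(y), dim(x))

  # zeroed convolutions + identity shortcut: y = ReLU(BN(0) + x) = ReLU(x)
  bp0 <- bp
  bp0$conv1$W[] <- 0; bp0$conv1$b[] <- 0
  bp0$conv2$W[] <- 0; bp0$conv2$b[] <- 0
  expect_equal(residual_block(x, bp0), pmax(x, 0), tolerance = 1e-12)

  # channel-changing block uses a 1x1 projection shortcut
  bp2 <- ppgfusion:::resblock_weights(4L, 6L, 3L)
  expect_equal(dim(residual_block(x, bp2)), c(16L, 6L))
})

test_that("gradient flows through the residual block to its input", {
  set.seed(2)
  x <- matrix(rnorm(16 * 2), 16)
  bp <- ppgfusion:::resblock_weights(2L, 2L, 3L)
  f <- function(m) sum(residual_block(m, bp)^2)
  eps <- 1e-5
  sens <- 0
  for (i in c(1, 9, 25)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    sens <- max(sens, abs(f(xp) - f(xm)) / (2 * eps))
  }
  expect_gt(sens, 0)
})

test_that("causal stem convolution does not look ahead", {
  set.seed(3)
  cfg <- tiny_model_config()
  ini <- init_fusion_dma(cfg, seed = 1)
  x <- array(rnorm(100), c(1, 100, 1))
  y1 <- ppgfusion:::conv1d_fwd(x, ini$params$time$stem$W,
                               ini$params$time$stem$b, "causal")$y
  x2 <- x; x2[1, 100, 1] <- x2[1, 100, 1] + 10
  y2 <- ppgfusion:::conv1d_fwd(x2, ini$params$time$stem$W,
                               ini$params$time$stem$b, "causal")$y
  expect_equal(y1[1, 1:99, ], y2[1, 1:99, ])
  expect_false(isTRUE(all.equal(y1[1, 100, ], y2[1, 100, ])))
})

test_that("branch outputs have the documented shapes and are deterministic", {
  cfg <- tiny_model_config()
  ini <- init_fusion_dma(cfg, seed = 2)
  b <- tiny_batch(cfg, n = 3, seed = 4)

  tf <- time_branch(b$x, cfg, ini$params, ini$state)
  expect_equal(dim(tf), c(3L, cfg$seq_len, 2L * cfg$bilstm_units[2]))
  expect_equal(tf, time_branch(b$x, cfg, ini$params, ini$state))
  # identical windows give identical features
  xx <- rbind(b$x[1, ], b$x[1, ])
  t2 <- time_branch(xx, cfg, ini$params, ini$state)
  expect_equal(t2[1, , ], t2[2, , ])

  ff <- freq_branch(b$ssm, cfg, ini$params)
  expect_equal(dim(ff), c(3L, cfg$n_bands, 2L * cfg$freq_bilstm_units))
  # zero SSM inputs: features depend only on the encoding and biases
  z <- array(0, c(2, cfg$n_bands, cfg$n_bands))
  fz <- freq_branch(z, cfg, ini$params)
  expect_equal(fz[1, , ], fz[2, , ])

  # joint row/column permutation of the SSM permutes pre-encoding tokens
  s1 <- b$ssm[1, , ]
  perm <- c(3, 1, 4, 2)
  expect_equal(s1[perm, perm], (s1[perm, ])[, perm])

  probs <- fusion_head(tf, ff, cfg, ini$params)
  expect_equal(rowSums(probs), rep(1, 3), tolerance = 1e-6)
  expect_true(all(probs >= 0))
  p2 <- fusion_head(t2, freq_branch(array(rep(b$ssm[1, , ], 2),
                                          c(cfg$n_bands, cfg$n_bands, 2)) |>
                                      aperm(c(3, 1, 2)),
                                    cfg, ini$params), cfg, ini$params)
  expect_equal(p2[1, ], p2[2, ])
})

test_that("parameter counting is exact", {
  # a bare dense layer 8 -> 4 with bias holds 36 scalars
  toy <- list(head = list(fc = list(W = matrix(0, 8, 4), b = numeric(4))))
  expect_identical(sum(vapply(ppgfusion:::flatten_params(toy), length, 0L)), 36L)

  # hand-computed total for the tiny configuration
  cfg <- tiny_model_config()
  conv <- function(cin, k, cout) cin * k * cout + cout
  bn <- function(c) 2 * c
  dense <- function(a, b) a * b + b
  mha <- function(dq, dkv, d) dense(dq, d) + 2 * dense(dkv, d) + dense(d, d)
  bilstm <- function(cin, h) 2 * (4 * ((cin + h) * h + h))
  expected <-
    conv(1, 3, 4) +                                  # stem
    (conv(4, 3, 8) + bn(8) + conv(8, 3, 8) + bn(8) + conv(4, 1, 8)) +  # rb1
    (conv(8, 3, 8) + bn(8) + conv(8, 3, 8) + bn(8)) +                  # rb2
    dense(1, 8) + mha(8, 8, 8) + bn(8) +             # CSIA value path + MHA + LN
    bilstm(8, 4) + bilstm(8, 3) +                    # time BiLSTMs
    (3 * 4 + 4) + mha(4, 4, 4) + bn(4) +             # pe conv, MHSA, LN1
    dense(4, 8) + dense(8, 4) + bn(4) +              # FFN + LN2
    dense(4, 4) + bilstm(4, 3) +                     # 1x1 conv + freq BiLSTM
    dense(6, 8) + dense(6, 8) +                      # projections
    2 * (dense(8, 4) + dense(4, 8)) +                # channel attention x2
    mha(8, 8, 8) + bn(8) + dense(16, 8) +            # cross + LN + fuse proj
    mha(8, 8, 8) + bn(8) + dense(16, 8) +            # self + LN + gate
    dense(cfg$seq_len * 8, 8) + dense(8, 4)          # head
  expect_identical(count_parameters(cfg), as.integer(expected))

  # full-size configuration stays within 10% of the 1.46 M budget
  n <- count_parameters(model_config("paper"))
  expect_gte(n, 1.31e6)
  expect_lte(n, 1.61e6)
})

test_that("analytic gradients match finite differences on a tiny model", {
  cfg <- tiny_model_config(dropout = 0)
  ini <- init_fusion_dma(cfg, seed = 3)
  params <- ini$params; state <- ini$state
  b <- tiny_batch(cfg, n = 3, seed = 42)
  targets <- ppgfusion:::one_hot(b$y[1:3], 4)
  w <- c(1.4, 0.8, 1.0, 0.8)

  loss_fn <- function(p) {
    fw <- ppgfusion:::fdma_forward(p, state, b$x, b$ssm, cfg, train = TRUE)
    kl_loss(targets, fw$probs, w)
  }
  fw <- ppgfusion:::fdma_forward(params, state, b$x, b$ssm, cfg, train = TRUE)
  dlog <- ppgfusion:::kl_grad_logits(fw$probs, targets, w)
  grads <- ppgfusion:::fdma_backward(dlog, fw$cache, params, cfg)

  fl_p <- ppgfusion:::flatten_params(params)
  fl_g <- ppgfusion:::flatten_params(grads)
  expect_setequal(names(fl_g), names(fl_p))

  set_leaf <- function(p, path, val) {
    parts <- strsplit(path, ".", fixed = TRUE)[[1]]
    expr <- Reduce(function(acc, nm) call("[[", acc, nm), parts, quote(p))
    eval(call("<-", expr, quote(val)))
    p
  }
  eps <- 1e-5
  set.seed(9)
  for (nm in sample(names(fl_g), 40)) {
    arr <- fl_p[[nm]]
    i <- sample(length(arr), 1)
    a1 <- arr; a1[i] <- a1[i] + eps
    a2 <- arr; a2[i] <- a2[i] - eps
    num <- (loss_fn(set_leaf(params, nm, a1)) -
              loss_fn(set_leaf(params, nm, a2))) / (2 * eps)
    ana <- fl_g[[nm]][i]
    if (abs(num) > 1e-6 || abs(ana) > 1e-6)
      expect_lt(abs(num - ana) / max(abs(num), abs(ana)), 1e-4,
                label = sprintf("gradient of %s[%d] (num %.3e ana %.3e)",
                                nm, i, num, ana))
  }
})

test_that("inference is deterministic and simplex-valued for any finite input", {
  cfg <- tiny_model_config(dropout = 0.3)   # dropout must be inert in inference
  ini <- init_fusion_dma(cfg, seed = 5)
  b <- tiny_batch(cfg, n = 4, seed = 6)
  p1 <- ppgfusion:::fdma_forward(ini$params, ini$state, b$x, b$ssm, cfg,
                                 train = FALSE)$probs
  p2 <- ppgfusion:::fdma_forward(ini$params, ini$state, b$x, b$ssm, cfg,
                                 train = FALSE)$probs
  expect_identical(p1, p2)
  expect_equal(rowSums(p1), rep(1, 4), tolerance = 1e-9)
  # extreme but finite inputs still land on the simplex
  xb <- b$x * 1e3
  p3 <- ppgfusion:::fdma_forward(ini$params, ini$state, xb, b$ssm, cfg,
                                 train = FALSE)$probs
  expect_true(all(is.finite(p3)))
  expect_equal(rowSums(p3), rep(1, 4), tolerance = 1e-9)
})
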