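# Network configuration, initialization and the full forward pass of the
# dual-branch time/frequency attention classifier.

fdma_presets <- list(
  # Full-size widths: ~1.44 M trainable parameters at 250 Hz / 10 s windows,
  # matching the ~1.46 M budget of the reference architecture.
  paper = list(stem_filters = 32L, stem_kernel = 7L, pool_size = 20L,
               res_filters = 64L, res_kernel = 5L, csia_heads = 4L,
               bilstm_units = c(64L, 32L),
               n_bands = 32L, freq_heads = 4L, ffn_width = 64L, use_ffn = TRUE,
               conv1x1_filters = 32L, freq_bilstm_units = 32L,
               common_dim = 64L, channel_reduction = 4L, fusion_heads = 4L,
               fc1_units = 144L),
  # Reduced widths for desk-scale experiments and tests.
  small = list(stem_filters = 8L, stem_kernel = 7L, pool_size = 50L,
               res_filters = 16L, res_kernel = 5L, csia_heads = 2L,
               bilstm_units = c(16L, 8L),
               n_bands = 8L, freq_heads = 2L, ffn_width = 16L, use_ffn = TRUE,
               conv1x1_filters = 8L, freq_bilstm_units = 8L,
               common_dim = 16L, channel_reduction = 4L, fusion_heads = 2L,
               fc1_units = 32L))

#' Model configuration
#'
#' All architectural widths of the dual-branch network. The `"paper"` preset
#' reproduces the full-scale architecture (~1.44 million trainable
#' parameters); `"small"` is a reduced-width variant for CPU-scale
#' experiments. Any field can be overridden by name. Structural ablations
#' are expressed with `use_residual`, `use_csia`, `use_cross_attention`,
#' `branches`.
#'
#' @param preset `"paper"` or `"small"`.
#' @param fs Sampling rate the model expects (Hz).
#' @param window_s Input window length in seconds.
#' @param n_classes Output classes (4).
#' @param dropout Dropout rate for attention weights, BiLSTM outputs, the
#'   fusion gate and the first dense layer.
#' @param welch A [welch_config()] used to derive self-similarity inputs.
#' @param use_residual,use_csia,use_cross_attention Ablation switches.
#' @param branches `"both"`, `"time"` or `"freq"`.
#' @param ... Width overrides (see `ppgfusion:::fdma_presets$paper` for names).
#' @return An object of class `model_config`.
#' @export
model_config <- function(preset = c("paper", "small"), fs = 250, window_s = 10,
                         n_classes = 4, dropout = 0.2, welch = welch_config(),
                         use_residual = TRUE, use_csia = TRUE,
                         use_cross_attention = TRUE, branches = "both", ...) {
  preset <- match.arg(preset)
  cfg <- fdma_presets[[preset]]
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    abort(paste("unknown model_config fields:", paste(bad, collapse = ", ")),
          "config_error")
  cfg[names(over)] <- over
  cfg$fs <- fs; cfg$window_s <- window_s
  cfg$n_classes <- as.integer(n_classes)
  cfg$dropout <- dropout
  cfg$welch <- welch
  cfg$use_residual <- isTRUE(use_residual)
  cfg$use_csia <- isTRUE(use_csia)
  cfg$use_cross_attention <- isTRUE(use_cross_attention)
  cfg$branches <- match.arg(branches, c("both", "time", "freq"))
  cfg$window_samples <- as.integer(round(window_s * fs))
  if (cfg$window_samples %% cfg$pool_size != 0)
    abort("window length in samples must be divisible by pool_size", "config_error")
  cfg$seq_len <- cfg$window_samples %/% cfg$pool_size
  if (cfg$res_filters %% cfg$csia_heads != 0 ||
      cfg$n_bands %% cfg$freq_heads != 0 ||
      cfg$common_dim %% cfg$fusion_heads != 0)
    abort("channel widths must be divisible by their head counts", "config_error")
  if (cfg$channel_reduction > cfg$common_dim)
    abort("channel_reduction exceeds common_dim", "config_error")
  if (cfg$n_bands < 2) abort("need at least 2 frequency bands", "config_error")
  if (cfg$branches == "both" && cfg$seq_len < cfg$n_bands)
    abort("time sequence must be at least as long as the band count", "config_error")
  structure(cfg, class = "model_config")
}

he_conv <- function(cin, k, cout) {
  array(stats::rnorm(cin * k * cout, 0, sqrt(2 / (cin * k))), c(cin, k, cout))
}

lstm_weights <- function(cin, h) {
  list(Wx = he_matrix(cin, 4 * h), Wh = he_matrix(h, 4 * h), b = numeric(4 * h))
}

bilstm_weights <- function(cin, h) list(fwd = lstm_weights(cin, h),
                                        bwd = lstm_weights(cin, h))

mha_par <- function(d_q, d_kv, d_model) {
  list(Wq = he_matrix(d_q, d_model), bq = numeric(d_model),
       Wk = he_matrix(d_kv, d_model), bk = numeric(d_model),
       Wv = he_matrix(d_kv, d_model), bv = numeric(d_model),
       Wo = he_matrix(d_model, d_model), bo = numeric(d_model))
}

bn_par <- function(c) list(gamma = rep(1, c), beta = numeric(c))
ln_par <- function(c) list(gamma = rep(1, c), beta = numeric(c))
bn_state <- function(c) list(mean = numeric(c), var = rep(1, c))

resblock_weights <- function(cin, cout, k) {
  p <- list(conv1 = list(W = he_conv(cin, k, cout), b = numeric(cout)),
            bn1 = bn_par(cout),
            conv2 = list(W = he_conv(cout, k, cout), b = numeric(cout)),
            bn2 = bn_par(cout))
  if (cin != cout)
    p$sc <- list(W = he_conv(cin, 1L, cout), b = numeric(cout))
  p
}

#' Initialize network parameters
#'
#' He-normal initialization for all weight tensors (fan-in scaled), zero
#' biases, unit batch-norm/layer-norm gains and a zero-initialized
#' positional-encoding adjustment kernel (residual identity at start).
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed.
#' @return List with `params` (trainable tensors) and `state`
#'   (batch-norm running statistics).
#' @export
init_fusion_dma <- function(cfg, seed = 1L) {
  with_seed(seed, {
    F0 <- cfg$stem_filters; F1 <- cfg$res_filters
    B <- cfg$n_bands; C <- cfg$common_dim
    params <- list(
      time = list(
        stem = list(W = he_conv(1L, cfg$stem_kernel, F0), b = numeric(F0)),
        rb1 = resblock_weights(F0, F1, cfg$res_kernel),
        rb2 = resblock_weights(F1, F1, cfg$res_kernel),
        vproj = list(W = he_matrix(1L, F1), b = numeric(F1)),
        csia = mha_par(F1, F1, F1),
        ln = ln_par(F1),
        lstm1 = bilstm_weights(F1, cfg$bilstm_units[1]),
        lstm2 = bilstm_weights(2L * cfg$bilstm_units[1], cfg$bilstm_units[2])),
      freq = list(
        pe_conv = list(kernel = matrix(0, 3, B), bias = numeric(B)),
        mhsa = mha_par(B, B, B),
        ln1 = ln_par(B),
        ffn = if (cfg$use_ffn) list(W1 = he_matrix(B, cfg$ffn_width),
                                    b1 = numeric(cfg$ffn_width),
                                    W2 = he_matrix(cfg$ffn_width, B),
                                    b2 = numeric(B)),
        ln2 = if (cfg$use_ffn) ln_par(B),
        conv1x1 = list(W = he_matrix(B, cfg$conv1x1_filters),
                       b = numeric(cfg$conv1x1_filters)),
        lstm = bilstm_weights(cfg$conv1x1_filters, cfg$freq_bilstm_units)),
      fusion = list(
        proj_t = list(W = he_matrix(2L * cfg$bilstm_units[2], C), b = numeric(C)),
        proj_f = list(W = he_matrix(2L * cfg$freq_bilstm_units, C), b = numeric(C)),
        ca_t = channel_attention_par(C, cfg$channel_reduction),
        ca_f = channel_attention_par(C, cfg$channel_reduction),
        cross = mha_par(C, C, C),
        ln_cross = ln_par(C),
        fuse_proj = list(W = he_matrix(2L * C, C), b = numeric(C)),
        self = mha_par(C, C, C),
        ln_self = ln_par(C),
        gate = list(W = he_matrix(2L * C, C), b = numeric(C))),
      head = list(
        fc1 = list(W = he_matrix(head_in_dim(cfg), cfg$fc1_units),
                   b = numeric(cfg$fc1_units)),
        fc2 = list(W = he_matrix(cfg$fc1_units, cfg$n_classes),
                   b = numeric(cfg$n_classes))))
    if (cfg$branches == "time") params$freq <- NULL
    if (cfg$branches == "freq") params$time <- NULL
    if (cfg$branches != "both") params$fusion <- NULL
    state <- list(time = list(rb1 = list(bn1 = bn_state(F1), bn2 = bn_state(F1)),
                              rb2 = list(bn1 = bn_state(F1), bn2 = bn_state(F1))))
    if (cfg$branches == "freq") state <- list()
    list(params = params, state = state)
  })
}

channel_attention_par <- function(channels, r) {
  hid <- max(1L, channels %/% r)
  list(W1 = he_matrix(channels, hid), b1 = numeric(hid),
       W2 = he_matrix(hid, channels), b2 = numeric(channels))
}

# Flattened input width of the classifier head for a given configuration.
head_in_dim <- function(cfg) {
  switch(cfg$branches,
         both = cfg$seq_len * cfg$common_dim,
         time = cfg$seq_len * 2L * cfg$bilstm_units[2],
         freq = cfg$n_bands * 2L * cfg$freq_bilstm_units)
}

#' Count trainable parameters
#'
#' The exact number of trainable scalars the configuration instantiates
#' (batch-norm running statistics are buffers, not parameters).
#'
#' @param cfg A [model_config()].
#' @return Integer count.
#' @export
#' @examples
#' count_parameters(model_config("small"))
count_parameters <- function(cfg) {
  p <- init_fusion_dma(cfg, seed = 1L)$params
  sum(vapply(flatten_params(p), length, 0L))
}

# Flatten a nested parameter list into a named list of leaf arrays.
flatten_params <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.null(v)) next
    key <- if (prefix == "") nm else paste(prefix, nm, sep = ".")
    if (is.list(v)) out <- c(out, flatten_params(v, key))
    else out[[key]] <- v
  }
  out
}

# ---- forward pass -----------------------------------------------------------

resblock_fwd <- function(x, p, st, train, use_residual = TRUE) {
  c1 <- conv1d_fwd(x, p$conv1$W, p$conv1$b, "same")
  b1 <- batchnorm_fwd(c1$y, p$bn1$gamma, p$bn1$beta, st$bn1, train)
  r1 <- relu_fwd(b1$y)
  c2 <- conv1d_fwd(r1$y, p$conv2$W, p$conv2$b, "same")
  b2 <- batchnorm_fwd(c2$y, p$bn2$gamma, p$bn2$beta, st$bn2, train)
  sc <- if (!is.null(p$sc)) conv1d_fwd(x, p$sc$W, p$sc$b, "same") else NULL
  short <- if (!use_residual) 0 else if (is.null(sc)) x else sc$y
  out <- relu_fwd(b2$y + short)
  list(y = out$y, c1 = c1, b1 = b1, r1 = r1, c2 = c2, b2 = b2, sc = sc,
       out = out, use_residual = use_residual,
       state = list(bn1 = b1$running, bn2 = b2$running))
}

resblock_bwd <- function(dy, cache, p) {
  g_out <- relu_bwd(dy, cache$out)
  gb2 <- batchnorm_bwd(g_out, cache$b2, p$bn2$gamma)
  gc2 <- conv1d_bwd(gb2$dx, cache$c2, p$conv2$W)
  gr1 <- relu_bwd(gc2$dx, cache$r1)
  gb1 <- batchnorm_bwd(gr1, cache$b1, p$bn1$gamma)
  gc1 <- conv1d_bwd(gb1$dx, cache$c1, p$conv1$W)
  dx <- gc1$dx
  grads <- list(conv1 = list(W = gc1$dW, b = gc1$db),
                bn1 = list(gamma = gb1$dgamma, beta = gb1$dbeta),
                conv2 = list(W = gc2$dW, b = gc2$db),
                bn2 = list(gamma = gb2$dgamma, beta = gb2$dbeta))
  if (cache$use_residual) {
    if (!is.null(cache$sc)) {
      gsc <- conv1d_bwd(g_out, cache$sc, p$sc$W)
      grads$sc <- list(W = gsc$dW, b = gsc$db)
      dx <- dx + gsc$dx
    } else {
      dx <- dx + g_out
    }
  }
  list(dx = dx, grads = grads)
}

time_branch_fwd <- function(x, params, state, cfg, train) {
  N <- nrow(x)
  xt <- array(x, c(N, ncol(x), 1L))
  p <- params$time
  stem <- conv1d_fwd(xt, p$stem$W, p$stem$b, "causal")
  sr <- relu_fwd(stem$y)
  mp <- maxpool_fwd(sr$y, cfg$pool_size)
  rb1 <- resblock_fwd(mp$y, p$rb1, state$time$rb1, train, cfg$use_residual)
  sd1 <- spatial_dropout_fwd(rb1$y, cfg$dropout, train)
  rb2 <- resblock_fwd(sd1$y, p$rb2, state$time$rb2, train, cfg$use_residual)
  sd2 <- spatial_dropout_fwd(rb2$y, cfg$dropout, train)
  if (cfg$use_csia) {
    # value path: the raw window, segment-averaged to the residual-feature
    # length ("adaptively reconstructed input"), then linearly projected
    P <- t(adaptive_pool_matrix(ncol(x), cfg$seq_len))
    vseq <- posmap_fwd(xt, P)
    vp <- dense_fwd(vseq$y, p$vproj$W, p$vproj$b)
    csia <- mha3_fwd(sd2$y, sd2$y, vp$y, p$csia, cfg$csia_heads,
                     cfg$dropout, train)
    rl <- resln_fwd(sd2$y, csia$y, p$ln$gamma, p$ln$beta)
    seq_in <- rl$y
  } else {
    P <- NULL; vseq <- NULL; vp <- NULL; csia <- NULL; rl <- NULL
    seq_in <- sd2$y
  }
  bl1 <- bilstm_fwd(seq_in, p$lstm1)
  d1 <- dropout_fwd(bl1$y, cfg$dropout, train)
  bl2 <- bilstm_fwd(d1$y, p$lstm2)
  d2 <- dropout_fwd(bl2$y, cfg$dropout, train)
  list(y = d2$y,
       cache = list(stem = stem, sr = sr, mp = mp, rb1 = rb1, sd1 = sd1,
                    rb2 = rb2, sd2 = sd2, P = P, vseq = vseq, vp = vp,
                    csia = csia, rl = rl, bl1 = bl1, d1 = d1, bl2 = bl2,
                    d2 = d2, xdim = dim(xt)),
       state = list(rb1 = rb1$state, rb2 = rb2$state))
}

time_branch_bwd <- function(dy, cache, params, cfg) {
  p <- params$time
  g <- list()
  d <- dropout_bwd(dy, cache$d2)
  gb2 <- bilstm_bwd(d, cache$bl2, p$lstm2)
  g$lstm2 <- gb2$grads
  d <- dropout_bwd(gb2$dx, cache$d1)
  gb1 <- bilstm_bwd(d, cache$bl1, p$lstm1)
  g$lstm1 <- gb1$grads
  dxt_extra <- NULL
  if (cfg$use_csia) {
    grl <- resln_bwd(gb1$dx, cache$rl, p$ln$gamma)
    g$ln <- list(gamma = grl$dgamma, beta = grl$dbeta)
    gm <- mha3_bwd(grl$dsub, cache$csia, p$csia)
    g$csia <- gm$grads
    d_sd2 <- grl$dx + gm$dq + gm$dk
    gvp <- dense_bwd(gm$dv, cache$vp, p$vproj$W)
    g$vproj <- list(W = gvp$dW, b = gvp$db)
    dxt_extra <- posmap_bwd(gvp$dx, cache$vseq, cache$P)
  } else {
    d_sd2 <- gb1$dx
  }
  d_sd2 <- dropout_bwd(d_sd2, cache$sd2)
  grb2 <- resblock_bwd(d_sd2, cache$rb2, p$rb2)
  g$rb2 <- grb2$grads
  d_sd1 <- dropout_bwd(grb2$dx, cache$sd1)
  grb1 <- resblock_bwd(d_sd1, cache$rb1, p$rb1)
  g$rb1 <- grb1$grads
  dmp <- maxpool_bwd(grb1$dx, cache$mp)
  dsr <- relu_bwd(dmp, cache$sr)
  gstem <- conv1d_bwd(dsr, cache$stem, p$stem$W)
  g$stem <- list(W = gstem$dW, b = gstem$db)
  dxt <- gstem$dx
  if (!is.null(dxt_extra)) dxt <- dxt + dxt_extra
  list(dx = matrix(dxt, dim(dxt)[1], dim(dxt)[2]), grads = g)
}

freq_branch_fwd <- function(ssm, params, cfg, train) {
  p <- params$freq
  B <- cfg$n_bands
  N <- dim(ssm)[1]
  pe <- positional_encoding(B, B)
  pec <- depthwise_conv_fwd(array(pe, c(1L, B, B)), p$pe_conv$kernel,
                            p$pe_conv$bias)
  peadj <- pe + matrix(pec$y, B, B)
  tok <- ssm
  for (n in seq_len(N)) tok[n, , ] <- tok[n, , ] + peadj
  mhsa <- mha3_fwd(tok, tok, tok, p$mhsa, cfg$freq_heads, cfg$dropout, train)
  r1 <- resln_fwd(tok, mhsa$y, p$ln1$gamma, p$ln1$beta)
  if (cfg$use_ffn) {
    f1 <- dense_fwd(r1$y, p$ffn$W1, p$ffn$b1)
    fr <- relu_fwd(f1$y)
    f2 <- dense_fwd(fr$y, p$ffn$W2, p$ffn$b2)
    r2 <- resln_fwd(r1$y, f2$y, p$ln2$gamma, p$ln2$beta)
    enc <- r2$y
  } else {
    f1 <- fr <- f2 <- r2 <- NULL
    enc <- r1$y
  }
  cv <- dense_fwd(enc, p$conv1x1$W, p$conv1x1$b)   # 1x1 conv = per-token dense
  bl <- bilstm_fwd(cv$y, p$lstm)
  dd <- dropout_fwd(bl$y, cfg$dropout, train)
  list(y = dd$y,
       cache = list(pe = pe, pec = pec, mhsa = mhsa, r1 = r1, f1 = f1,
                    fr = fr, f2 = f2, r2 = r2, cv = cv, bl = bl, dd = dd,
                    N = N))
}

freq_branch_bwd <- function(dy, cache, params, cfg) {
  p <- params$freq
  g <- list()
  d <- dropout_bwd(dy, cache$dd)
  gbl <- bilstm_bwd(d, cache$bl, p$lstm)
  g$lstm <- gbl$grads
  gcv <- dense_bwd(gbl$dx, cache$cv, p$conv1x1$W)
  g$conv1x1 <- list(W = gcv$dW, b = gcv$db)
  if (cfg$use_ffn) {
    gr2 <- resln_bwd(gcv$dx, cache$r2, p$ln2$gamma)
    g$ln2 <- list(gamma = gr2$dgamma, beta = gr2$dbeta)
    gf2 <- dense_bwd(gr2$dsub, cache$f2, p$ffn$W2)
    gfr <- relu_bwd(gf2$dx, cache$fr)
    gf1 <- dense_bwd(gfr, cache$f1, p$ffn$W1)
    g$ffn <- list(W1 = gf1$dW, b1 = gf1$db, W2 = gf2$dW, b2 = gf2$db)
    dr1 <- gr2$dx + gf1$dx
  } else {
    dr1 <- gcv$dx
  }
  gr1 <- resln_bwd(dr1, cache$r1, p$ln1$gamma)
  g$ln1 <- list(gamma = gr1$dgamma, beta = gr1$dbeta)
  gm <- mha3_bwd(gr1$dsub, cache$mhsa, p$mhsa)
  g$mhsa <- gm$grads
  dtok <- gr1$dx + gm$dq + gm$dk + gm$dv
  # the positional adjustment is shared across the batch: sum over items
  B <- cfg$n_bands
  dpe_sum <- matrix(0, B, B)
  for (n in seq_len(cache$N)) dpe_sum <- dpe_sum + matrix(dtok[n, , ], B)
  gpec <- depthwise_conv_bwd(array(dpe_sum, c(1L, B, B)), cache$pec,
                             params$freq$pe_conv$kernel)
  g$pe_conv <- list(kernel = gpec$dkernel, bias = gpec$dbias)
  list(dssm = dtok, grads = g)
}

cat3 <- function(a, b) {
  d <- dim(a)
  array(c(a, b), c(d[1], d[2], d[3] + dim(b)[3]))
}

fusion_fwd <- function(tf, ff, params, cfg, train) {
  p <- params$fusion
  C <- cfg$common_dim
  pt <- dense_fwd(tf, p$proj_t$W, p$proj_t$b)
  pf <- dense_fwd(ff, p$proj_f$W, p$proj_f$b)
  Lt <- dim(pt$y)[2]; Lf <- dim(pf$y)[2]
  # align the shorter sequence: integer-factor linear upsampling, then
  # zero-padding to the exact target length
  M <- align_matrix(Lf, Lt)
  fa <- posmap_fwd(pf$y, M)
  ca_t <- chattn_fwd(pt$y, p$ca_t)
  ca_f <- chattn_fwd(fa$y, p$ca_f)
  if (cfg$use_cross_attention) {
    cross <- mha3_fwd(ca_f$y, ca_t$y, ca_t$y, p$cross, cfg$fusion_heads,
                      cfg$dropout, train)
    crl <- resln_fwd(ca_f$y, cross$y, p$ln_cross$gamma, p$ln_cross$beta)
    a_path <- crl$y
  } else {
    cross <- crl <- NULL
    a_path <- ca_f$y
  }
  u <- cat3(ca_t$y, ca_f$y)
  fp <- dense_fwd(u, p$fuse_proj$W, p$fuse_proj$b)
  self <- mha3_fwd(fp$y, fp$y, fp$y, p$self, cfg$fusion_heads, cfg$dropout, train)
  srl <- resln_fwd(fp$y, self$y, p$ln_self$gamma, p$ln_self$beta)
  gt <- gate_fwd(a_path, srl$y, p$gate)
  gd <- dropout_fwd(gt$y, cfg$dropout, train)
  list(y = gd$y,
       cache = list(pt = pt, pf = pf, M = M, fa = fa, ca_t = ca_t,
                    ca_f = ca_f, cross = cross, crl = crl, u = u, fp = fp,
                    self = self, srl = srl, gt = gt, gd = gd, C = C))
}

fusion_bwd <- function(dy, cache, params, cfg) {
  p <- params$fusion
  g <- list()
  d <- dropout_bwd(dy, cache$gd)
  gg <- gate_bwd(d, cache$gt, p$gate)
  g$gate <- gg$grads
  gsrl <- resln_bwd(gg$db, cache$srl, p$ln_self$gamma)
  g$ln_self <- list(gamma = gsrl$dgamma, beta = gsrl$dbeta)
  gself <- mha3_bwd(gsrl$dsub, cache$self, p$self)
  g$self <- gself$grads
  dfp <- gsrl$dx + gself$dq + gself$dk + gself$dv
  gfp <- dense_bwd(dfp, cache$fp, p$fuse_proj$W)
  g$fuse_proj <- list(W = gfp$dW, b = gfp$db)
  C <- cache$C
  d_cat <- gfp$dx
  d_ca_t <- d_cat[, , 1:C, drop = FALSE]
  d_ca_f <- d_cat[, , (C + 1):(2 * C), drop = FALSE]
  if (cfg$use_cross_attention) {
    gcrl <- resln_bwd(gg$da, cache$crl, p$ln_cross$gamma)
    g$ln_cross <- list(gamma = gcrl$dgamma, beta = gcrl$dbeta)
    gcross <- mha3_bwd(gcrl$dsub, cache$cross, p$cross)
    g$cross <- gcross$grads
    d_ca_f <- d_ca_f + gcrl$dx + gcross$dq
    d_ca_t <- d_ca_t + gcross$dk + gcross$dv
  } else {
    d_ca_f <- d_ca_f + gg$da
  }
  gcaf <- chattn_bwd(d_ca_f, cache$ca_f, p$ca_f)
  g$ca_f <- gcaf$grads
  gcat <- chattn_bwd(d_ca_t, cache$ca_t, p$ca_t)
  g$ca_t <- gcat$grads
  dfa <- posmap_bwd(gcaf$dx, cache$fa, cache$M)
  gpf <- dense_bwd(dfa, cache$pf, p$proj_f$W)
  g$proj_f <- list(W = gpf$dW, b = gpf$db)
  gpt <- dense_bwd(gcat$dx, cache$pt, p$proj_t$W)
  g$proj_t <- list(W = gpt$dW, b = gpt$db)
  list(dtf = gpt$dx, dff = gpf$dx, grads = g)
}

# Upsample-then-pad alignment operator mapping length Lf to length Lt.
align_matrix <- function(Lf, Lt) {
  if (Lf == Lt) return(diag(Lt))
  if (Lf > Lt) abort("frequency sequence longer than time sequence", "config_error")
  fac <- max(1L, Lt %/% Lf)
  U <- upsample_matrix(Lf, Lf * fac)
  rbind(U, matrix(0, Lt - Lf * fac, Lf))
}

fdma_forward <- function(params, state, x, ssm, cfg, train = FALSE) {
  N <- nrow(x)
  tb <- fb <- NULL
  new_state <- state
  if (cfg$branches != "freq") {
    tb <- time_branch_fwd(x, params, state, cfg, train)
    new_state$time <- tb$state
  }
  if (cfg$branches != "time")
    fb <- freq_branch_fwd(ssm, params, cfg, train)
  feat <- switch(cfg$branches,
    both = { fu <- fusion_fwd(tb$y, fb$y, params, cfg, train); fu },
    time = list(y = tb$y, cache = NULL),
    freq = list(y = fb$y, cache = NULL))
  flat <- matrix(feat$y, N, prod(dim(feat$y)[-1]))
  fc1 <- dense_fwd(flat, params$head$fc1$W, params$head$fc1$b)
  fr <- relu_fwd(fc1$y)
  fd <- dropout_fwd(fr$y, cfg$dropout, train)
  fc2 <- dense_fwd(fd$y, params$head$fc2$W, params$head$fc2$b)
  probs <- softmax_rows(fc2$y)
  list(probs = probs, logits = fc2$y,
       cache = list(tb = tb, fb = fb, fu = feat, flat_dim = dim(feat$y),
                    fc1 = fc1, fr = fr, fd = fd, fc2 = fc2),
       state = new_state)
}

fdma_backward <- function(dlogits, cache, params, cfg) {
  g <- list()
  gfc2 <- dense_bwd(dlogits, cache$fc2, params$head$fc2$W)
  g$head$fc2 <- list(W = gfc2$dW, b = gfc2$db)
  dfd <- dropout_bwd(gfc2$dx, cache$fd)
  dfr <- relu_bwd(dfd, cache$fr)
  gfc1 <- dense_bwd(dfr, cache$fc1, params$head$fc1$W)
  g$head$fc1 <- list(W = gfc1$dW, b = gfc1$db)
  dfeat <- array(gfc1$dx, cache$flat_dim)
  if (cfg$branches == "both") {
    gfu <- fusion_bwd(dfeat, cache$fu$cache, params, cfg)
    g$fusion <- gfu$grads
    dtf <- gfu$dtf; dff <- gfu$dff
  } else if (cfg$branches == "time") {
    dtf <- dfeat; dff <- NULL
  } else {
    dtf <- NULL; dff <- dfeat
  }
  if (!is.null(dtf)) {
    gtb <- time_branch_bwd(dtf, cache$tb$cache, params, cfg)
    g$time <- gtb$grads
  }
  if (!is.null(dff)) {
    gfb <- freq_branch_bwd(dff, cache$fb$cache, params, cfg)
    g$freq <- gfb$grads
  }
  g
}

# ---- exported module surfaces ----------------------------------------------

#' Residual convolution block
#'
#' Two same-padded 1-D convolutions with batch normalization and ReLU, a
#' shortcut (identity, or a 1x1 convolution when channel counts differ) and
#' a final ReLU: `y = ReLU(BN(conv2(ReLU(BN(conv1(x))))) + shortcut(x))`.
#'
#' @param x `time x channels` matrix.
#' @param block_params Weights as produced by `resblock_weights` (internal);
#'   see [init_fusion_dma()].
#' @param state Batch-norm running statistics (defaults to fresh zeros/ones;
#'   inference mode).
#' @param train Use batch statistics (TRUE) or running statistics (FALSE).
#' @return `time x channels_out` matrix, same number of rows as `x`.
#' @export
residual_block <- function(x, block_params, state = NULL, train = FALSE) {
  cout <- length(block_params$bn1$gamma)
  if (is.null(state)) state <- list(bn1 = bn_state(cout), bn2 = bn_state(cout))
  x3 <- array(x, c(1L, nrow(x), ncol(x)))
  out <- resblock_fwd(x3, block_params, state, train)
  matrix(out$y, nrow(x), cout)
}

#' Time-domain feature branch
#'
#' Causal convolution stem, max pooling, two residual blocks, cross-scale
#' interactive attention (deep residual features as query/key, the
#' segment-averaged and projected raw window as value, wrapped in residual
#' layer normalization) and two bidirectional LSTM layers returning full
#' sequences.
#'
#' @param x Window matrix `[n, window_samples]` (a single window may be
#'   given as a vector).
#' @param cfg A [model_config()].
#' @param params,state From [init_fusion_dma()] or a fitted model.
#' @return Array `[n, seq_len, 2 * bilstm_units[2]]`.
#' @export
time_branch <- function(x, cfg, params, state = NULL) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  if (is.null(state)) state <- init_fusion_dma(cfg, 1L)$state
  time_branch_fwd(x, params, state, cfg, train = FALSE)$y
}

#' Frequency-domain feature branch
#'
#' Treats the rows of each self-similarity matrix as the token sequence,
#' adds the convolution-adjusted sinusoidal positional encoding, applies a
#' Transformer encoder block (multi-head self-attention with residual layer
#' normalization, optional feed-forward sublayer), a 1x1 channel projection
#' and a bidirectional LSTM over the band axis.
#'
#' @param ssm `[n, B, B]` array (or a single `B x B` matrix).
#' @inheritParams time_branch
#' @return Array `[n, B, 2 * freq_bilstm_units]`.
#' @export
freq_branch <- function(ssm, cfg, params) {
  if (length(dim(ssm)) == 2L) ssm <- array(ssm, c(1L, dim(ssm)))
  freq_branch_fwd(ssm, params, cfg, train = FALSE)$y
}

#' Fusion head
#'
#' Projects both branch outputs to a common width, aligns lengths
#' (upsampling plus zero-padding of the shorter sequence), applies
#' per-branch channel attention, cross-attention (frequency features as
#' query, time features as key/value), self-attention over the fused
#' sequence, a learnable gate between the two attention pathways, and the
#' flatten/dense/softmax classifier.
#'
#' @param time_features,freq_features Branch outputs (arrays; a single
#'   window's `L x C` matrices are also accepted).
#' @inheritParams time_branch
#' @return Matrix of class probabilities (rows sum to 1).
#' @export
fusion_head <- function(time_features, freq_features, cfg, params) {
  if (length(dim(time_features)) == 2L)
    time_features <- array(time_features, c(1L, dim(time_features)))
  if (length(dim(freq_features)) == 2L)
    freq_features <- array(freq_features, c(1L, dim(freq_features)))
  if (!all(is.finite(time_features)) || !all(is.finite(freq_features)))
    abort("branch features must be finite", "numeric_error")
  fu <- fusion_fwd(time_features, freq_features, params, cfg, train = FALSE)
  N <- dim(fu$y)[1]
  flat <- matrix(fu$y, N, prod(dim(fu$y)[-1]))
  fc1 <- dense_fwd(flat, params$head$fc1$W, params$head$fc1$b)
  fc2 <- dense_fwd(pmax(fc1$y, 0), params$head$fc2$W, params$head$fc2$b)
  softmax_rows(fc2$y)
}
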