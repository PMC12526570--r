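# Low-level network primitives. Every *_fwd returns list(y, ...cache...) and
# has a matching *_bwd that consumes the cache and the upstream gradient.
# Activations are [N, L, C] arrays (batch, position, channel); because R
# stores the batch index fastest, matrix(x, N*L, C) is a free reshape with
# rows indexed by (batch, position) pairs.

mat3 <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3])
  x
}
arr3 <- function(m, n, l) array(m, c(n, l, ncol(m)))

# ---- dense -----------------------------------------------------------------

dense_fwd <- function(x, W, b) {
  if (length(dim(x)) == 3L) {
    d <- dim(x)
    y <- arr3(sweep_add(mat3(x) %*% W, b), d[1], d[2])
  } else {
    y <- sweep_add(x %*% W, b)
  }
  list(y = y, x = x)
}

dense_bwd <- function(dy, cache, W) {
  x <- cache$x
  if (length(dim(x)) == 3L) {
    d <- dim(x)
    dy2 <- mat3(dy); x2 <- mat3(x)
    list(dx = arr3(dy2 %*% t(W), d[1], d[2]),
         dW = crossprod(x2, dy2), db = colSums(dy2))
  } else {
    list(dx = dy %*% t(W), dW = crossprod(x, dy), db = colSums(dy))
  }
}

# add a row vector to every row (cheaper than sweep())
sweep_add <- function(m, b) m + rep(b, each = nrow(m))

# ---- 1D convolution --------------------------------------------------------

# W has dim (Cin, k, Cout); padding "causal" (left only) or "same".
conv1d_fwd <- function(x, W, b, pad = "same") {
  d <- dim(x); N <- d[1]; L <- d[2]; Cin <- d[3]
  k <- dim(W)[2]; Cout <- dim(W)[3]
  padl <- if (pad == "causal") k - 1L else (k - 1L) %/% 2L
  padr <- k - 1L - padl
  xp <- array(0, c(N, L + k - 1L, Cin))
  xp[, (padl + 1):(padl + L), ] <- x
  xcol <- matrix(0, N * L, k * Cin)
  for (j in seq_len(k))
    xcol[, ((j - 1) * Cin + 1):(j * Cin)] <- mat3(xp[, j:(j + L - 1L), , drop = FALSE])
  Wm <- matrix(W, k * Cin, Cout)
  y <- arr3(sweep_add(xcol %*% Wm, b), N, L)
  list(y = y, xcol = xcol, dims = c(N, L, Cin, k, Cout), padl = padl)
}

conv1d_bwd <- function(dy, cache, W) {
  dm <- cache$dims; N <- dm[1]; L <- dm[2]; Cin <- dm[3]; k <- dm[4]; Cout <- dm[5]
  Wm <- matrix(W, k * Cin, Cout)
  dy2 <- mat3(dy)
  dxcol <- dy2 %*% t(Wm)
  dW <- array(crossprod(cache$xcol, dy2), dim(W))
  db <- colSums(dy2)
  dxp <- array(0, c(N, L + k - 1L, Cin))
  for (j in seq_len(k)) {
    blk <- arr3(dxcol[, ((j - 1) * Cin + 1):(j * Cin), drop = FALSE], N, L)
    dxp[, j:(j + L - 1L), ] <- dxp[, j:(j + L - 1L), , drop = FALSE] + blk
  }
  list(dx = dxp[, (cache$padl + 1):(cache$padl + L), , drop = FALSE],
       dW = dW, db = db)
}

# Depthwise conv (kernel [k, C], same padding) used by the positional-encoding
# adjustment module.
depthwise_conv_fwd <- function(x, kernel, bias) {
  d <- dim(x); N <- d[1]; L <- d[2]; C <- d[3]
  k <- nrow(kernel)
  padl <- (k - 1L) %/% 2L
  xp <- array(0, c(N, L + k - 1L, C))
  xp[, (padl + 1):(padl + L), ] <- x
  y2 <- matrix(rep(bias, each = N * L), N * L, C)
  for (j in seq_len(k))
    y2 <- y2 + mat3(xp[, j:(j + L - 1L), , drop = FALSE]) *
      rep(kernel[j, ], each = N * L)
  list(y = arr3(y2, N, L), xp = xp, dims = d, k = k, padl = padl)
}

depthwise_conv_bwd <- function(dy, cache, kernel) {
  d <- cache$dims; N <- d[1]; L <- d[2]; C <- d[3]
  k <- cache$k
  dy2 <- mat3(dy)
  dker <- matrix(0, k, C)
  dxp <- array(0, dim(cache$xp))
  for (j in seq_len(k)) {
    xs <- mat3(cache$xp[, j:(j + L - 1L), , drop = FALSE])
    dker[j, ] <- colSums(dy2 * xs)
    dxp[, j:(j + L - 1L), ] <- dxp[, j:(j + L - 1L), , drop = FALSE] +
      arr3(dy2 * rep(kernel[j, ], each = N * L), N, L)
  }
  list(dx = dxp[, (cache$padl + 1):(cache$padl + L), , drop = FALSE],
       dkernel = dker, dbias = colSums(dy2))
}

# ---- pooling ---------------------------------------------------------------

maxpool_fwd <- function(x, p) {
  d <- dim(x); N <- d[1]; L <- d[2]; C <- d[3]
  if (L %% p != 0) abort("sequence length not divisible by pool size", "config_error")
  Lp <- L %/% p
  y <- array(-Inf, c(N, Lp, C))
  arg <- array(1L, c(N, Lp, C))
  for (j in seq_len(p)) {
    s <- x[, seq.int(j, L, by = p), , drop = FALSE]
    m <- s > y
    y[m] <- s[m]
    arg[m] <- j
  }
  list(y = y, arg = arg, dims = d, p = p)
}

maxpool_bwd <- function(dy, cache) {
  d <- cache$dims; p <- cache$p
  dx <- array(0, d)
  for (j in seq_len(p)) {
    m <- cache$arg == j
    sl <- array(0, dim(dy))
    sl[m] <- dy[m]
    dx[, seq.int(j, d[2], by = p), ] <- sl
  }
  dx
}

# Average-pool an [N, L, 1] signal to Lout positions via a fixed projection
# matrix (segment boundaries floor/ceil as in adaptive pooling).
adaptive_pool_matrix <- function(L, Lout) {
  P <- matrix(0, L, Lout)
  for (i in seq_len(Lout)) {
    a <- floor((i - 1) * L / Lout) + 1L
    b <- ceiling(i * L / Lout)
    P[a:b, i] <- 1 / (b - a + 1L)
  }
  P
}

# Linear-interpolation upsampling matrix (align-corners) from Lin to Lout.
upsample_matrix <- function(Lin, Lout) {
  U <- matrix(0, Lout, Lin)
  if (Lin == 1L) { U[, 1] <- 1; return(U) }
  for (i in seq_len(Lout)) {
    src <- (i - 1) * (Lin - 1) / (Lout - 1) + 1
    l <- floor(src); fr <- src - l
    if (l >= Lin) { U[i, Lin] <- 1 } else {
      U[i, l] <- 1 - fr
      U[i, l + 1] <- fr
    }
  }
  U
}

# Apply a fixed [Lout x Lin] matrix along the position axis.
posmap_fwd <- function(x, M) {
  d <- dim(x); N <- d[1]
  y <- array(0, c(N, nrow(M), d[3]))
  for (n in seq_len(N)) y[n, , ] <- M %*% x[n, , ]
  list(y = y, dims = d)
}

posmap_bwd <- function(dy, cache, M) {
  d <- cache$dims
  dx <- array(0, d)
  for (n in seq_len(d[1])) dx[n, , ] <- t(M) %*% dy[n, , ]
  dx
}

# ---- normalization ---------------------------------------------------------

batchnorm_fwd <- function(x, gamma, beta, running, train, momentum = 0.9,
                          eps = 1e-5) {
  d <- dim(x)
  m <- mat3(x)
  if (train) {
    mu <- colMeans(m)
    v <- colMeans(m^2) - mu^2
    running$mean <- momentum * running$mean + (1 - momentum) * mu
    running$var <- momentum * running$var + (1 - momentum) * v
  } else {
    mu <- running$mean; v <- running$var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (m - rep(mu, each = nrow(m))) * rep(inv, each = nrow(m))
  y <- arr3(xhat * rep(gamma, each = nrow(m)) + rep(beta, each = nrow(m)), d[1], d[2])
  list(y = y, xhat = xhat, inv = inv, dims = d, running = running, train = train)
}

batchnorm_bwd <- function(dy, cache, gamma) {
  d <- cache$dims
  dy2 <- mat3(dy)
  R <- nrow(dy2)
  dxhat <- dy2 * rep(gamma, each = R)
  dgamma <- colSums(dy2 * cache$xhat)
  dbeta <- colSums(dy2)
  if (cache$train) {
    t1 <- rep(colMeans(dxhat), each = R)
    t2 <- cache$xhat * rep(colMeans(dxhat * cache$xhat), each = R)
    dx <- (dxhat - t1 - t2) * rep(cache$inv, each = R)
  } else {
    dx <- dxhat * rep(cache$inv, each = R)
  }
  list(dx = arr3(dx, d[1], d[2]), dgamma = dgamma, dbeta = dbeta)
}

layernorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  m <- mat3(x)
  mu <- rowMeans(m)
  v <- rowMeans(m^2) - mu^2
  inv <- 1 / sqrt(v + eps)
  xhat <- (m - mu) * inv
  y <- arr3(sweep_add(xhat * rep(gamma, each = nrow(m)), beta), d[1], d[2])
  list(y = y, xhat = xhat, inv = inv, dims = d)
}

layernorm_bwd <- function(dy, cache, gamma) {
  d <- cache$dims
  dy2 <- mat3(dy)
  R <- nrow(dy2)
  dxhat <- dy2 * rep(gamma, each = R)
  dgamma <- colSums(dy2 * cache$xhat)
  dbeta <- colSums(dy2)
  dx <- (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat)) *
    cache$inv
  list(dx = arr3(dx, d[1], d[2]), dgamma = dgamma, dbeta = dbeta)
}

# ---- activations / regularization -----------------------------------------

relu_fwd <- function(x) list(y = pmax(x, 0), mask = x > 0)
relu_bwd <- function(dy, cache) dy * cache$mask

sigmoid <- function(x) 1 / (1 + exp(-x))

# Inverted dropout; identity when not training or rate == 0.
dropout_fwd <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(y = x, mask = NULL))
  mask <- array(stats::rbinom(length(x), 1L, 1 - rate), dim(x)) / (1 - rate)
  list(y = x * mask, mask = mask)
}

dropout_bwd <- function(dy, cache) {
  if (is.null(cache$mask)) dy else dy * cache$mask
}

# Channel-wise (spatial) dropout: one mask entry per (batch, channel).
spatial_dropout_fwd <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(y = x, mask = NULL))
  d <- dim(x)
  m <- matrix(stats::rbinom(d[1] * d[3], 1L, 1 - rate), d[1], d[3]) / (1 - rate)
  mask <- array(0, d)
  for (l in seq_len(d[2])) mask[, l, ] <- m
  list(y = x * mask, mask = mask)
}

softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}
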