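# Batched attention blocks with caches for backpropagation. The math is the
# same as the exported matrix-level primitives in attention.R.

# Scaled dot-product attention over a batch: q [N,Lq,d], k/v [N,Lk,d].
attn_fwd3 <- function(q, k, v, rate = 0, train = FALSE) {
  N <- dim(q)[1]; Lq <- dim(q)[2]; Lk <- dim(k)[2]; dv <- dim(v)[3]
  dk <- dim(k)[3]
  y <- array(0, c(N, Lq, dv))
  A <- array(0, c(N, Lq, Lk))
  mask <- if (train && rate > 0)
    array(stats::rbinom(N * Lq * Lk, 1L, 1 - rate), c(N, Lq, Lk)) / (1 - rate)
  else NULL
  for (n in seq_len(N)) {
    S <- matrix(q[n, , ], Lq) %*% t(matrix(k[n, , ], Lk)) / sqrt(dk)
    An <- softmax_rows(S)
    A[n, , ] <- An
    Ad <- if (is.null(mask)) An else An * matrix(mask[n, , ], Lq)
    y[n, , ] <- Ad %*% matrix(v[n, , ], Lk)
  }
  list(y = y, A = A, mask = mask, q = q, k = k, v = v)
}

attn_bwd3 <- function(dy, cache) {
  q <- cache$q; k <- cache$k; v <- cache$v
  N <- dim(q)[1]; Lq <- dim(q)[2]; Lk <- dim(k)[2]; dk <- dim(k)[3]
  dq <- array(0, dim(q)); dkk <- array(0, dim(k)); dv <- array(0, dim(v))
  for (n in seq_len(N)) {
    An <- matrix(cache$A[n, , ], Lq)
    Ad <- if (is.null(cache$mask)) An else An * matrix(cache$mask[n, , ], Lq)
    dyn <- matrix(dy[n, , ], Lq)
    vn <- matrix(v[n, , ], Lk)
    dv[n, , ] <- crossprod(Ad, dyn)
    dAd <- dyn %*% t(vn)
    dA <- if (is.null(cache$mask)) dAd else dAd * matrix(cache$mask[n, , ], Lq)
    dS <- An * (dA - rowSums(dA * An))
    dq[n, , ] <- dS %*% matrix(k[n, , ], Lk) / sqrt(dk)
    dkk[n, , ] <- crossprod(dS, matrix(q[n, , ], Lq)) / sqrt(dk)
  }
  list(dq = dq, dk = dkk, dv = dv)
}

# Multi-head attention over a batch (inputs may have different widths; the
# projections map everything to d_model).
mha3_fwd <- function(qin, kin, vin, p, heads, rate = 0, train = FALSE) {
  cq <- dense_fwd(qin, p$Wq, p$bq)
  ck <- dense_fwd(kin, p$Wk, p$bk)
  cv <- dense_fwd(vin, p$Wv, p$bv)
  D <- ncol(p$Wq); dk <- D %/% heads
  N <- dim(cq$y)[1]; Lq <- dim(cq$y)[2]
  O <- array(0, c(N, Lq, D))
  hc <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dk + 1):(h * dk)
    hc[[h]] <- attn_fwd3(cq$y[, , cols, drop = FALSE],
                         ck$y[, , cols, drop = FALSE],
                         cv$y[, , cols, drop = FALSE], rate, train)
    O[, , cols] <- hc[[h]]$y
  }
  co <- dense_fwd(O, p$Wo, p$bo)
  list(y = co$y, cq = cq, ck = ck, cv = cv, heads = hc, co = co, dk = dk)
}

mha3_bwd <- function(dy, cache, p) {
  go <- dense_bwd(dy, cache$co, p$Wo)
  dk <- cache$dk
  dQp <- array(0, dim(cache$cq$y))
  dKp <- array(0, dim(cache$ck$y))
  dVp <- array(0, dim(cache$cv$y))
  for (h in seq_along(cache$heads)) {
    cols <- ((h - 1) * dk + 1):(h * dk)
    g <- attn_bwd3(go$dx[, , cols, drop = FALSE], cache$heads[[h]])
    dQp[, , cols] <- g$dq; dKp[, , cols] <- g$dk; dVp[, , cols] <- g$dv
  }
  gq <- dense_bwd(dQp, cache$cq, p$Wq)
  gk <- dense_bwd(dKp, cache$ck, p$Wk)
  gv <- dense_bwd(dVp, cache$cv, p$Wv)
  list(dq = gq$dx, dk = gk$dx, dv = gv$dx,
       grads = list(Wq = gq$dW, bq = gq$db, Wk = gk$dW, bk = gk$db,
                    Wv = gv$dW, bv = gv$db, Wo = go$dW, bo = go$db))
}

# Residual + layer norm wrapper: y = LN(x + sub).
resln_fwd <- function(x, sub, gamma, beta) {
  ln <- layernorm_fwd(x + sub, gamma, beta)
  list(y = ln$y, ln = ln)
}

resln_bwd <- function(dy, cache, gamma) {
  g <- layernorm_bwd(dy, cache$ln, gamma)
  list(dx = g$dx, dsub = g$dx, dgamma = g$dgamma, dbeta = g$dbeta)
}

# Squeeze-excite channel attention over a batch.
chattn_fwd <- function(x, p) {
  d <- dim(x); N <- d[1]; L <- d[2]
  grp <- rep(seq_len(N), times = L)
  m <- mat3(x)
  s <- rowsum(m, grp) / L                 # [N, C] squeeze
  h <- sweep_add(s %*% p$W1, p$b1)
  hr <- pmax(h, 0)
  g <- sigmoid(sweep_add(hr %*% p$W2, p$b2)) # [N, C] gates
  gexp <- g[grp, , drop = FALSE]
  list(y = arr3(m * gexp, N, L), m = m, s = s, h = h, hr = hr, g = g,
       grp = grp, L = L)
}

chattn_bwd <- function(dy, cache, p) {
  d <- dim(dy); N <- d[1]; L <- cache$L
  dym <- mat3(dy)
  gexp <- cache$g[cache$grp, , drop = FALSE]
  dx_m <- dym * gexp
  dg <- rowsum(dym * cache$m, cache$grp)
  dz <- dg * cache$g * (1 - cache$g)
  dW2 <- crossprod(cache$hr, dz); db2 <- colSums(dz)
  dhr <- dz %*% t(p$W2)
  dh <- dhr * (cache$h > 0)
  dW1 <- crossprod(cache$s, dh); db1 <- colSums(dh)
  ds <- dh %*% t(p$W1)
  dx_m <- dx_m + ds[cache$grp, , drop = FALSE] / L
  list(dx = arr3(dx_m, N, d[2]),
       grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

# Gated fusion over a batch: z = sigmoid([a || b] W + bias); y = z*a + (1-z)*b.
gate_fwd <- function(a, b, p) {
  d <- dim(a)
  am <- mat3(a); bm <- mat3(b)
  u <- cbind(am, bm)
  z <- sigmoid(sweep_add(u %*% p$W, p$b))
  list(y = arr3(z * am + (1 - z) * bm, d[1], d[2]),
       u = u, z = z, am = am, bm = bm)
}

gate_bwd <- function(dy, cache, p) {
  d <- dim(dy)
  dym <- mat3(dy)
  dz <- dym * (cache$am - cache$bm)
  dzs <- dz * cache$z * (1 - cache$z)
  dW <- crossprod(cache$u, dzs); db <- colSums(dzs)
  du <- dzs %*% t(p$W)
  C <- ncol(cache$am)
  da <- dym * cache$z + du[, 1:C, drop = FALSE]
  db_ <- dym * (1 - cache$z) + du[, (C + 1):(2 * C), drop = FALSE]
  list(da = arr3(da, d[1], d[2]), db = arr3(db_, d[1], d[2]),
       grads = list(W = dW, b = db))
}
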