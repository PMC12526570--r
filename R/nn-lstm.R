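# LSTM / bidirectional LSTM with full backpropagation through time.
# Gate order in the fused weight matrices is (input, forget, output, cell).

lstm_fwd <- function(x, Wx, Wh, b) {
  d <- dim(x); N <- d[1]; L <- d[2]
  H <- nrow(Wh)
  I <- Fg <- O <- G <- Cc <- Tc <- Hh <- array(0, c(N, L, H))
  h <- matrix(0, N, H); cc <- matrix(0, N, H)
  for (t in seq_len(L)) {
    xt <- matrix(x[, t, ], N)
    z <- xt %*% Wx + h %*% Wh + rep(b, each = N)
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    o <- sigmoid(z[, (2 * H + 1):(3 * H), drop = FALSE])
    g <- tanh(z[, (3 * H + 1):(4 * H), drop = FALSE])
    cc <- f * cc + i * g
    tc <- tanh(cc)
    h <- o * tc
    I[, t, ] <- i; Fg[, t, ] <- f; O[, t, ] <- o; G[, t, ] <- g
    Cc[, t, ] <- cc; Tc[, t, ] <- tc; Hh[, t, ] <- h
  }
  list(y = Hh, x = x, I = I, Fg = Fg, O = O, G = G, Cc = Cc, Tc = Tc,
       H = H)
}

lstm_bwd <- function(dy, cache, Wx, Wh) {
  x <- cache$x
  d <- dim(x); N <- d[1]; L <- d[2]
  H <- cache$H
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, H, 4 * H)
  db <- numeric(4 * H)
  dx <- array(0, d)
  dh_next <- matrix(0, N, H)
  dc_next <- matrix(0, N, H)
  for (t in rev(seq_len(L))) {
    i <- matrix(cache$I[, t, ], N); f <- matrix(cache$Fg[, t, ], N)
    o <- matrix(cache$O[, t, ], N); g <- matrix(cache$G[, t, ], N)
    tc <- matrix(cache$Tc[, t, ], N)
    c_prev <- if (t > 1) matrix(cache$Cc[, t - 1, ], N) else matrix(0, N, H)
    dh <- matrix(dy[, t, ], N) + dh_next
    do_ <- dh * tc
    dc <- dc_next + dh * o * (1 - tc^2)
    di <- dc * g
    dg <- dc * i
    df <- dc * c_prev
    dc_next <- dc * f
    dz <- cbind(di * i * (1 - i), df * f * (1 - f), do_ * o * (1 - o),
                dg * (1 - g^2))
    xt <- matrix(x[, t, ], N)
    dWx <- dWx + crossprod(xt, dz)
    hp <- if (t > 1) matrix(cache$y[, t - 1, ], N) else matrix(0, N, H)
    dWh <- dWh + crossprod(hp, dz)
    db <- db + colSums(dz)
    dx[, t, ] <- dz %*% t(Wx)
    dh_next <- dz %*% t(Wh)
  }
  list(dx = dx, dWx = dWx, dWh = dWh, db = db)
}

# Bidirectional LSTM returning the full sequence [N, L, 2H]
# (forward-direction channels first).
bilstm_fwd <- function(x, p) {
  fw <- lstm_fwd(x, p$fwd$Wx, p$fwd$Wh, p$fwd$b)
  L <- dim(x)[2]
  xr <- x[, L:1, , drop = FALSE]
  bw <- lstm_fwd(xr, p$bwd$Wx, p$bwd$Wh, p$bwd$b)
  d <- dim(fw$y)
  y <- array(0, c(d[1], d[2], 2 * d[3]))
  y[, , 1:d[3]] <- fw$y
  y[, , (d[3] + 1):(2 * d[3])] <- bw$y[, L:1, , drop = FALSE]
  list(y = y, fw = fw, bw = bw, H = d[3], L = L)
}

bilstm_bwd <- function(dy, cache, p) {
  H <- cache$H; L <- cache$L
  dy_f <- dy[, , 1:H, drop = FALSE]
  dy_b <- dy[, L:1, (H + 1):(2 * H), drop = FALSE]
  gf <- lstm_bwd(dy_f, cache$fw, p$fwd$Wx, p$fwd$Wh)
  gb <- lstm_bwd(dy_b, cache$bw, p$bwd$Wx, p$bwd$Wh)
  list(dx = gf$dx + gb$dx[, L:1, , drop = FALSE],
       grads = list(fwd = list(Wx = gf$dWx, Wh = gf$dWh, b = gf$db),
                    bwd = list(Wx = gb$dWx, Wh = gb$dWh, b = gb$db)))
}
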