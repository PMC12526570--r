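# Frequency-domain feature construction: Welch power spectral density,
# arctan dynamic-range compression, and the spectral self-similarity matrix
# (SSM) that feeds the frequency branch of the network.

#' Welch estimator configuration
#'
#' Defaults (256-sample segments ~ 1 s at 250 Hz, 50% overlap, Hann taper)
#' give K = 18 averaged segments on a 10 s window — enough averaging for a
#' clearly lower-variance estimate than a single periodogram.
#'
#' @param seg_len Segment length L in samples.
#' @param overlap Overlap fraction in \[0, 1).
#' @param window_fn Taper name; `"hann"` or `"rect"`.
#' @param scaling `"density"` (power per Hz) or `"eq"` (the bare
#'   window-energy-normalized periodogram average; `density` = `eq` / (L fs)).
#'   The constant is immaterial downstream of the arctan compression but is
#'   fixed for reproducibility.
#' @return An object of class `welch_config`.
#' @export
welch_config <- function(seg_len = 256, overlap = 0.5, window_fn = "hann",
                         scaling = c("density", "eq")) {
  check_number(seg_len, "seg_len", lower = 2)
  check_number(overlap, "overlap", lower = 0, upper = 1 - 1e-12)
  structure(list(seg_len = as.integer(seg_len), overlap = overlap,
                 window_fn = match.arg(window_fn, c("hann", "rect")),
                 scaling = match.arg(scaling)),
            class = "welch_config")
}

welch_taper <- function(L, window_fn) {
  switch(window_fn,
         hann = 0.5 * (1 - cos(2 * pi * (seq_len(L) - 1) / L)),  # periodic Hann
         rect = rep(1, L))
}

# Per-segment one-sided periodograms, normalized by the window energy
# U = (1/L) sum w^2(n). Returns an (L/2 + 1) x K matrix.
welch_segments <- function(window, fs, cfg) {
  L <- cfg$seg_len
  n <- length(window)
  if (L > n) abort("Welch segment length exceeds the window", "invalid_parameter")
  hop <- max(1L, as.integer(round((1 - cfg$overlap) * L)))
  starts <- seq.int(1L, n - L + 1L, by = hop)
  w <- welch_taper(L, cfg$window_fn)
  U <- sum(w^2) / L
  seg <- vapply(starts, function(s) window[s:(s + L - 1L)] * w, numeric(L))
  spec <- stats::mvfft(seg)                       # columns = segments
  nb <- L %/% 2 + 1L
  p <- (Mod(spec[seq_len(nb), , drop = FALSE])^2) / U
  # one-sided: double everything except DC (and Nyquist when L is even)
  dbl <- rep(2, nb); dbl[1] <- 1
  if (L %% 2 == 0) dbl[nb] <- 1
  p <- p * dbl
  if (cfg$scaling == "density") p <- p / (L * fs)
  p
}

#' Welch power spectral density
#'
#' Splits the window into overlapping tapered segments, computes each
#' segment's window-energy-normalized periodogram and averages them
#' pointwise along the frequency axis.
#'
#' @param window Numeric signal (one analysis window).
#' @param fs Sampling rate in Hz.
#' @param cfg A [welch_config()].
#' @return List of class `welch_psd` with `freqs` (Hz, 0..fs/2), `power`
#'   (nonnegative), and `k_segments`.
#' @export
welch_psd <- function(window, fs, cfg = welch_config()) {
  p <- welch_segments(window, fs, cfg)
  structure(list(freqs = seq(0, fs / 2, length.out = nrow(p)),
                 power = rowMeans(p),
                 k_segments = ncol(p)),
            class = "welch_psd")
}

#' Arctan dynamic-range compression
#'
#' Maps nonnegative power values from \[0, Inf) into \[0, pi/2), elementwise
#' and strictly order-preserving, bounding the influence of local energy
#' spikes while preserving the relative energy ranking.
#'
#' @param power Nonnegative numeric values.
#' @return `atan(power)`.
#' @export
arctan_compress <- function(power) {
  if (any(!is.finite(power)) || any(power < 0))
    abort("power values must be finite and nonnegative", "invalid_parameter")
  atan(power)
}

#' Spectral self-similarity matrix
#'
#' Builds the band-by-segment energy matrix X (`n_bands` contiguous
#' equal-width partitions of the one-sided spectrum; entry \[b, k\] is the
#' arctan-compressed energy of band b in Welch segment k) and returns the
#' Gram matrix S = X X^T, whose entry (i, j) measures the energy similarity
#' between frequency bands i and j over the window. With `mode = "bins"`
#' the compressed per-bin PSD columns are used directly instead of band
#' aggregates.
#'
#' @inheritParams welch_psd
#' @param n_bands Number of frequency bands B (tokens); at least 2.
#' @param mode `"bands"` (default) or `"bins"`.
#' @return List of class `ssm` with `S` (B x B), `X`, `band_edges` (Hz).
#' @export
build_ssm <- function(window, fs, cfg = welch_config(), n_bands = 32,
                      mode = c("bands", "bins")) {
  mode <- match.arg(mode)
  check_number(n_bands, "n_bands", lower = 2)
  p <- welch_segments(window, fs, cfg)    # bins x segments
  nb <- nrow(p)
  if (mode == "bands") {
    if (n_bands > nb)
      abort("more bands than frequency bins", "invalid_parameter")
    grp <- cut(seq_len(nb), breaks = n_bands, labels = FALSE)
    X <- arctan_compress(rowsum(p, grp))  # band energy per segment, compressed
    edges <- seq(0, fs / 2, length.out = n_bands + 1L)
  } else {
    X <- arctan_compress(p)
    edges <- seq(0, fs / 2, length.out = nb + 1L)
  }
  structure(list(S = X %*% t(X), X = X, band_edges = edges,
                 k_segments = ncol(p)),
            class = "ssm")
}

#' Sinusoidal positional encoding
#'
#' Standard interleaved sine/cosine encoding:
#' `PE[pos, 2i] = sin(pos / 10000^(2i/dim))`,
#' `PE[pos, 2i+1] = cos(pos / 10000^(2i/dim))` (positions 0-based).
#'
#' @param length Number of token positions.
#' @param dim Embedding dimension.
#' @return `length x dim` matrix with entries in \[-1, 1\].
#' @export
positional_encoding <- function(length, dim) {
  check_number(length, "length", lower = 1)
  check_number(dim, "dim", lower = 1)
  pos <- seq_len(length) - 1
  pe <- matrix(0, length, dim)
  for (j in seq_len(dim)) {
    i2 <- 2 * ((j - 1) %/% 2)
    ang <- pos / 10000^(i2 / dim)
    pe[, j] <- if (j %% 2 == 1) sin(ang) else cos(ang)
  }
  pe
}

#' Convolutional adjustment of a positional encoding
#'
#' Adds a lightweight depthwise 1-D convolution (kernel 3, same padding)
#' residually to the encoding, letting the model deform the fixed sinusoidal
#' grid. With a zero kernel and bias the output equals the input exactly.
#'
#' @param pe `length x dim` positional-encoding matrix.
#' @param kernel `3 x dim` depthwise kernel (one column per channel).
#' @param bias Length-`dim` bias.
#' @return Adjusted encoding, same shape as `pe`.
#' @export
conv_adjust <- function(pe, kernel = matrix(0, 3, ncol(pe)),
                        bias = numeric(ncol(pe))) {
  stopifnot(nrow(kernel) == 3, ncol(kernel) == ncol(pe),
            length(bias) == ncol(pe))
  x <- array(pe, c(1L, nrow(pe), ncol(pe)))
  adj <- depthwise_conv_fwd(x, kernel, bias)$y
  pe + matrix(adj, nrow(pe), ncol(pe))
}

# SSM tensors for a whole window matrix: returns [n, B, B] array.
#' Self-similarity tensors for a window set
#'
#' @param windows Matrix of windows (one per row).
#' @param fs Sampling rate in Hz.
#' @param cfg A [welch_config()].
#' @param n_bands Number of frequency bands.
#' @return Array `[n_windows, n_bands, n_bands]`.
#' @export
window_ssm_tensor <- function(windows, fs, cfg = welch_config(), n_bands = 32) {
  n <- nrow(windows)
  out <- array(0, c(n, n_bands, n_bands))
  for (i in seq_len(n))
    out[i, , ] <- build_ssm(windows[i, ], fs, cfg, n_bands)$S
  out
}
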