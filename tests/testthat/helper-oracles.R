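# Independent oracles used across the suite. These are deliberately naive
# (literal formulas, explicit loops) and never share code with the package
# implementation they check.

# Literal Welch estimate: explicit segment loop, naive DFT, window-energy
# normalization, pointwise averaging.
brute_welch <- function(x, fs, L, overlap, taper = "hann",
                        scaling = "density") {
  hop <- round((1 - overlap) * L)
  starts <- seq(1, length(x) - L + 1, by = hop)
  w <- if (taper == "hann") 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / L)) else rep(1, L)
  U <- sum(w^2) / L
  nb <- L %/% 2 + 1
  acc <- numeric(nb)
  for (s in starts) {
    seg <- x[s:(s + L - 1)] * w
    dft <- vapply(0:(nb - 1), function(k)
      sum(seg * exp(-2i * pi * k * (0:(L - 1)) / L)), complex(1))
    p <- Mod(dft)^2 / U
    dbl <- rep(2, nb); dbl[1] <- 1
    if (L %% 2 == 0) dbl[nb] <- 1
    acc <- acc + p * dbl
  }
  p <- acc / length(starts)
  if (scaling == "density") p / (L * fs) else p
}

# Literal two-loop scaled dot-product attention.
naive_attention <- function(Q, K, V) {
  n <- nrow(Q); m <- nrow(K)
  W <- matrix(0, n, m)
  for (i in seq_len(n)) {
    s <- numeric(m)
    for (j in seq_len(m)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(ncol(K))
    e <- exp(s - max(s))
    W[i, ] <- e / sum(e)
  }
  list(output = W %*% V, weights = W)
}

# Mean heart rate (bpm) from a simple local-maximum sweep with a minimum
# peak distance, as an independent check of the pulse trains.
peak_rate_bpm <- function(x, fs, min_dist_s) {
  pk <- pracma::findpeaks(x, minpeakdistance = max(1L, round(min_dist_s * fs)),
                          minpeakheight = stats::quantile(x, 0.8))
  if (is.null(pk) || nrow(pk) < 3) return(NA_real_)
  60 / mean(diff(sort(pk[, 2])) / fs)
}

# Dominant frequency by brute-force periodogram argmax on the detrended
# signal.
dominant_freq <- function(x, fs, fmin = 0.2) {
  x <- x - mean(x)
  s <- Mod(stats::fft(x))^2
  f <- (seq_along(x) - 1) / length(x) * fs
  sel <- f > fmin & f < fs / 2
  f[sel][which.max(s[sel])]
}

# Pairwise-concordance AUC (Mann-Whitney identity), ties counted half.
concordance_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Literal one-line-per-formula one-vs-rest metrics (percent).
literal_ovr_metrics <- function(cm, cls) {
  tp <- cm[cls, cls]
  fp <- sum(cm[, cls]) - tp
  fn <- sum(cm[cls, ]) - tp
  tn <- sum(cm) - tp - fp - fn
  c(Pre = 100 * tp / (tp + fp),
    Sen = 100 * tp / (tp + fn),
    Spe = 100 * tn / (fp + tn),
    F1 = 2 * (100 * tp / (tp + fp)) * (100 * tp / (tp + fn)) /
      (100 * tp / (tp + fp) + 100 * tp / (tp + fn)),
    Acc = 100 * (tp + tn) / (tp + fp + fn + tn))
}

# Literal three-branch clip of the stride rule.
literal_stride <- function(w, s_ref = 250, s_min = 125, s_max = 500, beta = 1) {
  raw <- sign(s_ref / w^beta) * floor(abs(s_ref / w^beta) + 0.5)
  if (raw < s_min) s_min else if (raw > s_max) s_max else raw
}
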