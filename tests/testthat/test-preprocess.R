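# Signal-conditioning chain.

fs <- 250
tt <- seq(0, 60 - 1 / fs, by = 1 / fs)
guard <- function(x, s = 0.5) x[(s * fs):(length(x) - s * fs)]

test_that("zero-phase band-pass passes in-band tones at unit gain, lag 0", {
  x <- sin(2 * pi * 5 * tt)
  y <- bandpass_zero_phase(x, fs)
  expect_lt(abs(max(abs(y)) - 1), 0.01)
  cc <- ccf(y, x, lag.max = 10, plot = FALSE)
  expect_identical(cc$lag[which.max(cc$acf)], 0)
})

test_that("zero-phase band-pass rejects DC and attenuates out-of-band tones", {
  yc <- bandpass_zero_phase(rep(3, length(tt)), fs)
  expect_lt(max(abs(guard(yc))), 1e-3)

  y45 <- bandpass_zero_phase(sin(2 * pi * 45 * tt), fs)
  bound <- 1 / sqrt(1 + (45 / 30)^8)  # analytic order-4 Butterworth |H(45)|
  expect_lte(max(abs(guard(y45))), bound)
})

test_that("zero-phase property holds across in-band frequencies", {
  for (f0 in c(0.5, 2, 11, 24)) {
    x <- sin(2 * pi * f0 * tt)
    y <- bandpass_zero_phase(x, fs)
    cc <- ccf(y, x, lag.max = 5, plot = FALSE)
    expect_identical(cc$lag[which.max(cc$acf)], 0)
  }
})

test_that("too-short signals raise an explicit error", {
  expect_error(bandpass_zero_phase(rnorm(20), fs), class = "signal_too_short")
})

test_that("moving average matches hand-computed cases and preserves range", {
  expect_equal(moving_average(c(0, 0, 3, 0, 0), fs = 1, window_s = 3),
               c(0, 1, 1, 1, 0))
  x <- rep(2.5, 100)
  expect_equal(moving_average(x, fs, 0.04), x)
  set.seed(1); x <- rnorm(100)
  expect_identical(moving_average(x, fs = 1, window_s = 1), x)  # 1-sample window
  y <- moving_average(x, fs = 1, window_s = 9)
  expect_gte(min(y), min(x)); expect_lte(max(y), max(x))
  expect_error(moving_average(x, fs = 1, window_s = 200),
               class = "invalid_parameter")
})

test_that("baseline correction removes injected drift, keeps clean signals", {
  # strictly periodic pulse train: no drift, nothing to remove
  beat <- function(d) exp(-0.5 * (d / 0.07)^2) +
    0.35 * exp(-0.5 * ((d - 0.25) / 0.112)^2)
  clean <- rowSums(vapply(seq(0.5, 59.5, by = 0.5),
                          function(b) beat(tt - b), numeric(length(tt))))
  out <- baseline_correct(clean, fs)
  # interior comparison: at the record edges the local level genuinely dips
  # (silence before the first beat), which the drift estimate follows
  mid <- guard(seq_along(clean), 2)
  expect_lt(sqrt(mean((out[mid] - (clean - mean(clean))[mid])^2)),
            0.05 * sd(clean))

  # injected 0.05 Hz wander with amplitude = signal sd: low-band power drops >= 90%
  wander <- sd(clean) * sin(2 * pi * 0.05 * tt)
  corr <- baseline_correct(clean + wander, fs)
  low_power <- function(x) {
    x <- x - mean(x)
    s <- Mod(fft(x))^2
    f <- (seq_along(x) - 1) / length(x) * fs
    sum(s[f > 0 & f < 0.1])
  }
  expect_lt(low_power(corr), 0.1 * low_power(clean + wander))

  # a pure ramp is drift only
  ramp <- seq(0, 10, length.out = length(tt))
  expect_lt(max(abs(baseline_correct(ramp, fs))), 0.05 * diff(range(ramp)))

  expect_error(baseline_correct(rnorm(600), fs = 250,
                                preprocess_config(decomp_level = 12)),
               class = "invalid_parameter")
})

test_that("min-max normalization scales, is idempotent, rejects constants", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  set.seed(2)
  x <- minmax_normalize(rnorm(50))
  expect_equal(minmax_normalize(x), x)
  expect_error(minmax_normalize(c(5, 5, 5)), class = "degenerate_signal")
  expect_error(minmax_normalize(c(1, NA, 3)), class = "invalid_parameter")
})

test_that("preprocess_record applies the full chain in order", {
  r <- simulate_record("Tachycardia", sim_params(duration_s = 30, seed = 9))
  out <- preprocess_record(r)
  expect_length(out$samples, length(r$samples))
  expect_equal(range(out$samples), c(0, 1))
  expect_true(all(is.finite(out$samples)))
  expect_identical(out$label, r$label)
  expect_identical(out$record_id, r$record_id)
  # purity
  out2 <- preprocess_record(r)
  expect_identical(out$samples, out2$samples)
  # normalization toggle leaves the range unconstrained
  raw <- preprocess_record(r, preprocess_config(normalize = FALSE))
  expect_false(isTRUE(all.equal(range(raw$samples), c(0, 1))))
})

test_that("wavelet approximation reconstructs slow structure only", {
  n <- 2048
  slow <- sin(2 * pi * (1:n) / 1024)
  fast <- 0.5 * sin(2 * pi * (1:n) / 8)
  ap <- dwt_approximation(slow + fast, level = 4)
  expect_lt(sqrt(mean((ap - slow)^2)), 0.02)
  expect_error(dwt_approximation(rnorm(100), level = 8),
               class = "invalid_parameter")
})
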