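# Synthetic single-channel PPG generator for the four target rhythm classes.
#
# Each class is generated from rhythm semantics rather than a physiological
# model: bradycardia/tachycardia/VT are quasi-periodic pulse trains whose
# inter-beat intervals are drawn from the class heart-rate band, with VT using
# a wider, dicrotic-suppressed pulse template; ventricular flutter/fibrillation
# is a drifting band-limited oscillation with no pulse train at all.

#' Rhythm class labels
#'
#' The four arrhythmia classes handled by the package, in their stable
#' integer encoding (0-3). The same ordering is used for class weights,
#' confusion matrices and network outputs everywhere downstream.
#'
#' @return Character vector of the four class names, in encoding order:
#'   `Bradycardia` (0), `Tachycardia` (1), `VentricularTachycardia` (2),
#'   `VentricularFlutterFib` (3).
#' @export
#' @examples
#' rhythm_classes()
rhythm_classes <- function() {
  c("Bradycardia", "Tachycardia", "VentricularTachycardia",
    "VentricularFlutterFib")
}

# Coerce a label (name, factor or 0-based integer code) to a canonical name.
as_rhythm <- function(label) {
  cls <- rhythm_classes()
  if (is.numeric(label)) {
    if (!label %in% 0:3) abort("integer rhythm codes must be 0-3", "invalid_parameter")
    return(cls[label + 1L])
  }
  label <- as.character(label)
  if (!label %in% cls)
    abort(sprintf("unknown rhythm class '%s'", label), "invalid_parameter")
  label
}

rhythm_code <- function(label) match(as_rhythm(label), rhythm_classes()) - 1L

#' Simulation parameters for the synthetic PPG generator
#'
#' Defaults emulate the recording conditions of ICU alarm records: 250 Hz
#' sampling, 5-minute records, unit-amplitude pulses with a dicrotic notch,
#' 0.05 Hz baseline wander at 30% amplitude and 2% additive Gaussian noise.
#' Per-class heart-rate bands respect the alarm definitions (bradycardia
#' below 40 bpm, tachycardia above 140 bpm, ventricular tachycardia at or
#' above 100 bpm); ventricular flutter/fibrillation is an oscillation whose
#' instantaneous frequency stays inside `vf_osc_band_hz`.
#'
#' @param fs Sampling rate in Hz.
#' @param duration_s Record duration in seconds.
#' @param hr_bpm_range Named list of per-class heart-rate intervals (bpm).
#' @param pulse_template List with systolic `amp`, `width_s`, dicrotic
#'   `dicrotic_amp` (fraction of systolic) and `dicrotic_delay_s`.
#' @param vf_osc_band_hz Oscillation band (Hz) for flutter/fibrillation.
#' @param baseline_wander List with `amp` (fraction of pulse amplitude) and
#'   `freq_hz` (at most 0.1 Hz).
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param seed Integer seed; identical seeds give bitwise-identical records.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(fs = 250, duration_s = 300,
                       hr_bpm_range = list(
                         Bradycardia = c(25, 39),
                         Tachycardia = c(141, 180),
                         VentricularTachycardia = c(100, 140)),
                       pulse_template = list(amp = 1, width_s = 0.07,
                                             dicrotic_amp = 0.35,
                                             dicrotic_delay_s = 0.25),
                       vf_osc_band_hz = c(4, 7),
                       baseline_wander = list(amp = 0.3, freq_hz = 0.05),
                       noise_sd = 0.02,
                       seed = 1L) {
  check_number(fs, "fs", lower = 1e-6)
  check_number(duration_s, "duration_s", lower = 1e-6)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(seed, "seed")
  if (hr_bpm_range$Bradycardia[2] >= 40)
    abort("bradycardia heart-rate range must stay below 40 bpm", "invalid_parameter")
  if (hr_bpm_range$Tachycardia[1] <= 140)
    abort("tachycardia heart-rate range must stay above 140 bpm", "invalid_parameter")
  if (hr_bpm_range$VentricularTachycardia[1] < 100)
    abort("ventricular tachycardia heart rate must be at least 100 bpm", "invalid_parameter")
  if (vf_osc_band_hz[1] <= 0 || vf_osc_band_hz[2] >= fs / 2 ||
      vf_osc_band_hz[1] >= vf_osc_band_hz[2])
    abort("vf_osc_band_hz must lie within (0, fs/2)", "invalid_parameter")
  if (baseline_wander$freq_hz > 0.1)
    abort("baseline wander frequency must be at most 0.1 Hz", "invalid_parameter")
  structure(list(fs = fs, duration_s = duration_s, hr_bpm_range = hr_bpm_range,
                 pulse_template = pulse_template, vf_osc_band_hz = vf_osc_band_hz,
                 baseline_wander = baseline_wander, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_params")
}

# Pulse-train synthesis: each beat is a systolic Gaussian plus a delayed
# dicrotic Gaussian; amplitudes jittered per beat (lognormal, sd 5%),
# inter-beat intervals jittered (3% sd; 8% for the irregular VT rhythm).
pulse_train <- function(n, fs, hr_bpm, ibi_jitter, tmpl) {
  ibi <- 60 / hr_bpm
  n_beats <- ceiling(n / fs / ibi) + 2L
  ibis <- ibi * exp(stats::rnorm(n_beats, 0, ibi_jitter))
  beat_t <- cumsum(c(stats::runif(1, 0, ibi), ibis))
  beat_t <- beat_t[beat_t * fs < n + 2 * fs]
  amps <- tmpl$amp * exp(stats::rnorm(length(beat_t), 0, 0.05))
  x <- numeric(n)
  tt <- seq_len(n) / fs
  w <- tmpl$width_s
  half <- ceiling(4 * (w + tmpl$dicrotic_delay_s) * fs)
  for (b in seq_along(beat_t)) {
    c0 <- round(beat_t[b] * fs)
    idx <- max(1L, c0 - half):min(n, c0 + half)
    if (idx[1] > n || idx[length(idx)] < 1) next
    d <- tt[idx] - beat_t[b]
    x[idx] <- x[idx] + amps[b] * (exp(-0.5 * (d / w)^2) +
      tmpl$dicrotic_amp * exp(-0.5 * ((d - tmpl$dicrotic_delay_s) / (1.6 * w))^2))
  }
  x
}

# VF/flutter: amplitude-modulated sinusoid whose instantaneous frequency
# performs a reflected random walk inside the oscillation band.
vf_waveform <- function(n, fs, band) {
  steps <- stats::rnorm(n, 0, 0.4 / sqrt(fs))
  f <- numeric(n)
  f[1] <- stats::runif(1, band[1] + 0.3, band[2] - 0.3)
  lo <- band[1] + 0.1; hi <- band[2] - 0.1
  for (i in 2:n) {
    v <- f[i - 1] + steps[i]
    if (v > hi) v <- 2 * hi - v
    if (v < lo) v <- 2 * lo - v
    f[i] <- v
  }
  phase <- 2 * pi * cumsum(f) / fs + stats::runif(1, 0, 2 * pi)
  am <- 0.5 * (1 + 0.3 * sin(2 * pi * 0.3 * seq_len(n) / fs +
                             stats::runif(1, 0, 2 * pi)))
  0.9 * am * sin(phase)
}

#' Simulate one labeled PPG record
#'
#' @param label Rhythm class name (see [rhythm_classes()]) or 0-3 code.
#' @param params A [sim_params()] object.
#' @param record_id Identifier stored on the record.
#' @return A `ppg_record`: list with `samples`, `fs`, `label`, `record_id`
#'   and a `meta` provenance list.
#' @export
#' @examples
#' r <- simulate_record("Bradycardia", sim_params(duration_s = 20))
#' length(r$samples) == 20 * 250
simulate_record <- function(label, params = sim_params(), record_id = NULL) {
  if (!inherits(params, "sim_params")) params <- do.call(sim_params, params)
  label <- as_rhythm(label)
  n <- round(params$fs * params$duration_s)
  if (n < 1) abort("duration too short", "invalid_parameter")
  fs <- params$fs
  x <- with_seed(params$seed + 7919L * rhythm_code(label), {
    core <- switch(label,
      Bradycardia = pulse_train(n, fs, stats::runif(1, params$hr_bpm_range$Bradycardia[1],
                                                    params$hr_bpm_range$Bradycardia[2]),
                                0.03, params$pulse_template),
      Tachycardia = pulse_train(n, fs, stats::runif(1, params$hr_bpm_range$Tachycardia[1],
                                                    params$hr_bpm_range$Tachycardia[2]),
                                0.03, params$pulse_template),
      VentricularTachycardia = {
        tmpl <- params$pulse_template
        tmpl$width_s <- 2.2 * tmpl$width_s      # broad ventricular upstroke
        tmpl$dicrotic_amp <- 0.25 * tmpl$dicrotic_amp # suppressed notch
        pulse_train(n, fs, stats::runif(1, params$hr_bpm_range$VentricularTachycardia[1],
                                        params$hr_bpm_range$VentricularTachycardia[2]),
                    0.08, tmpl)
      },
      VentricularFlutterFib = vf_waveform(n, fs, params$vf_osc_band_hz))
    wander <- params$baseline_wander$amp * params$pulse_template$amp *
      sin(2 * pi * params$baseline_wander$freq_hz * seq_len(n) / fs +
          stats::runif(1, 0, 2 * pi))
    core + wander + stats::rnorm(n, 0, params$noise_sd)
  })
  stopifnot(all(is.finite(x)))
  structure(list(samples = x, fs = fs, label = label,
                 record_id = record_id %||% sprintf("%s_seed%d", label, params$seed),
                 meta = list(generator = "ppgfusion-synth", seed = params$seed,
                             duration_s = params$duration_s)),
            class = "ppg_record")
}

#' Simulate a balanced labeled dataset
#'
#' Generates `n_per_class` records for each of the four rhythm classes with
#' unique record ids. Deterministic for a fixed `params$seed`.
#'
#' @param n_per_class Records per class (at least 1).
#' @param params A [sim_params()] object; its `seed` drives all randomness.
#' @return A `ppg_dataset`: list of `ppg_record`s with a manifest attribute.
#' @export
make_dataset <- function(n_per_class, params = sim_params()) {
  if (!is.numeric(n_per_class) || n_per_class < 1)
    abort("n_per_class must be at least 1", "invalid_parameter")
  n_per_class <- as.integer(n_per_class)
  records <- vector("list", 4L * n_per_class)
  k <- 0L
  for (cls in rhythm_classes()) {
    for (i in seq_len(n_per_class)) {
      p <- params
      # distinct, reproducible per-record seed; stays far below 2^31
      p$seed <- params$seed + 100000L * rhythm_code(cls) + 211L * i
      k <- k + 1L
      records[[k]] <- simulate_record(cls, p,
        record_id = sprintf("%s_%03d", cls, i))
    }
  }
  structure(records, class = "ppg_dataset", sim_seed = params$seed)
}

#' @export
print.ppg_dataset <- function(x, ...) {
  labs <- vapply(x, `[[`, "", "label")
  cat("ppg_dataset:", length(x), "records\n")
  print(table(factor(labs, levels = rhythm_classes())))
  invisible(x)
}

dataset_manifest <- function(records) {
  data.frame(record_id = vapply(records, `[[`, "", "record_id"),
             label = vapply(records, `[[`, "", "label"),
             fs = vapply(records, `[[`, 0, "fs"),
             duration = vapply(records, function(r) length(r$samples) / r$fs, 0),
             stringsAsFactors = FALSE)
}

#' Write / read a dataset container
#'
#' The container is a single serialized file holding the sample matrix,
#' sampling rate, labels and record ids, accompanied by a plain-text CSV
#' manifest (`record_id,label,fs,duration`).
#'
#' @param records A `ppg_dataset` or list of `ppg_record`s.
#' @param dir Output directory (created if missing).
#' @return `save_dataset` returns the directory invisibly; `load_dataset`
#'   returns a `ppg_dataset`.
#' @export
save_dataset <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(records, file.path(dir, "dataset.rds"), compress = "gzip")
  utils::write.csv(dataset_manifest(records), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(dir) readRDS(file.path(dir, "dataset.rds"))
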