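---
title: "Dual-domain attention classification of PPG arrhythmias: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-domain attention classification of PPG arrhythmias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ppgfusion)
```

## The problem

Photoplethysmography (PPG) records blood-volume pulsations optically, so a
single-channel PPG waveform carries the heart rhythm: beat-to-beat intervals,
pulse morphology and, for disorganized rhythms, the spectral signature of the
oscillation itself. `ppgfusion` classifies 10-second PPG windows into four
life-threatening rhythm classes — bradycardia (rate below 40 bpm), tachycardia
(above 140 bpm), ventricular tachycardia (VT, ventricular beats at or above
100 bpm with altered pulse morphology) and ventricular flutter/fibrillation
(VF, an oscillatory waveform with no discernible pulse train).

The classifier is a dual-branch neural network. The *time branch* models
waveform dynamics: a causal convolution stem with max pooling, two residual
convolution blocks, a cross-scale interactive attention (CSIA) block, and two
bidirectional LSTM layers. The *frequency branch* models the energy structure
of the spectrum: Welch power spectral density, arctan compression, a spectral
self-similarity matrix (SSM) whose rows become the tokens of a small
Transformer encoder, a 1x1 channel projection and a BiLSTM over the band
axis. A *fusion head* aligns the two feature sequences, applies per-branch
channel attention, cross-attention (frequency as query, time as key/value)
and self-attention over the fused sequence, merges the two attention pathways
through a learnable sigmoid gate, and classifies with two dense layers and a
softmax.

Everything — including backpropagation through convolutions, batch
normalization, LSTMs and attention — is implemented in base R. The
correctness of the hand-written gradients is established in the test suite by
central finite differences over a random sample of every parameter tensor of
a miniature configuration.

## The model, block by block

**Scaled dot-product attention.** `Attention(Q,K,V) = softmax(QK'/sqrt(d_k)) V`,
with the softmax stabilized by row-max subtraction. Multi-head attention
projects queries, keys and values per head with learnable matrices, runs the
heads in parallel subspaces, concatenates and projects with `W^O`. Each
attention block is wrapped as `Y = LayerNorm(sublayer(X) + X)` (epsilon
1e-5).

**CSIA.** Deep residual features serve as both query and key; the value is an
"adaptively reconstructed input": the raw window is segment-averaged
(adaptive average pooling) down to the residual-feature length and linearly
projected to the model width. We deliberately do *not* collapse the window to
a single global average: if the value sequence is constant across positions,
every attention-weight row (which sums to one) yields the same output vector
and the attention weights become mathematically irrelevant. Segment-wise
pooling keeps the value sequence time-varying, so attention actually routes
information.

**Frequency branch input.** For each 10 s window the Welch estimate uses
256-sample (~1 s) Hann-tapered segments with 50% overlap, giving K = 18
segments. Band-by-segment energies (32 equal-width bands by default) are
arctan-compressed into [0, pi/2) — bounding the influence of any single
energy spike while preserving energy ranking — and the SSM is the Gram matrix
S = XX', a symmetric positive-semidefinite 32x32 map of band-to-band energy
similarity. The alternative reading that builds the SSM directly over PSD
bins is available via `build_ssm(..., mode = "bins")`. Compression is applied
*before* the inner products, so what is preserved is the ranking among band
energies. Token embeddings receive a standard sinusoidal positional encoding
plus a zero-initialized depthwise convolution applied residually
(`conv_adjust`), so training starts from the canonical encoding exactly.

**Fusion.** Both branch outputs are projected to a common width (64). The
shorter (frequency) sequence is linearly upsampled by an integer factor and
zero-padded to the time-branch length; the time branch is never resampled.
Channel attention is squeeze-and-excite with reduction 4. The gate computes
`z = sigmoid([a||b] W + bias)` and returns `z*a + (1-z)*b`, an elementwise
convex combination of the cross-attention and self-attention pathways.

**Capacity.** All layer widths are configurable; the `"paper"` preset
(stem 32\@k7, residual blocks to 64\@k5, CSIA width 64 with 4 heads, BiLSTMs
64/32, 32 bands, Transformer width 32 with 4 heads and FFN 64, 1x1 conv 32,
frequency BiLSTM 32, common width 64, head 144) totals 1,440,692 trainable
parameters, within the ~1.46 M budget of the reference architecture. The head
width 144 (rather than a rounder 128) was chosen from the parameter-count
arithmetic so the default configuration lands near that budget. At 32-bit
precision the reference total of 1,465,175 parameters occupies
`1465175 * 4 / 1024^2 = 5.59` MB.

## Preprocessing

The conditioning chain is band-pass, smoothing, baseline correction, min-max
scaling, in that order.

**Zero-phase band-pass (0.05–30 Hz, order 4).** Implemented as the *squared*
order-4 Butterworth magnitude response — exactly what a forward–backward
(filtfilt) application realizes — applied in the frequency domain with
bilinear prewarping, after demeaning, even-reflection padding
(`2 / band_low` seconds per side) and a raised-cosine taper on the pads. The
reason is numerical: at 250 Hz a 0.05 Hz corner puts recursive-filter poles
at |z| ≈ 0.999, and transfer-function filtfilt (in any environment) shows
2–28% in-band amplitude error on a 60 s tone, with edge transients lasting
tens of seconds. The frequency-domain realization has exactly zero phase,
passes a 5 Hz tone with 0.5% amplitude error, rejects DC to machine
precision, and confines boundary artifacts to roughly 0.2 s at each record
edge. Contracts on out-of-band attenuation are therefore asserted with a
0.5 s edge guard.

**Moving average.** 0.04 s (10 samples at 250 Hz) centered window with
symmetrically shrinking edges — long enough to suppress sample noise, short
enough to preserve the dicrotic notch. The length is not pinned by any
published value and is exposed in `preprocess_config()`.

**Baseline correction.** Drift is the sum of (1) the Daubechies-4 wavelet
approximation at a level whose approximation band falls below 0.5 Hz (level 8
at 250 Hz), computed on a generously mirror-padded signal because the level-8
analysis filters spread over ~2000 samples, and (2) a natural cubic spline
through 1 s-spaced medians of the residual, *centered on the median of those
medians*. The centering matters: the running median of a pulsatile waveform
sits below its mean (between-pulse baseline), and subtracting that constant
offset would distort every window; only local fluctuation of the median is
drift. No DWT implementation exists in the installed R stack, so the
periodized Daubechies-4 pyramid (standard published 8-tap coefficients) is
implemented in the package and verified for perfect reconstruction in the
tests. Wavelet family, level and knot spacing are configurable; none is a
published value.

**Scaling.** Per-record min-max to [0, 1]; constant records raise an
explicit degenerate-signal error. Windows cut later are *not* re-normalized
per window (configurable via the preprocessing step itself), keeping
within-record amplitude relations intact.

## Splitting and weight-aware sliding windows (WASW)

Records are split 6:2:2 (train/validation/test) *before* any windowing,
stratified by class via per-class shuffling and largest-remainder rounding,
so no source record contributes windows to two splits — the test suite
asserts empty source-id intersections. Class weights are inverse record
frequency rescaled to mean 1 (so a balanced set yields weight 1 and recovers
the reference stride); the weight formula is not published and this
normalization is our convention. The training stride per class is

    S_c = clip(round(S_ref / w_c^beta), S_min, S_max),

with S_ref = 250 samples (1 s), S_min = 125, S_max = 500, beta = 1, and
rounding half away from zero (integer conversion is not specified anywhere;
this choice is tested against a literal three-branch oracle). Validation
records use the fixed reference stride; test records use non-overlapping
windows (stride = window length) so that evaluation windows are maximally
independent and unaffected by augmentation choices — whether published test
metrics used overlapping windows is unknowable from the text, and
non-overlapping is the conservative default.

## Training protocol

Adam (beta1 0.9, beta2 0.999, epsilon 1e-7) with initial learning rate 5e-4,
batch size 60, up to 160 epochs. The loss is the Kullback–Leibler divergence
between the one-hot target rows and the predicted distribution, with
predictions clipped to [1e-7, 1]; for one-hot targets this equals
class-weighted categorical cross-entropy (asserted to 1e-9 in the tests).
Class weights enter the loss as per-row multipliers — one mechanism, not also
a sampler, to avoid double-counting the imbalance correction. He-normal
initialization everywhere; dropout 0.2 on attention weights, BiLSTM outputs,
the fusion gate output and the first dense layer; channel-wise
(spatial) dropout after each residual block. Learning rate is divided by 10
after 30 epochs without validation-loss improvement (floor 1e-6); early
stopping waits 50 epochs (the published protocol states early stopping but
not its patience); the best validation-accuracy weights are checkpointed and
restored. All randomness (shuffling, dropout masks, init) flows from the
single seed in `train_config()`, making runs bit-reproducible.

## Evaluation

All metrics derive from the 4x4 confusion matrix, one-vs-rest per class:
precision, sensitivity, specificity, F1 (harmonic mean) and per-class
accuracy, as percentages rounded half-up to two decimals. Per-class
"accuracy" is one-vs-rest accuracy — the only reading under which per-class
accuracies can differ and exceed the overall multi-class accuracy, as the
reference tables show. The overall row reports support-weighted averages
(macro averages do not reproduce the reference overall row; the aggregation
rule there is unstated, so ours is documented rather than asserted). ROC
curves use a threshold sweep with trapezoidal AUC (equal to the
pairwise-concordance statistic, tested exhaustively on small cases and
against pROC); micro-averages pool all (class, window) decisions; average
precision uses step interpolation.

## The synthetic generator

No waveform data ships with the package; every experiment runs on synthetic
records. Each pulse class draws a heart rate uniformly from its band
(bradycardia 25–39, tachycardia 141–180, VT 100–140 bpm) and renders one
Gaussian systolic peak plus a delayed dicrotic Gaussian per beat, with 5%
lognormal amplitude jitter and 3% inter-beat-interval jitter (8% for VT,
whose template is also 2.2x wider with a suppressed dicrotic notch). VF is an
amplitude-modulated sinusoid whose instantaneous frequency random-walks
inside 4–7 Hz, reflected at the band edges — matching the spectral
description of fibrillatory waveforms without claiming hemodynamic fidelity.
All records get a 0.05 Hz sinusoidal baseline wander at 30% of pulse
amplitude and 2% Gaussian noise. The sampling rate defaults to 250 Hz; note
that the source protocol never states the PPG sampling rate — 250 Hz is
inferred from the reference stride being "250 samples (1 s)". Records are
bitwise-reproducible from the seed.

What the generator does *not* emulate: motion artifacts, sensor saturation,
inter-patient morphology differences, rhythm transitions within a record, or
asystole (excluded by design). Passing the end-to-end test therefore shows
that the architecture, augmentation and training machinery can learn
rhythm-defining features; it does not certify performance on clinical
recordings.

## Problem sizes used in the shipped experiments

The test suite trains the reduced-width `"small"` preset (50-sample pooled
sequence, 8 bands, ~45k parameters) on 40 records per class of 30 s each:
after the 6:2:2 split and WASW this yields ~2,000 training windows, and 15
epochs at batch 60 reach ≥90% test accuracy and macro-F1 (typically 100%) in
a few CPU-minutes. These sizes are the package's own desk-scale choice; the
full-scale protocol (5-minute records, 160 epochs, the `"paper"` preset) is
expressible with the same configuration objects. A separate property check
verifies the generator is informative: mean inter-peak interval plus dominant
frequency linearly separate bradycardia/tachycardia/VF with at least 95%
accuracy on 50 records per class.

## Numerical choices and degenerate inputs

* Softmax rows are stabilized by row-max subtraction; layer-norm epsilon is
  1e-5; batch-norm momentum 0.9 with running statistics used at inference.
* KL loss treats `0 log 0` as 0 and errors on rows off the simplex beyond
  1e-5.
* Min-max scaling, attention shape mismatches, infeasible wavelet levels,
  too-short filter inputs, zero class counts and non-positive weights all
  raise classed errors rather than propagating NaN.
* Metric cells with zero denominators return `NA` markers, never NaN
  arithmetic.
* The Transformer encoder includes the standard feed-forward sublayer;
  `use_ffn = FALSE` reproduces the literal "attention + residual norm only"
  reading. Ablation switches (`use_residual`, `use_csia`,
  `use_cross_attention`, `branches`) express the usual component-removal
  variants.
* The two printed parameter totals in the reference material (1,461,904 vs
  1,465,175) disagree; the package targets the stated ~1.46 M budget and
  makes no attempt to reproduce either figure exactly.

## Known limitations

Training large configurations in base R is slow (the full `"paper"` preset
at 250 Hz is practical for inference and short fine-tuning, not 160-epoch
training); the generator's four classes are far more separable than clinical
data, so reported synthetic metrics are upper bounds; and the optional
external-data path (WFDB waveform reading) is not implemented because no
WFDB reader exists in the supported dependency set.
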