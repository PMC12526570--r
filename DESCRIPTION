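Package: ppgfusion
Title: Dual-Domain Attention Networks for PPG Arrhythmia Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for four-class arrhythmia classification (bradycardia,
    tachycardia, ventricular tachycardia, ventricular flutter/fibrillation)
    from single-channel photoplethysmography (PPG). Implements a synthetic
    PPG rhythm generator, a signal-conditioning chain (zero-phase Butterworth
    band-pass, moving average, hybrid wavelet/spline baseline correction,
    min-max scaling), record-level stratified splitting with class-weight-aware
    sliding-window augmentation, Welch spectral self-similarity encoding, and a
    dual-branch time/frequency attention network (residual convolutions,
    cross-scale interactive attention, BiLSTM, Transformer encoder, gated
    cross-modal fusion) trained with Adam on a class-weighted
    Kullback-Leibler loss. All network forward and backward passes are
    implemented in base R; no external deep-learning framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    pracma,
    MASS,
    optparse
Config/testthat/edition: 3
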