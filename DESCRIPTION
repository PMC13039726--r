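Package: eegfdf
Title: ICA-Assisted Frequency-Domain Preprocessing and CNN-LSTM Decoding
    for Imagined-Speech EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for decoding imagined speech from multichannel EEG.
    Implements a six-phase preprocessing pipeline that combines independent
    component analysis artifact rejection with a zero-phase frequency-domain
    band-reject filter (4-15 Hz stopband, raised-cosine transition ramps),
    sliding-window segmentation, and train-only z-score normalization; a
    family of five CNN-LSTM sequence classifiers with a pure-R training
    engine (Adam, early stopping, learning-rate reduction on plateau); and
    three leakage-aware cross-validation strategies (multi-seed random
    splits, grouped k-fold, and leave-one-subject-out with per-subject
    calibration) together with a weighted and macro metric suite and the
    effect-size statistics used to compare strategies. A synthetic EEG
    generator with class-discriminative oscillations, physiological
    artifacts, and subject effects makes the full pipeline testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
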