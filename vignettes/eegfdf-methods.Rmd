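---
title: "Methods: frequency-domain preprocessing and CNN-LSTM decoding of imagined-speech EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frequency-domain preprocessing and CNN-LSTM decoding of imagined-speech EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Imagined speech brain-computer interfaces try to decode which word a person
is internally articulating from scalp EEG. Two obstacles dominate: the
signal is buried under physiological artifacts (eye blinks and movements,
muscle activity, line noise) whose power concentrates in the low-frequency
theta/alpha range, and EEG patterns differ so strongly between people that a
classifier trained on one group often fails on a new user. This package
implements a complete decoding toolkit for the canonical 14-channel,
128 Hz, 10-second-epoch recording geometry: a six-phase preprocessing
pipeline, five CNN-LSTM classifier templates, three cross-validation
strategies with very different leakage characteristics, and a synthetic EEG
generator that makes all of it testable without any external data.

## The six-phase preprocessing pipeline

`run_pipeline()` executes the phases in order:

1. **ICA artifact rejection** (`ica_clean()`). The multichannel signal is
   PCA-reduced to the smallest rank explaining at least 99.99% of total
   variance, unmixed into independent components by a FastICA-style
   fixed-point iteration (tanh contrast, symmetric decorrelation), and each
   component is scored by an artifact statistic. Components whose score
   exceeds 2.5 standard deviations of the across-component score
   distribution are zeroed before reconstruction.
2. **FFT** of every channel.
3. **Zero-phase band rejection**: the spectrum is multiplied by a
   raised-cosine band-reject mask with zero gain on 4-15 Hz and 2 Hz
   cosine transition ramps.
4. **Inverse FFT** back to the time domain.
5. **Sliding-window segmentation** (`segment()`), Scheme A (32 samples,
   stride 8, overlapping) or Scheme B (8 samples, stride 8,
   non-overlapping). The count per recording is
   `floor((N_spr - WS) / Stride) + 1`: 157 and 160 windows respectively for
   a 1280-sample trial.
6. **Channel-wise z-scoring** (`fit_normalizer()` / `apply_normalizer()`)
   with mean and standard deviation computed on training windows only and
   reused unchanged on test windows.

### Decisions the pipeline description leaves open

Several details of this recipe are not fixed by the description it follows;
the package resolves them explicitly and exposes each as a parameter.

* **What "2.5 sigma" refers to.** We score each independent component with
  an artifact statistic - the peak amplitude of the component relative to
  its own spread, its excess kurtosis, or the maximum of the two z-scores
  (the default) - and compare the across-component z-score of that
  statistic against the threshold. This is standard automatic IC-rejection
  practice: blinks produce sparse, high-amplitude, high-kurtosis
  components, so either statistic flags them, and the across-component
  distribution provides the sigma.
* **Where "99.99% variance" enters.** The only place a variance-retention
  knob exists naturally in an ICA pipeline is the PCA rank reduction
  before unmixing, so `variance_retained` selects the PCA rank. With the
  rejection threshold set to infinity, `ica_clean()` therefore returns the
  rank-limited PCA projection of its input - a useful identity check.
* **Fit scope.** ICA is fit label-blind per subject by default (all of a
  subject's recordings concatenated), which gives the unmixing estimate
  far more samples than a single 1280-sample trial. Groups with fewer than
  `10 * n_channels^2` samples are skipped with a warning rather than fit
  unstably. Because the fit uses no labels, applying it before the
  train/test split does not leak label information; it does share
  unlabeled test-subject signal statistics, which we consider acceptable
  for an artifact-removal step and note here explicitly.
* **"Forward-backward" filtering.** A real, non-negative frequency-domain
  gain already has zero phase, so the default applies the mask once;
  `fd_application = "squared_gain"` reproduces the magnitude response of a
  literal forward-backward application (the mask squared), which only
  sharpens the transition. Both are exactly zero-phase.
* **Ramp placement.** The transitions lie *outside* the printed stopband
  (on 2-4 Hz and 15-17 Hz), so the whole 4-15 Hz band sits at exactly
  zero gain.
* **Non-divisible window counts.** When `(N_spr - WS)` is not a multiple of
  the stride, trailing samples are dropped (floor convention) - the
  standard sliding-window behaviour, exact for all canonical
  configurations.
* **The time-domain baseline.** The comparison mode `td_bandreject` is a
  zero-phase forward-backward Butterworth band-stop over 4-15 Hz, order 4
  by default (`td_order`), since only the band, not a design, is specified
  for this conventional alternative.
* **Degenerate channels.** A constant channel would make the z-score
  divide by zero; the normalizer clamps standard deviations at
  `sd_floor = 1e-8`.

## The classifier family

`arch_spec()` fixes five structural templates (see its help page for the
exact composition and dropout placement): one to three stacked LSTMs,
optionally bidirectional, behind an optional Conv1D + batch-norm +
max-pooling block, with one or two ReLU dense layers and a softmax output.
The templates fix composition, not width. Since no widths accompany the
templates, the package chooses `paper_default` widths of 64 conv filters
(kernel 3, pool 2), 128/64/32 recurrent units by depth and dense width 64,
and a `tiny` profile (8 filters, 16 units) used throughout the tests; every
width is an explicit argument. Published total-parameter tables for such
templates are not reproduced exactly - they are internally inconsistent
with the stated layer composition (e.g. non-trainable parameters without
any batch-normalization layer) - so `count_parameters()` is instead
verified against closed-form per-layer formulas, and `model_size_mb()`
against the float32 size arithmetic, which does check out
(2,453,590 parameters -> 9.36 MB).

The training engine is written in base R: minibatch Adam
(`lr = 0.001`, `beta1 = 0.9`, `beta2 = 0.999`), categorical cross-entropy,
at most 500 epochs, early stopping on validation loss with patience 30 and
best-weight restoration, learning-rate reduction by 0.1 after 10 stagnant
epochs, batch size 256 (128 for calibration fine-tuning). The validation
split for monitoring is a stratified 10% carve-out of the training windows,
seeded - a definition the training recipe needs but leaves open. Backward
passes for every layer are verified against finite differences in the test
suite. Weight initialization is Glorot-uniform throughout with the LSTM
forget-gate bias initialized to 1; with identical seeds two runs produce
bit-identical histories on the same platform.

## Validation strategies and their leakage

* **Strategy 1, `random_multiseed`**: stratified window-level 90/10 splits
  over seeds {1,...,5}, Scheme A. Overlapping windows from one recording
  can land on both sides, so this deliberately tolerates temporal leakage:
  it is the upper-bound protocol.
* **Strategy 2, `group_kfold`**: stratified 10-fold cross-validation over
  Scheme B windows. The default grouping key is the window itself
  (sample-level grouping: non-overlapping windows share no raw samples);
  recording- and subject-level grouping are offered because the protocol
  description admits several readings. Subject leakage persists by design.
* **Strategy 3, `loso_calibrated`**: one fold per subject; 20% of the
  held-out subject's windows (stratified by class) fine-tune the
  pretrained model, the remaining 80% are test-only.

In paper-faithful mode the grouped strategies refuse overlapping windows,
and `run_strategy()` additionally audits every fold: a test window whose
sample interval overlaps a training window from the same recording is a
hard error. The metric suite (`compute_metrics()`) reports accuracy,
weighted precision, per-class recall, weighted and macro F1, and balanced
accuracy; two identities - support-weighted recall equals accuracy, and
balanced accuracy equals macro recall - are exploited as invariant tests.
Classes with zero support are excluded from macro averages with a warning.

Summary comparisons use the Student-t 95% CI margin
(`t_crit(0.975, n-1) * sd / sqrt(n)`), Welch's t reconstructed from
mean-and-margin summaries, and Cohen's d under two conventions:
`d = t * sqrt(2/n)` for independent equal-n comparisons across seeds and
`d = t / sqrt(n)` for paired per-subject comparisons. Both conventions are
implemented because each reproduces one of the published comparison values
(t = 4.12 with d = 2.61 across 5 seeds; d = 9.54 from t(19) = 42.64 across
20 subjects). Coefficients of variation are `sd / mean`.

## The synthetic generator

`generate_dataset()` emulates the benchmark geometry - by default 20
subjects, the 30-word vocabulary, one 10 s trial of 14 channels at 128 Hz
per subject and class. Each class carries a deterministic template: a
carrier frequency evenly spaced inside `class_band` (default 18-40 Hz) and
a fixed channel-loading vector derived from the class index. Trials mix the
template into pink (1/f) plus white noise - EEG's canonical background
spectrum - at a configurable SNR, then apply per-subject log-normal channel
gains and DC offsets (the simplest mechanism that breaks naive
cross-subject transfer), then inject artifacts: frontal blink pulses,
broadband temporal-channel EMG bursts, sustained 50 Hz line noise, and an
8-12 Hz alpha confound whose amplitude and frequency follow the *subject*,
not the class. The seed fully determines the dataset.

Placing class information at 18-40 Hz makes the 4-15 Hz rejection
information-preserving in the synthetic world; this mirrors the modelling
assumption that theta/alpha carry artifact and subject confound rather than
class signal. Under that construction two orderings become testable
predictions rather than hopes: band rejection should not lose to full-band
input under leave-one-subject-out evaluation when an alpha confound tracks
subject identity, and calibration should help under strong subject gain
shifts. What the generator does *not* emulate: volume conduction from a
head model, non-stationarity within a trial, realistic class overlap, or
correlated channel noise. Passing the end-to-end tests therefore shows the
pipeline's machinery behaves as designed, not that real-data headline
accuracies are reproduced - reproducing those requires the external
benchmark dataset and full-size models, both out of scope here.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at desk scale, a
deliberate package choice: the tiny architecture profile, 6 classes, 3-4
subjects, 2-3 s epochs (256 samples), 25-40 training epochs. At these sizes
a full strategy run takes seconds while every contract - stratification,
leakage audits, train-only normalization, calibration - is exercised
unchanged. Other numerical choices: the FFT mask is applied symmetrically
to the negative frequencies so the inverse transform is exactly real; the
ICA fixed-point iteration caps at 200 iterations with tolerance 1e-6 and a
seeded random orthonormal start; max-pooling ties resolve to the earliest
time step; prediction ties resolve to the first class; batch-norm uses
momentum 0.99 and epsilon 1e-3.

## Known limitations

* The ICA engine separates a strong artifact source cleanly, but when the
  class signal is weak relative to the artifact a rejected component can
  carry a noticeable share of frontal class-band power; separation quality
  degrades with SNR, which is inherent to subspace methods.
* The training engine is CPU-bound pure R. It is exact and deterministic
  but not fast; the paper-default profile at real dataset scale is
  impractical here and is exposed for completeness, not benchmarking.
* EDF support covers the common single-record, uniform-rate layout used by
  the toolkit's own writer; trial annotations (EDF+) are not interpreted.
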