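## Shared fixtures built in code at test time.

## band power of a single channel via the periodogram
bandpower <- function(x, fs, lo, hi) {
  n <- length(x)
  X <- abs(stats::fft(x))^2 / n
  f <- seq(0, n - 1) * fs / n
  sum(X[f >= lo & f <= hi & f <= fs / 2])
}

## artifact-free, strongly separable dataset (used by the training oracles)
separable_dataset <- function(n_subjects = 3, n_classes = 6,
                              trials_per_class = 3, n_samples = 256,
                              snr_db = 20, seed = 7) {
  cfg <- synth_config(
    n_subjects = n_subjects,
    classes = LETTERS[seq_len(n_classes)],
    trials_per_class = trials_per_class, n_samples = n_samples,
    snr_db = snr_db,
    artifact_rates = list(blink = 0, emg = 0, line = 0, alpha_confound = 0),
    subject_gain_sd = 0.05, subject_offset_sd = 0,
    fdf_advantage_scenario = TRUE, seed = seed)
  list(cfg = cfg, ds = generate_dataset(cfg))
}

## a deterministic multi-channel test recording
noise_recording <- function(n_ch = 14, n = 256, fs = 128, seed = 1,
                            subject_id = "S01", sd = 20) {
  set.seed(seed)
  eeg_recording(matrix(stats::rnorm(n_ch * n, sd = sd), n_ch, n), fs = fs,
                subject_id = subject_id)
}

## sinusoidal recording, same waveform on all channels
sine_recording <- function(freq, n = 1280, fs = 128, n_ch = 14) {
  t <- (seq_len(n) - 1) / fs
  eeg_recording(matrix(rep(sin(2 * pi * freq * t), n_ch), n_ch, byrow = TRUE),
                fs = fs)
}

## independent brute-force metric computation: per-sample loops over the
## label pairs implied by a confusion matrix
brute_force_metrics <- function(counts) {
  C <- nrow(counts)
  truth <- integer(0); pred <- integer(0)
  for (i in seq_len(C)) for (j in seq_len(C)) {
    truth <- c(truth, rep(i, counts[i, j]))
    pred <- c(pred, rep(j, counts[i, j]))
  }
  N <- length(truth)
  acc <- sum(truth == pred) / N
  prec <- rec <- f1 <- numeric(C); sup <- numeric(C)
  for (i in seq_len(C)) {
    tp <- sum(truth == i & pred == i)
    fp <- sum(truth != i & pred == i)
    fn <- sum(truth == i & pred != i)
    sup[i] <- sum(truth == i)
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[i] <- if (tp + fn > 0) tp / (tp + fn) else NA
    f1[i] <- if (prec[i] + rec[i] > 0 && !is.na(rec[i]))
      2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  live <- sup > 0
  w <- sup / N
  list(accuracy = acc,
       weighted_precision = sum(w[live] * prec[live]),
       weighted_recall = sum(w[live] * rec[live]),
       macro_f1 = mean(f1[live]),
       weighted_f1 = sum(w[live] * f1[live]),
       balanced_accuracy = mean(rec[live]))
}

## brute-force sliding-window start enumeration
brute_force_window_count <- function(n_samples, ws, stride) {
  count <- 0L
  start <- 1L
  while (start + ws - 1L <= n_samples) {
    count <- count + 1L
    start <- start + stride
  }
  count
}
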