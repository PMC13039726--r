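#' Synthetic dataset configuration
#'
#' Describes an EEG-like dataset with the statistical structure the pipeline
#' assumes: each class carries a deterministic oscillatory template (carrier
#' frequency and channel loading) inside `class_band`, mixed into pink + white
#' background noise at `snr_db`, with per-subject gain/offset effects and
#' optional physiological artifacts. Defaults mirror the benchmark geometry:
#' 14 channels, 10-s epochs at 128 Hz, 30-word vocabulary, one trial per
#' subject and class.
#'
#' @param n_subjects Number of subjects (default 20).
#' @param classes Character vector of class labels; default the 30-item
#'   vocabulary (10 characters, 10 digits, 10 objects).
#' @param trials_per_class Trials per subject and class (default 1).
#' @param fs Sampling rate in Hz (default 128).
#' @param n_samples Samples per trial (default 1280, i.e. 10 s).
#' @param n_channels Number of channels (default 14).
#' @param class_band Frequency range (Hz) holding class information; default
#'   `c(18, 40)`, deliberately outside the 4-15 Hz stopband.
#' @param snr_db Class-signal to background-noise ratio in dB (default 0).
#' @param artifact_rates Named list of per-trial probabilities for
#'   `blink`, `emg`, `line`, `alpha_confound` (defaults 0.7/0.3/0.1/0).
#' @param subject_gain_sd SD of per-subject, per-channel log-normal gain
#'   (default 0.1).
#' @param subject_offset_sd SD of per-subject DC offset in microvolts
#'   (default 2).
#' @param fdf_advantage_scenario If `TRUE`, require `class_band` disjoint
#'   from 4-15 Hz (so the band-reject filter is information-preserving) and
#'   tie the alpha confound's amplitude/frequency to subject identity.
#' @param seed Integer seed; fully determines the dataset.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 20,
                         classes = default_vocabulary(),
                         trials_per_class = 1, fs = 128, n_samples = 1280,
                         n_channels = 14, class_band = c(18, 40),
                         snr_db = 0,
                         artifact_rates = list(blink = 0.7, emg = 0.3,
                                               line = 0.1,
                                               alpha_confound = 0),
                         subject_gain_sd = 0.1, subject_offset_sd = 2,
                         fdf_advantage_scenario = FALSE, seed = 1L) {
  if (length(classes) == 0L) stop("`classes` must be non-empty", call. = FALSE)
  if (class_band[2] >= fs / 2) {
    stop("class_band extends to or beyond the Nyquist frequency", call. = FALSE)
  }
  if (class_band[1] >= class_band[2]) stop("invalid class_band", call. = FALSE)
  if (fdf_advantage_scenario &&
      class_band[1] < 15 && class_band[2] > 4) {
    stop("class_band must not intersect [4, 15] Hz in the FD-F advantage scenario",
         call. = FALSE)
  }
  defaults <- list(blink = 0.7, emg = 0.3, line = 0.1, alpha_confound = 0)
  defaults[names(artifact_rates)] <- artifact_rates
  structure(
    list(n_subjects = as.integer(n_subjects), classes = as.character(classes),
         trials_per_class = as.integer(trials_per_class), fs = fs,
         n_samples = as.integer(n_samples),
         n_channels = as.integer(n_channels),
         class_band = class_band, snr_db = snr_db,
         artifact_rates = defaults,
         subject_gain_sd = subject_gain_sd,
         subject_offset_sd = subject_offset_sd,
         fdf_advantage_scenario = isTRUE(fdf_advantage_scenario),
         seed = as.integer(seed)),
    class = "synth_config")
}

#' The 30-item imagined-speech vocabulary
#' @return Character vector: 10 characters, 10 digits, 10 object words.
#' @export
default_vocabulary <- function() {
  c("A", "C", "F", "H", "J", "M", "P", "S", "T", "Y",
    as.character(0:9),
    "Apple", "Car", "Dog", "Gold", "Mobile", "Rose", "Scooter", "Tiger",
    "Wallet", "Watch")
}

vocab_category <- function(label) {
  chars <- c("A", "C", "F", "H", "J", "M", "P", "S", "T", "Y")
  if (label %in% chars) "characters"
  else if (label %in% as.character(0:9)) "digits"
  else "objects"
}

#' Deterministic class templates
#'
#' Each class gets a carrier frequency evenly spaced inside `class_band` and
#' a fixed channel-loading vector derived from the class index alone (no
#' randomness), so oracle classifiers can be built from the generator's own
#' templates.
#'
#' @param config A `synth_config`.
#' @return List with one element per class: `list(freq, loading)`.
#' @export
class_templates <- function(config) {
  C <- length(config$classes)
  lo <- config$class_band[1]; hi <- config$class_band[2]
  lapply(seq_len(C), function(c_idx) {
    freq <- lo + (c_idx - 0.5) * (hi - lo) / C
    j <- seq_len(config$n_channels)
    loading <- 0.3 + 0.7 * abs(sin(pi * c_idx * j / (config$n_channels + 1)))
    list(freq = freq, loading = loading / sqrt(mean(loading^2)))
  })
}

#' 1/f (pink) noise
#' @param n Number of samples.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector with unit standard deviation.
#' @keywords internal
pink_noise <- function(n, fs) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- seq(0, n - 1) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]
  scale <- 1 / sqrt(pmax(f, 0.5))
  x <- Re(stats::fft(W * scale, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Construct an artifact event
#'
#' @param kind One of `"blink"`, `"emg"`, `"line_noise"`, `"alpha_confound"`.
#' @param channels Channel names affected.
#' @param onset 1-based onset sample.
#' @param duration Duration in samples.
#' @param amplitude Peak amplitude in microvolts.
#' @param freq Oscillation frequency in Hz (line noise and alpha only).
#' @return An object of class `artifact_event`.
#' @export
artifact_event <- function(kind, channels, onset, duration, amplitude,
                           freq = NA_real_) {
  kind <- match.arg(kind, c("blink", "emg", "line_noise", "alpha_confound"))
  if (kind == "blink" && !all(channels %in% frontal_channels())) {
    stop("blink events are restricted to frontal channels", call. = FALSE)
  }
  if (kind == "alpha_confound" && (is.na(freq) || freq < 8 || freq > 12)) {
    stop("alpha confound frequency must lie in 8-12 Hz", call. = FALSE)
  }
  if (kind == "line_noise") freq <- 50
  structure(list(kind = kind, channels = channels, onset = as.integer(onset),
                 duration = as.integer(duration), amplitude = amplitude,
                 freq = freq),
            class = "artifact_event")
}

## time-domain waveform of one event over its support
event_waveform <- function(ev, fs) {
  t <- (seq_len(ev$duration) - 1) / fs
  switch(ev$kind,
    blink = ev$amplitude * sin(pi * seq_len(ev$duration) / ev$duration)^2,
    emg = {
      hf <- stats::rnorm(ev$duration)
      b <- signal::butter(4, 25 / (fs / 2), type = "high")
      w <- as.numeric(signal::filtfilt(b, hf))
      ev$amplitude * w / max(abs(w))
    },
    line_noise = ev$amplitude * sin(2 * pi * ev$freq * t),
    alpha_confound = ev$amplitude * sin(2 * pi * ev$freq * t))
}

#' Inject artifact events into a recording
#'
#' Additive superposition; the input recording is not modified.
#'
#' @param recording An `eeg_recording`.
#' @param events List of `artifact_event`s.
#' @return A new `eeg_recording` with the events added.
#' @export
inject_artifacts <- function(recording, events) {
  stopifnot(inherits(recording, "eeg_recording"))
  data <- recording$data
  for (ev in events) {
    stopifnot(inherits(ev, "artifact_event"))
    if (ev$onset < 1L || ev$onset + ev$duration - 1L > ncol(data)) {
      stop("artifact event exceeds recording bounds", call. = FALSE)
    }
    idx <- ev$onset:(ev$onset + ev$duration - 1L)
    wf <- event_waveform(ev, recording$fs)
    rows <- match(ev$channels, recording$channel_names)
    if (anyNA(rows)) stop("event names unknown channels", call. = FALSE)
    for (r in rows) data[r, idx] <- data[r, idx] + wf
  }
  out <- recording
  out$data <- data
  out
}

sample_events <- function(config, subject_idx, montage) {
  rates <- config$artifact_rates
  n <- config$n_samples; fs <- config$fs
  events <- list()
  if (stats::runif(1) < rates$blink) {
    dur <- min(as.integer(round(stats::runif(1, 0.5, 1.0) * fs)), n - 1L)
    onset <- sample.int(n - dur + 1L, 1)
    events[[length(events) + 1L]] <- artifact_event(
      "blink", intersect(frontal_channels(), montage), onset, dur,
      amplitude = stats::runif(1, 80, 150))
  }
  if (stats::runif(1) < rates$emg) {
    dur <- min(as.integer(round(stats::runif(1, 0.5, 1.5) * fs)), n - 1L)
    onset <- sample.int(n - dur + 1L, 1)
    ch <- intersect(c("T7", "T8", "FC5", "FC6"), montage)
    events[[length(events) + 1L]] <- artifact_event(
      "emg", ch, onset, dur, amplitude = stats::runif(1, 15, 30))
  }
  if (stats::runif(1) < rates$line) {
    events[[length(events) + 1L]] <- artifact_event(
      "line_noise", montage, 1L, n, amplitude = stats::runif(1, 3, 8))
  }
  if (stats::runif(1) < rates$alpha_confound) {
    ## amplitude and frequency are functions of the SUBJECT, not the class:
    ## a subject-identity confound that full-band models can exploit
    s <- subject_idx
    freq <- 8 + 4 * ((s - 1) %% config$n_subjects) /
      max(config$n_subjects - 1, 1)
    amp <- 10 + 15 * ((s * 7) %% config$n_subjects) /
      max(config$n_subjects - 1, 1)
    events[[length(events) + 1L]] <- artifact_event(
      "alpha_confound", montage, 1L, n, amplitude = amp, freq = freq)
  }
  events
}

#' Generate a synthetic EEG dataset
#'
#' @param config A `synth_config`.
#' @return List with elements `manifest` (an `eeg_manifest`), `recordings`
#'   (list of `eeg_recording`), and `ground_truth` (list of injected
#'   `artifact_event`s, named by recording id).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  montage <- if (config$n_channels == 14L) default_montage() else
    paste0("ch", seq_len(config$n_channels))
  templates <- class_templates(config)
  amp <- template_amplitude(config, templates)

  gains <- matrix(exp(stats::rnorm(config$n_subjects * config$n_channels,
                                   sd = config$subject_gain_sd)),
                  nrow = config$n_subjects)
  offsets <- matrix(stats::rnorm(config$n_subjects * config$n_channels,
                                 sd = config$subject_offset_sd),
                    nrow = config$n_subjects)

  recs <- list(); rows <- list(); truth <- list()
  k <- 0L
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("S%02d", s)
    for (c_idx in seq_along(config$classes)) {
      for (tr in seq_len(config$trials_per_class)) {
        k <- k + 1L
        rid <- sprintf("%s_c%02d_t%02d", sid, c_idx, tr)
        tpl <- templates[[c_idx]]
        tt <- (seq_len(config$n_samples) - 1) / config$fs
        phase <- stats::runif(1, 0, 2 * pi)
        carrier <- sin(2 * pi * tpl$freq * tt + phase)
        sig <- amp * tpl$loading %o% carrier
        noise <- t(vapply(seq_len(config$n_channels), function(j) {
          0.8 * pink_noise(config$n_samples, config$fs) +
            0.6 * stats::rnorm(config$n_samples)
        }, numeric(config$n_samples)))
        data <- (sig + noise) * gains[s, ] + offsets[s, ]
        rec <- eeg_recording(data, fs = config$fs, subject_id = sid,
                             class_label = config$classes[c_idx],
                             category = vocab_category(config$classes[c_idx]),
                             channel_names = montage, recording_id = rid)
        events <- sample_events(config, s, montage)
        if (length(events) > 0L) rec <- inject_artifacts(rec, events)
        recs[[k]] <- rec
        truth[[rid]] <- events
        rows[[k]] <- data.frame(recording_id = rid, subject_id = sid,
                                class_label = config$classes[c_idx],
                                category = vocab_category(config$classes[c_idx]),
                                stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- eeg_manifest(do.call(rbind, rows),
                           class_universe = config$classes,
                           subject_universe = sprintf("S%02d",
                                                      seq_len(config$n_subjects)))
  list(manifest = manifest, recordings = recs, ground_truth = truth)
}

## carrier amplitude achieving snr_db against the unit-variance-ish
## pink+white background (variance 0.8^2 + 0.6^2 = 1)
template_amplitude <- function(config, templates) {
  noise_var <- 0.8^2 + 0.6^2
  mean_load2 <- mean(vapply(templates, function(t) mean(t$loading^2), 0))
  sqrt(2 * noise_var * 10^(config$snr_db / 10) / mean_load2)
}

#' Matched-filter oracle classifier
#'
#' Classifies recordings by projecting each channel onto the generator's
#' class carriers (quadrature, so phase-invariant) and weighting by the
#' class channel loadings. Used as an independent oracle for the synthetic
#' generator, never as the package's classifier.
#'
#' @param recordings List of `eeg_recording`.
#' @param config The `synth_config` that generated them.
#' @return Character vector of predicted class labels.
#' @export
matched_filter_classify <- function(recordings, config) {
  templates <- class_templates(config)
  vapply(recordings, function(rec) {
    tt <- (seq_len(ncol(rec$data)) - 1) / rec$fs
    scores <- vapply(seq_along(templates), function(ci) {
      tpl <- templates[[ci]]
      cs <- cos(2 * pi * tpl$freq * tt); sn <- sin(2 * pi * tpl$freq * tt)
      pow <- (rec$data %*% cs)^2 + (rec$data %*% sn)^2
      sum(tpl$loading * sqrt(pow))
    }, 0)
    config$classes[which.max(scores)]
  }, "")
}
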