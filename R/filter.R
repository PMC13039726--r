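#' Band-reject filter specification
#'
#' Defines the preprocessing mode: `fd_bandreject` is the frequency-domain
#' zero-phase band-reject filter (the pipeline's own method), `td_bandreject`
#' is the conventional time-domain Butterworth band-stop baseline, and
#' `full_band` is the identity (no filtering).
#'
#' The frequency-domain gain is 1 up to `stop_lo - ramp`, descends along a
#' raised cosine to 0 at `stop_lo`, stays 0 through `stop_hi`, and rises back
#' to 1 at `stop_hi + ramp`; the transitions therefore lie outside the
#' printed stopband, which is attenuated to exactly zero gain.
#'
#' @param mode `"fd_bandreject"`, `"td_bandreject"`, or `"full_band"`.
#' @param stop_lo,stop_hi Stopband edges in Hz (defaults 4 and 15).
#' @param ramp Transition width in Hz (default 2).
#' @param fd_application `"single_pass"` (a real non-negative mask is already
#'   zero-phase) or `"squared_gain"` (the magnitude response of a literal
#'   forward-backward application).
#' @param td_order Butterworth order for the time-domain baseline (default 4).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(mode = c("fd_bandreject", "td_bandreject",
                                 "full_band"),
                        stop_lo = 4, stop_hi = 15, ramp = 2,
                        fd_application = c("single_pass", "squared_gain"),
                        td_order = 4) {
  mode <- match.arg(mode)
  fd_application <- match.arg(fd_application)
  if (stop_lo >= stop_hi) stop("stop_lo must be < stop_hi", call. = FALSE)
  if (stop_lo - ramp < 0) stop("ramp extends below 0 Hz", call. = FALSE)
  structure(list(mode = mode, stop_lo = stop_lo, stop_hi = stop_hi,
                 ramp = ramp, fd_application = fd_application,
                 td_order = as.integer(td_order)),
            class = "filter_spec")
}

#' Design the frequency-domain band-reject gain mask
#'
#' Evaluates the raised-cosine band-reject gain on the non-negative frequency
#' grid of an `n_samples`-point real FFT at sampling rate `fs`.
#'
#' @param spec A `filter_spec` with `mode == "fd_bandreject"`.
#' @param n_samples Signal length in samples.
#' @param fs Sampling rate in Hz.
#' @return Numeric gain vector of length `floor(n_samples/2) + 1`, in
#'   `[0, 1]`, named with the frequencies in Hz.
#' @export
design_fd_mask <- function(spec, n_samples, fs) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$mode != "fd_bandreject") {
    stop("design_fd_mask requires mode fd_bandreject", call. = FALSE)
  }
  if (spec$stop_hi + spec$ramp >= fs / 2) {
    stop("upper transition ramp reaches the Nyquist frequency", call. = FALSE)
  }
  f <- seq(0, floor(n_samples / 2)) * fs / n_samples
  gain <- fd_gain(f, spec)
  names(gain) <- format(f, trim = TRUE)
  gain
}

## raised-cosine band-reject gain at frequencies f (vectorized)
fd_gain <- function(f, spec) {
  lo <- spec$stop_lo; hi <- spec$stop_hi; r <- spec$ramp
  g <- numeric(length(f)) + 1
  desc <- f > lo - r & f < lo
  g[desc] <- 0.5 * (1 + cos(pi * (f[desc] - (lo - r)) / r))
  g[f >= lo & f <= hi] <- 0
  asc <- f > hi & f < hi + r
  g[asc] <- 0.5 * (1 - cos(pi * (f[asc] - hi) / r))
  if (spec$fd_application == "squared_gain") g <- g^2
  g
}

#' Apply a band-reject filter to a recording
#'
#' `fd_bandreject`: each channel is transformed with a real FFT, multiplied
#' by the raised-cosine mask (applied symmetrically to the negative
#' frequencies so the output is real), and inverse-transformed. The mask is
#' real and non-negative, so the operation is exactly zero-phase.
#' `td_bandreject`: zero-phase forward-backward Butterworth band-stop.
#' `full_band`: identity.
#'
#' @param recording An `eeg_recording`.
#' @param spec A `filter_spec`.
#' @return Filtered `eeg_recording` of identical length.
#' @export
apply_filter <- function(recording, spec) {
  stopifnot(inherits(recording, "eeg_recording"), inherits(spec, "filter_spec"))
  if (spec$mode == "full_band") return(recording)
  out <- recording
  n <- n_samples(recording)
  if (spec$mode == "fd_bandreject") {
    gain_half <- design_fd_mask(spec, n, recording$fs)
    full <- full_mask_from_half(gain_half, n)
    out$data <- t(apply(recording$data, 1, function(x) {
      Re(stats::fft(stats::fft(x) * full, inverse = TRUE)) / n
    }))
  } else {
    wn <- c(spec$stop_lo, spec$stop_hi) / (recording$fs / 2)
    b <- signal::butter(spec$td_order, wn, type = "stop")
    out$data <- t(apply(recording$data, 1, function(x)
      as.numeric(signal::filtfilt(b, x))))
  }
  rownames(out$data) <- recording$channel_names
  out
}

## extend a non-negative-frequency mask to the full FFT grid using real
## spectrum symmetry (bin k mirrors bin n - k; DC and Nyquist are unique)
full_mask_from_half <- function(gain_half, n) {
  full <- numeric(n)
  half_len <- length(gain_half)
  full[seq_len(half_len)] <- gain_half
  if (n >= 3) {
    idx <- 2:ceiling(n / 2)
    full[n - idx + 2] <- full[idx]
  }
  full
}
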