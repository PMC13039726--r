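#' Windowing scheme
#'
#' Scheme A: overlapping windows of 32 samples (250 ms at 128 Hz) with
#' stride 8. Scheme B: non-overlapping windows of 8 samples (62.5 ms) with
#' stride 8, used by the leakage-aware validation strategies because its
#' windows never share raw samples.
#'
#' @param name `"A"`, `"B"`, or `"custom"`.
#' @param ws Window size in samples (fixed by name for A and B).
#' @param stride Stride in samples.
#' @return An object of class `windowing_scheme`.
#' @export
windowing_scheme <- function(name = c("A", "B", "custom"), ws = NULL,
                             stride = NULL) {
  name <- match.arg(name)
  if (name == "A") { ws <- 32L; stride <- 8L }
  if (name == "B") { ws <- 8L; stride <- 8L }
  if (is.null(ws) || is.null(stride)) {
    stop("custom scheme requires ws and stride", call. = FALSE)
  }
  ws <- as.integer(ws); stride <- as.integer(stride)
  if (stride <= 0L || ws <= 0L || stride > ws) {
    stop("require 0 < stride <= ws", call. = FALSE)
  }
  structure(list(name = name, ws = ws, stride = stride),
            class = "windowing_scheme")
}

#' Number of windows per recording
#'
#' `floor((n_samples - ws) / stride) + 1`; trailing samples that cannot fill
#' a complete window are dropped. For the canonical 1280-sample trials this
#' gives 157 windows under Scheme A and 160 under Scheme B.
#'
#' @param n_samples Samples per recording.
#' @param scheme A `windowing_scheme`.
#' @return Integer window count.
#' @export
window_count <- function(n_samples, scheme) {
  if (scheme$ws > n_samples) {
    stop("window size exceeds recording length", call. = FALSE)
  }
  as.integer((n_samples - scheme$ws) %/% scheme$stride + 1L)
}

#' Construct a window set
#' @keywords internal
window_set <- function(windows, labels, class_universe, subject_ids,
                       recording_ids, starts, scheme, normalized = FALSE) {
  n <- dim(windows)[1]
  stopifnot(length(labels) == n, length(subject_ids) == n,
            length(recording_ids) == n, length(starts) == n)
  structure(list(windows = windows,
                 labels = factor(labels, levels = class_universe),
                 subject_ids = as.character(subject_ids),
                 recording_ids = as.character(recording_ids),
                 starts = as.integer(starts),
                 scheme = scheme, normalized = normalized),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf(
    "<window_set> %d windows of %d samples x %d channels (scheme %s%s)\n",
    d[1], d[2], d[3], x$scheme$name,
    if (x$normalized) ", normalized" else ""))
  invisible(x)
}

n_windows <- function(ws) dim(ws$windows)[1]

#' Segment recordings into windows
#'
#' Windows start at samples 1, 1+stride, 1+2*stride, ... and never cross a
#' recording boundary. Class, subject, and recording provenance is replicated
#' onto every window.
#'
#' @param recordings List of `eeg_recording`.
#' @param scheme A `windowing_scheme`.
#' @param class_universe Ordered class labels; defaults to sorted unique
#'   labels among the recordings.
#' @return A `window_set` with windows of shape `[N, ws, n_channels]`.
#' @export
segment <- function(recordings, scheme, class_universe = NULL) {
  stopifnot(length(recordings) > 0L, inherits(scheme, "windowing_scheme"))
  if (is.null(class_universe)) {
    class_universe <- sort(unique(vapply(recordings, `[[`, "", "class_label")))
  }
  per_rec <- lapply(seq_along(recordings), function(i) {
    rec <- recordings[[i]]
    n <- n_samples(rec)
    if (scheme$ws > n) {
      stop(sprintf("recording %s is shorter (%d) than the window size (%d)",
                   rec$recording_id, n, scheme$ws), call. = FALSE)
    }
    starts <- seq.int(1L, n - scheme$ws + 1L, by = scheme$stride)
    rid <- if (is.na(rec$recording_id)) sprintf("rec%04d", i) else
      rec$recording_id
    w <- array(0, dim = c(length(starts), scheme$ws, n_channels(rec)))
    for (k in seq_along(starts)) {
      w[k, , ] <- t(rec$data[, starts[k]:(starts[k] + scheme$ws - 1L)])
    }
    list(w = w, n = length(starts), label = rec$class_label,
         subject = rec$subject_id, rid = rid, starts = starts)
  })
  total <- sum(vapply(per_rec, `[[`, 0L, "n"))
  nc <- n_channels(recordings[[1]])
  windows <- array(0, dim = c(total, scheme$ws, nc))
  labels <- character(total); subjects <- character(total)
  rids <- character(total); starts <- integer(total)
  at <- 0L
  for (p in per_rec) {
    idx <- at + seq_len(p$n)
    windows[idx, , ] <- p$w
    labels[idx] <- p$label; subjects[idx] <- p$subject
    rids[idx] <- p$rid; starts[idx] <- p$starts
    at <- at + p$n
  }
  window_set(windows, labels, class_universe, subjects, rids, starts, scheme)
}

#' Subset a window set
#' @param ws A `window_set`.
#' @param idx Integer or logical index over windows.
#' @return A `window_set` containing the selected windows.
#' @export
subset_windows <- function(ws, idx) {
  window_set(ws$windows[idx, , , drop = FALSE],
             as.character(ws$labels[idx]), levels(ws$labels),
             ws$subject_ids[idx], ws$recording_ids[idx], ws$starts[idx],
             ws$scheme, ws$normalized)
}

#' Fit channel-wise normalization statistics on training windows
#'
#' Mean and standard deviation per channel, pooled over all training windows
#' and timepoints (population convention, divisor `n`). Statistics must be
#' computed on training data only and reused unchanged on test data.
#'
#' @param train A non-normalized `window_set`.
#' @param sd_floor Lower clamp for the standard deviation (default 1e-8),
#'   guarding constant channels.
#' @return An object of class `norm_stats` with per-channel `mean` and `sd`.
#' @export
fit_normalizer <- function(train, sd_floor = 1e-8) {
  stopifnot(inherits(train, "window_set"))
  if (n_windows(train) == 0L) stop("cannot fit normalizer on an empty window set",
                                   call. = FALSE)
  if (train$normalized) stop("window set is already normalized", call. = FALSE)
  nc <- dim(train$windows)[3]
  mu <- numeric(nc); sdv <- numeric(nc)
  for (j in seq_len(nc)) {
    v <- as.numeric(train$windows[, , j])
    mu[j] <- mean(v)
    sdv[j] <- sqrt(mean((v - mu[j])^2))
  }
  structure(list(mean = mu, sd = pmax(sdv, sd_floor), sd_floor = sd_floor),
            class = "norm_stats")
}

#' Apply normalization statistics to a window set
#'
#' `(x - mean) / sd` per channel using the supplied training statistics; the
#' statistics are never refit on the argument, so a shifted test set keeps
#' its shift.
#'
#' @param stats A `norm_stats` fit on training windows.
#' @param ws A non-normalized `window_set`.
#' @return The normalized `window_set`.
#' @export
apply_normalizer <- function(stats, ws) {
  stopifnot(inherits(stats, "norm_stats"), inherits(ws, "window_set"))
  if (ws$normalized) {
    stop("window set is already normalized (double-normalization guard)",
         call. = FALSE)
  }
  nc <- dim(ws$windows)[3]
  if (length(stats$mean) != nc) {
    stop("channel count mismatch between statistics and windows", call. = FALSE)
  }
  out <- ws
  for (j in seq_len(nc)) {
    out$windows[, , j] <- (ws$windows[, , j] - stats$mean[j]) / stats$sd[j]
  }
  out$normalized <- TRUE
  out
}
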