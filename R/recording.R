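#' Default 14-channel montage
#'
#' Electrode names of the 14-channel wireless headset montage (international
#' 10-20 positions) that the toolkit assumes by default.
#'
#' @return Character vector of 14 channel names.
#' @export
default_montage <- function() {
  c("AF3", "AF4", "F3", "F4", "F7", "F8", "FC5", "FC6",
    "T7", "T8", "P7", "P8", "O1", "O2")
}

#' Frontal channels eligible for ocular artifacts
#' @keywords internal
frontal_channels <- function() c("AF3", "AF4", "F3", "F4", "F7", "F8")

#' Construct an EEG recording
#'
#' A recording is one trial from one subject: a channels x samples matrix of
#' microvolt values plus its sampling rate and labels. The canonical layout
#' is 14 channels x 1280 samples (10 s at 128 Hz).
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in Hz (canonical value 128).
#' @param subject_id Subject identifier (coerced to character).
#' @param class_label Class label, one of the vocabulary items.
#' @param category One of `"characters"`, `"digits"`, `"objects"`.
#' @param channel_names Ordered channel names; defaults to [default_montage()]
#'   when the matrix has 14 rows, else `"ch1"`, `"ch2"`, ...
#' @param recording_id Optional unique identifier.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs = 128, subject_id = "S01",
                          class_label = "A", category = "characters",
                          channel_names = NULL, recording_id = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric matrix (channels x samples)", call. = FALSE)
  }
  if (any(!is.finite(data))) {
    stop("recording data contains non-finite values", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  category <- match.arg(category, c("characters", "digits", "objects"))
  if (is.null(channel_names)) {
    channel_names <- if (nrow(data) == 14L) default_montage() else
      paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_names) != nrow(data)) {
    stop(sprintf("channel_names has length %d but data has %d channels",
                 length(channel_names), nrow(data)), call. = FALSE)
  }
  rownames(data) <- channel_names
  structure(
    list(data = data, fs = fs,
         subject_id = as.character(subject_id),
         class_label = as.character(class_label),
         category = category,
         channel_names = channel_names,
         recording_id = if (is.null(recording_id)) NA_character_ else
           as.character(recording_id)),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> subject %s, class %s (%s)\n  %d channels x %d samples @ %g Hz\n",
    x$subject_id, x$class_label, x$category,
    nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

n_channels <- function(rec) nrow(rec$data)
n_samples <- function(rec) ncol(rec$data)

#' Read a recording from a plain CSV matrix
#'
#' The on-disk orientation is never guessed: `layout` states whether channels
#' are rows or columns, and the matrix is normalized to channels x samples in
#' memory.
#'
#' @param path Path to a headerless numeric CSV.
#' @param layout `"channels_as_rows"` or `"channels_as_columns"`.
#' @param fs Sampling rate in Hz.
#' @param subject_id,class_label,category Metadata carried into the recording.
#' @param channel_names Optional channel names overriding the default montage.
#' @param delim Field delimiter, default `","`.
#' @inheritParams eeg_recording
#' @return An `eeg_recording`.
#' @export
read_recording_csv <- function(path,
                               layout = c("channels_as_rows",
                                          "channels_as_columns"),
                               fs = 128, subject_id = "S01", class_label = "A",
                               category = "characters", channel_names = NULL,
                               recording_id = NULL, delim = ",") {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = delim, header = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  m <- suppressWarnings(vapply(raw, as.numeric, numeric(nrow(raw))))
  if (nrow(raw) == 1L) m <- matrix(m, nrow = 1L)
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric or non-finite cell at row %d, column %d of %s",
                 bad[1, 1], bad[1, 2], path), call. = FALSE)
  }
  if (layout == "channels_as_columns") m <- t(m)
  n_ch <- if (is.null(channel_names)) 14L else length(channel_names)
  if (nrow(m) != n_ch) {
    stop(sprintf(
      "matrix in %s has %d channels after orientation but montage declares %d",
      path, nrow(m), n_ch), call. = FALSE)
  }
  eeg_recording(m, fs = fs, subject_id = subject_id,
                class_label = class_label, category = category,
                channel_names = channel_names, recording_id = recording_id)
}

#' Write a recording to CSV
#'
#' @param rec An `eeg_recording`.
#' @param path Output path.
#' @param layout Orientation on disk; see [read_recording_csv()].
#' @param digits Significant digits written, default 15 (round-trips doubles).
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path,
                                layout = c("channels_as_rows",
                                           "channels_as_columns"),
                                digits = 15) {
  layout <- match.arg(layout)
  stopifnot(inherits(rec, "eeg_recording"))
  m <- rec$data
  if (layout == "channels_as_columns") m <- t(m)
  utils::write.table(format(m, digits = digits, trim = TRUE,
                            scientific = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
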