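## Minimal EDF (European Data Format) I/O.
## Layout: 256-byte fixed header, then 256 bytes of per-signal header fields
## (each field stored contiguously for all ns signals), then data records of
## little-endian int16 samples. Physical values are recovered linearly from
## the digital range declared per signal.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) edf_pad(format(x, scientific = FALSE), width)

#' Write a recording to an EDF file
#'
#' Encodes the recording as one EDF data record of little-endian 16-bit
#' integers, with the physical range set to the observed per-channel range
#' (so quantization error is at most half of range/65535).
#'
#' @param rec An `eeg_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- n_channels(rec)
  nspr <- n_samples(rec)
  duration <- nspr / rec$fs
  dig_min <- -32768; dig_max <- 32767

  phys_min <- apply(rec$data, 1, min)
  phys_max <- apply(rec$data, 1, max)
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_min[flat] + 1  # avoid degenerate scaling

  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  writeChar(paste0(
    edf_pad("0", 8), edf_pad("X", 80), edf_pad("eegfdf synthetic", 80),
    edf_pad("01.01.26", 8), edf_pad("00.00.00", 8),
    edf_num(hdr_bytes, 8), edf_pad("", 44),
    edf_num(1, 8), edf_num(duration, 8), edf_num(ns, 4)),
    con, eos = NULL)
  fields <- list(
    vapply(rec$channel_names, edf_pad, "", width = 16),
    rep(edf_pad("", 80), ns),
    rep(edf_pad("uV", 8), ns),
    vapply(phys_min, function(v) edf_pad(formatC(v, digits = 6, format = "g"), 8), ""),
    vapply(phys_max, function(v) edf_pad(formatC(v, digits = 6, format = "g"), 8), ""),
    rep(edf_num(dig_min, 8), ns),
    rep(edf_num(dig_max, 8), ns),
    rep(edf_pad("", 80), ns),
    rep(edf_num(nspr, 8), ns),
    rep(edf_pad("", 32), ns))
  for (f in fields) writeChar(paste0(f, collapse = ""), con, eos = NULL)

  ## re-parse the headers we just wrote so reader and writer share the exact
  ## truncated physical range
  pmin_hdr <- as.numeric(vapply(phys_min, function(v)
    formatC(v, digits = 6, format = "g"), ""))
  pmax_hdr <- as.numeric(vapply(phys_max, function(v)
    formatC(v, digits = 6, format = "g"), ""))
  for (i in seq_len(ns)) {
    scale <- (dig_max - dig_min) / (pmax_hdr[i] - pmin_hdr[i])
    dig <- round((rec$data[i, ] - pmin_hdr[i]) * scale) + dig_min
    dig <- pmin(pmax(dig, dig_min), dig_max)
    writeBin(as.integer(dig), con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf_field <- function(con, width, ns) {
  vapply(seq_len(ns), function(i)
    trimws(readChar(con, width, useBytes = TRUE)), "")
}

#' Read recordings from an EDF/EDF+ file
#'
#' Returns one recording covering the file (trial annotations are not
#' interpreted). The sampling rate is taken from the header; channel names
#' come from the signal labels.
#'
#' @param path Path to an EDF file.
#' @param subject_id,class_label,category Metadata attached to the result.
#' @return List of `eeg_recording` objects (length one).
#' @export
read_recording_edf <- function(path, subject_id = "S01", class_label = "A",
                               category = "characters") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  version <- trimws(readChar(con, 8, useBytes = TRUE))
  if (!nzchar(version)) stop("unreadable EDF header in ", path, call. = FALSE)
  invisible(readChar(con, 80 + 80 + 8 + 8, useBytes = TRUE))
  hdr_bytes <- suppressWarnings(as.integer(trimws(readChar(con, 8))))
  invisible(readChar(con, 44, useBytes = TRUE))
  n_rec <- suppressWarnings(as.integer(trimws(readChar(con, 8))))
  duration <- suppressWarnings(as.numeric(trimws(readChar(con, 8))))
  ns <- suppressWarnings(as.integer(trimws(readChar(con, 4))))
  if (anyNA(c(hdr_bytes, n_rec, duration, ns)) || ns < 1L) {
    stop("unreadable EDF header in ", path, call. = FALSE)
  }
  labels <- read_edf_field(con, 16, ns)
  invisible(readChar(con, 80 * ns, useBytes = TRUE))
  invisible(readChar(con, 8 * ns, useBytes = TRUE))
  phys_min <- as.numeric(read_edf_field(con, 8, ns))
  phys_max <- as.numeric(read_edf_field(con, 8, ns))
  dig_min <- as.numeric(read_edf_field(con, 8, ns))
  dig_max <- as.numeric(read_edf_field(con, 8, ns))
  invisible(readChar(con, 80 * ns, useBytes = TRUE))
  spr <- as.integer(read_edf_field(con, 8, ns))
  invisible(readChar(con, 32 * ns, useBytes = TRUE))

  if (length(unique(spr)) != 1L) {
    stop("unsupported EDF: signals have heterogeneous sampling rates",
         call. = FALSE)
  }
  fs <- spr[1] / duration
  data <- matrix(0, nrow = ns, ncol = spr[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      phys <- phys_min[i] +
        (dig - dig_min[i]) * (phys_max[i] - phys_min[i]) /
          (dig_max[i] - dig_min[i])
      data[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
    }
  }
  list(eeg_recording(data, fs = fs, subject_id = subject_id,
                     class_label = class_label, category = category,
                     channel_names = labels))
}
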