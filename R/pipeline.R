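#' Run the six-phase preprocessing pipeline
#'
#' Executes, in order: (1) ICA artifact rejection (optional, label-blind),
#' (2-4) the frequency- or time-domain band-reject filter (FFT, mask, IFFT
#' for the frequency-domain mode), (5) sliding-window segmentation, and
#' (6) channel-wise z-score normalization with statistics fit on the
#' training windows only.
#'
#' @param manifest An `eeg_manifest` covering `recordings`.
#' @param recordings List of `eeg_recording` in manifest order.
#' @param split List with character vectors `train` and `test` of recording
#'   ids; must partition the manifest disjointly.
#' @param filter A `filter_spec` (default the 4-15 Hz frequency-domain
#'   band-reject).
#' @param scheme A `windowing_scheme` (default Scheme A).
#' @param ica An `ica_config`, or `NULL` to disable ICA.
#' @param sd_floor Normalizer SD clamp.
#' @return List with `train` and `test` normalized `window_set`s, the fitted
#'   `norm_stats`, and a `report` (per-phase timings, ICA rejection count,
#'   window counts).
#' @export
run_pipeline <- function(manifest, recordings, split,
                         filter = filter_spec("fd_bandreject"),
                         scheme = windowing_scheme("A"),
                         ica = NULL, sd_floor = 1e-8) {
  stopifnot(inherits(manifest, "eeg_manifest"))
  rids <- manifest$recording_id
  if (length(recordings) != length(rids)) {
    stop("recordings and manifest lengths differ", call. = FALSE)
  }
  for (i in seq_along(recordings)) {
    if (is.na(recordings[[i]]$recording_id)) {
      recordings[[i]]$recording_id <- rids[i]
    }
  }
  if (length(intersect(split$train, split$test)) > 0L) {
    stop("split is not disjoint: ",
         intersect(split$train, split$test)[1], call. = FALSE)
  }
  if (!setequal(c(split$train, split$test), rids)) {
    stop("split does not cover all recordings", call. = FALSE)
  }

  timings <- c(); report <- list()

  t0 <- proc.time()[3]
  ica_rejections <- 0L
  if (!is.null(ica)) {
    res <- ica_clean(recordings, ica)
    recordings <- res$recordings
    report$ica <- res$report
    ica_rejections <- sum(res$report$rejected, na.rm = TRUE)
  }
  timings["ica"] <- proc.time()[3] - t0

  t0 <- proc.time()[3]
  recordings <- lapply(recordings, apply_filter, spec = filter)
  timings["filter"] <- proc.time()[3] - t0

  t0 <- proc.time()[3]
  classes <- attr(manifest, "class_universe")
  all_ws <- segment(recordings, scheme, class_universe = classes)
  train_ws <- subset_windows(all_ws, all_ws$recording_ids %in% split$train)
  test_ws <- subset_windows(all_ws, all_ws$recording_ids %in% split$test)
  timings["segment"] <- proc.time()[3] - t0

  t0 <- proc.time()[3]
  stats <- fit_normalizer(train_ws, sd_floor = sd_floor)
  train_ws <- apply_normalizer(stats, train_ws)
  test_ws <- apply_normalizer(stats, test_ws)
  timings["normalize"] <- proc.time()[3] - t0

  report$timings <- timings
  report$ica_rejections <- ica_rejections
  report$n_train_windows <- n_windows(train_ws)
  report$n_test_windows <- n_windows(test_ws)
  list(train = train_ws, test = test_ws, stats = stats, report = report)
}
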