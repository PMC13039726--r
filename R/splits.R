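#' Split plan container
#'
#' A list of folds, each assigning every window of a window set to exactly
#' one role among train / test / (optionally) calibration.
#' @keywords internal
split_plan <- function(strategy, folds, params = list()) {
  structure(list(strategy = strategy, folds = folds, params = params),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %s, %d fold(s)\n", x$strategy, length(x$folds)))
  invisible(x)
}

check_partition <- function(fold, n) {
  roles <- c(fold$train, fold$test, fold$calibration)
  stopifnot(length(roles) == n, setequal(roles, seq_len(n)))
}

## stratified sample of approximately frac of each class's indices
stratified_sample <- function(labels, frac) {
  out <- integer(0)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) == 0L) next
    k <- max(1L, round(frac * length(idx)))
    out <- c(out, sample(idx, k))
  }
  sort(out)
}

#' Multi-seed stratified random splits (Strategy 1)
#'
#' Window-level stratified partition into train and test, one fold per seed.
#' This is the upper-bound protocol: overlapping Scheme A windows from the
#' same recording may land on both sides, so temporal leakage is tolerated
#' by design.
#'
#' @param ws A `window_set`.
#' @param seeds Integer seeds, default `1:5`.
#' @param test_frac Test fraction (default 0.10).
#' @return A `split_plan` with one fold per seed.
#' @export
make_random_splits <- function(ws, seeds = 1:5, test_frac = 0.10) {
  stopifnot(inherits(ws, "window_set"))
  if (test_frac <= 0 || test_frac >= 1) {
    stop("test_frac must be in (0, 1)", call. = FALSE)
  }
  labels <- droplevels(ws$labels)
  min_class <- min(table(labels))
  if (min_class < ceiling(1 / test_frac)) {
    stop("every class needs at least ", ceiling(1 / test_frac),
         " windows for stratified splitting", call. = FALSE)
  }
  n <- n_windows(ws)
  folds <- lapply(seeds, function(s) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(s)
    test <- stratified_sample(labels, test_frac)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    list(train = setdiff(seq_len(n), test), test = test, seed = s)
  })
  split_plan("random_multiseed", folds,
             params = list(seeds = seeds, test_frac = test_frac))
}

#' Grouped stratified k-fold splits (Strategy 2)
#'
#' With `group_key = "window"` (the default, matching sample-level grouping
#' over non-overlapping windows) this is stratified k-fold over windows.
#' With `"recording"` or `"subject"`, whole groups are assigned to folds, so
#' each group's windows are tested exactly once and never trained on in the
#' same fold. In paper-faithful mode the windows must come from
#' non-overlapping Scheme B segmentation, otherwise folds would share raw
#' samples (temporal leakage) and the call is refused.
#'
#' @param ws A `window_set`.
#' @param k Number of folds (default 10).
#' @param group_key `"window"`, `"recording"`, or `"subject"`.
#' @param seed Seed for fold assignment.
#' @param paper_faithful Require Scheme B windows (default `TRUE`).
#' @return A `split_plan` with `k` folds.
#' @export
make_group_kfold <- function(ws, k = 10, group_key = c("window", "recording",
                                                       "subject"),
                             seed = 1L, paper_faithful = TRUE) {
  stopifnot(inherits(ws, "window_set"))
  group_key <- match.arg(group_key)
  if (paper_faithful && ws$scheme$ws != ws$scheme$stride) {
    stop(paste("temporal-leakage risk: grouped k-fold requires",
               "non-overlapping (Scheme B) windows in paper-faithful mode"),
         call. = FALSE)
  }
  n <- n_windows(ws)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({ if (!is.null(old)) assign(".Random.seed", old, globalenv()) })
  set.seed(seed)

  fold_of <- integer(n)
  if (group_key == "window") {
    labels <- droplevels(ws$labels)
    if (k > n) stop("k exceeds the number of windows", call. = FALSE)
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    key <- if (group_key == "recording") ws$recording_ids else ws$subject_ids
    groups <- unique(key)
    if (k > length(groups)) {
      stop("k exceeds the number of groups", call. = FALSE)
    }
    assign_g <- rep_len(seq_len(k), length(groups))[sample(length(groups))]
    names(assign_g) <- sample(groups)
    fold_of <- assign_g[key]
  }
  folds <- lapply(seq_len(k), function(f) {
    test <- which(fold_of == f)
    list(train = which(fold_of != f), test = test, fold = f)
  })
  split_plan("group_kfold", folds,
             params = list(k = k, group_key = group_key, seed = seed))
}

#' Leave-one-subject-out folds with calibration (Strategy 3)
#'
#' One fold per subject: the other subjects' windows train the model; the
#' held-out subject's windows are split, stratified by class, into a
#' calibration fraction (default 20%, used to fine-tune) and a test
#' remainder (80%, used exclusively for evaluation).
#'
#' @param ws A `window_set`.
#' @param calib_frac Calibration fraction of the held-out subject's windows.
#' @param seed Seed for the stratified calibration draw.
#' @param paper_faithful Require Scheme B windows (default `TRUE`).
#' @return A `split_plan` with one fold per subject; each fold records
#'   `subject`.
#' @export
make_loso_folds <- function(ws, calib_frac = 0.20, seed = 1L,
                            paper_faithful = TRUE) {
  stopifnot(inherits(ws, "window_set"))
  if (paper_faithful && ws$scheme$ws != ws$scheme$stride) {
    stop(paste("temporal-leakage risk: LOSO requires non-overlapping",
               "(Scheme B) windows in paper-faithful mode"), call. = FALSE)
  }
  subjects <- unique(ws$subject_ids)
  if (length(subjects) < 2L) {
    stop("LOSO requires at least 2 subjects", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({ if (!is.null(old)) assign(".Random.seed", old, globalenv()) })
  set.seed(seed)
  n <- n_windows(ws)
  folds <- lapply(subjects, function(s) {
    held <- which(ws$subject_ids == s)
    held_labels <- droplevels(ws$labels[held])
    if (calib_frac > 0 && any(table(held_labels) < 2L)) {
      stop("subject ", s, " has too few windows per class for a stratified ",
           "calibration split", call. = FALSE)
    }
    calib_local <- if (calib_frac > 0) {
      stratified_sample(ws$labels[held], calib_frac)
    } else integer(0)
    calibration <- held[calib_local]
    list(train = setdiff(seq_len(n), held),
         test = setdiff(held, calibration),
         calibration = calibration, subject = s)
  })
  split_plan("loso_calibrated", folds,
             params = list(calib_frac = calib_frac, seed = seed))
}
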