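#' Run a full evaluation strategy end-to-end
#'
#' Orchestrates preprocess -> train (-> per-subject fine-tune for LOSO) ->
#' predict -> metrics for one of the three validation strategies. ICA (if
#' enabled) and filtering are label-blind and applied once; segmentation
#' happens once; normalization statistics are fit on each fold's training
#' windows only. In paper-faithful mode a leakage audit fails hard if any
#' test window shares raw samples with a training window of the same fold.
#'
#' @param manifest An `eeg_manifest`.
#' @param recordings Matching list of `eeg_recording`.
#' @param strategy `"random_multiseed"`, `"group_kfold"`, or
#'   `"loso_calibrated"`.
#' @param arch An `arch_spec` (its `n_classes` must match the manifest).
#' @param filter A `filter_spec`.
#' @param scheme A `windowing_scheme`; defaults to Scheme A for the random
#'   strategy and Scheme B otherwise.
#' @param ica An `ica_config` or `NULL` (default) to disable ICA.
#' @param train_cfg A `training_config`.
#' @param seeds Seeds for the random strategy (default `1:5`).
#' @param k Folds for grouped k-fold (default 10).
#' @param group_key Grouping for k-fold (see [make_group_kfold()]).
#' @param calib_frac LOSO calibration fraction (default 0.20).
#' @param calibrate Fine-tune on the calibration windows under LOSO
#'   (default `TRUE`).
#' @param paper_faithful Enforce Scheme B + leakage audit for the grouped
#'   strategies.
#' @param verbose Print per-fold progress.
#' @return An object of class `result_table`: `per_fold` data.frame,
#'   `aggregate` (mean and 95% CI margin per metric), `confusions`,
#'   `per_class_recall` matrix, and the pipeline/strategy configuration.
#' @export
run_strategy <- function(manifest, recordings,
                         strategy = c("random_multiseed", "group_kfold",
                                      "loso_calibrated"),
                         arch, filter = filter_spec("fd_bandreject"),
                         scheme = NULL, ica = NULL,
                         train_cfg = training_config(),
                         seeds = 1:5, k = 10, group_key = "window",
                         calib_frac = 0.20, calibrate = TRUE,
                         paper_faithful = TRUE, verbose = FALSE) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(arch, "arch_spec"))
  if (is.null(scheme)) {
    scheme <- windowing_scheme(if (strategy == "random_multiseed") "A" else "B")
  }
  classes <- attr(manifest, "class_universe")
  if (arch$n_classes != length(classes)) {
    stop("arch n_classes does not match the manifest class universe",
         call. = FALSE)
  }
  rids <- manifest$recording_id
  for (i in seq_along(recordings)) {
    if (is.na(recordings[[i]]$recording_id)) {
      recordings[[i]]$recording_id <- rids[i]
    }
  }

  if (!is.null(ica)) recordings <- ica_clean(recordings, ica)$recordings
  recordings <- lapply(recordings, apply_filter, spec = filter)
  ws <- segment(recordings, scheme, class_universe = classes)

  plan <- switch(strategy,
    random_multiseed = make_random_splits(ws, seeds = seeds),
    group_kfold = make_group_kfold(ws, k = k, group_key = group_key,
                                   seed = train_cfg$seed,
                                   paper_faithful = paper_faithful),
    loso_calibrated = make_loso_folds(ws, calib_frac = calib_frac,
                                      seed = train_cfg$seed,
                                      paper_faithful = paper_faithful))

  per_fold <- list(); confusions <- list(); recalls <- list()
  for (fi in seq_along(plan$folds)) {
    fold <- plan$folds[[fi]]
    if (paper_faithful && strategy != "random_multiseed") {
      audit_leakage(ws, fold)
    }
    tr <- subset_windows(ws, fold$train)
    te <- subset_windows(ws, fold$test)
    stats <- fit_normalizer(tr)
    tr <- apply_normalizer(stats, tr)
    te <- apply_normalizer(stats, te)

    fold_seed <- if (strategy == "random_multiseed") fold$seed else
      train_cfg$seed + fi
    cfg <- train_cfg
    cfg$seed <- fold_seed
    model <- build_model(arch, input_shape = dim(ws$windows)[2:3],
                         seed = fold_seed)
    fit <- train_model(model, tr, cfg)
    model <- fit$model

    if (strategy == "loso_calibrated" && calibrate &&
        length(fold$calibration) > 0L) {
      cal <- apply_normalizer(stats, subset_windows(ws, fold$calibration))
      cal_cfg <- training_config(lr = 0.001, batch_size = 128,
                                 max_epochs = cfg$max_epochs,
                                 early_stop_patience = cfg$early_stop_patience,
                                 lr_reduce_patience = cfg$lr_reduce_patience,
                                 val_fraction = cfg$val_fraction,
                                 seed = fold_seed + 1000L)
      model <- fine_tune(model, cal, cal_cfg)$model
    }

    pred <- predict(model, te)
    cm <- confusion_matrix(te$labels, pred$classes, class_labels = classes)
    m <- compute_metrics(cm)
    row <- data.frame(
      fold = fi,
      id = as.character(fold$seed %||% fold$subject %||% fold$fold %||% fi),
      accuracy = m$accuracy, balanced_accuracy = m$balanced_accuracy,
      macro_f1 = m$macro_f1, weighted_precision = m$weighted_precision,
      weighted_f1 = m$weighted_f1, n_test = m$n,
      stringsAsFactors = FALSE)
    if (strategy == "loso_calibrated") row$subject <- fold$subject
    per_fold[[fi]] <- row
    confusions[[fi]] <- cm
    recalls[[fi]] <- m$per_class_recall
    if (verbose) {
      message(sprintf("fold %d/%d (%s): accuracy %.3f", fi,
                      length(plan$folds), row$id, m$accuracy))
    }
  }
  per_fold <- do.call(rbind, per_fold)
  metric_cols <- c("accuracy", "balanced_accuracy", "macro_f1",
                   "weighted_precision", "weighted_f1")
  aggregate <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(mc) mean(per_fold[[mc]]), 0),
    ci_margin = vapply(metric_cols, function(mc) {
      if (nrow(per_fold) >= 2L) ci_margin(per_fold[[mc]]) else NA_real_
    }, 0),
    row.names = NULL)
  structure(list(strategy = strategy, per_fold = per_fold,
                 aggregate = aggregate, confusions = confusions,
                 per_class_recall = do.call(rbind, recalls),
                 scheme = scheme, plan_params = plan$params),
            class = "result_table")
}

#' @export
print.result_table <- function(x, ...) {
  cat(sprintf("<result_table> strategy %s, %d fold(s)\n", x$strategy,
              nrow(x$per_fold)))
  acc <- x$aggregate[x$aggregate$metric == "accuracy", ]
  cat(sprintf("  accuracy %.4f +/- %.4f (95%% CI margin)\n",
              acc$mean, acc$ci_margin))
  invisible(x)
}

## hard error if any test window's raw samples are reachable from a train
## window of the same fold (same recording, overlapping sample interval)
audit_leakage <- function(ws, fold) {
  tr_rec <- ws$recording_ids[fold$train]
  te_rec <- ws$recording_ids[fold$test]
  shared <- intersect(unique(tr_rec), unique(te_rec))
  if (length(shared) == 0L) return(invisible(TRUE))
  w <- ws$scheme$ws
  for (rid in shared) {
    tr_i <- fold$train[tr_rec == rid]
    te_i <- fold$test[te_rec == rid]
    tr_starts <- ws$starts[tr_i]
    for (s in ws$starts[te_i]) {
      if (any(abs(tr_starts - s) < w)) {
        stop("leakage audit failure: train and test windows share raw ",
             "samples in recording ", rid, call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}
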