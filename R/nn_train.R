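#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam with learning rate
#' 0.001 (first/second moment decay 0.9 and 0.999), categorical
#' cross-entropy, at most 500 epochs, early stopping on validation loss with
#' patience 30 (best weights restored), learning rate multiplied by 0.1
#' after 10 stagnant validation epochs, batch size 256 for standard training
#' and 128 for per-subject calibration.
#'
#' @param lr Initial learning rate.
#' @param beta1,beta2 Adam moment decay rates.
#' @param max_epochs Maximum epochs.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping.
#' @param lr_reduce_factor,lr_reduce_patience Plateau schedule parameters.
#' @param batch_size Minibatch size (256 standard, 128 calibration).
#' @param val_fraction Stratified fraction of the training windows carved
#'   out for validation monitoring.
#' @param seed Seed governing shuffling, dropout, and the validation split.
#' @return An object of class `training_config`.
#' @export
training_config <- function(lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                            max_epochs = 500, early_stop_patience = 30,
                            lr_reduce_factor = 0.1, lr_reduce_patience = 10,
                            batch_size = 256, val_fraction = 0.1,
                            seed = 1L) {
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 lr_reduce_factor = lr_reduce_factor,
                 lr_reduce_patience = as.integer(lr_reduce_patience),
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "training_config")
}

one_hot <- function(labels, n_classes) {
  Y <- matrix(0, length(labels), n_classes)
  Y[cbind(seq_along(labels), as.integer(labels))] <- 1
  Y
}

## stratified index split: for each class, floor(frac * n) indices (at least
## 1 when the class has > 1 windows) go to the carve-out
stratified_holdout <- function(labels, frac) {
  hold <- integer(0)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) == 0L) next
    k <- max(if (length(idx) > 1L) 1L else 0L, floor(frac * length(idx)))
    if (k > 0L) hold <- c(hold, sample(idx, k))
  }
  sort(hold)
}

cross_entropy <- function(probs, Y) {
  eps <- 1e-12
  -mean(log(pmax(rowSums(probs * Y), eps)))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(state, params, grads, lr, beta1, beta2, eps = 1e-7) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / corr1) / (sqrt(state$v[[k]] / corr2) + eps)
  }
  list(state = state, params = params)
}

eval_loss <- function(model, X, Y) {
  logits <- model_forward(model, X, train = FALSE)$logits
  cross_entropy(softmax_rows(logits), Y)
}

#' Train a classifier on a window set
#'
#' Minimizes categorical cross-entropy with Adam. A stratified
#' `val_fraction` of the training windows monitors validation loss for early
#' stopping (patience `early_stop_patience`, best weights restored) and for
#' the plateau learning-rate schedule (multiply by `lr_reduce_factor` after
#' `lr_reduce_patience` stagnant epochs). All randomness (validation split,
#' shuffling, dropout) is governed by `cfg$seed`.
#'
#' @param model An `eeg_model` from [build_model()].
#' @param train A normalized `window_set`.
#' @param cfg A `training_config`.
#' @param verbose Print per-epoch progress.
#' @return List with `model` (trained `eeg_model`) and `history`
#'   (data.frame of epoch, loss, val_loss, lr; attributes `stop_epoch`,
#'   `best_epoch`, `batch_size`).
#' @export
train_model <- function(model, train, cfg = training_config(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "eeg_model"), inherits(train, "window_set"))
  if (!train$normalized) {
    stop("training windows must be normalized first", call. = FALSE)
  }
  present <- droplevels(train$labels)
  if (nlevels(present) < 2L) {
    stop("training set contains a single class", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(cfg$seed)

  model$class_levels <- levels(train$labels)
  Yall <- one_hot(train$labels, model$n_classes)
  val_idx <- stratified_holdout(train$labels, cfg$val_fraction)
  tr_idx <- setdiff(seq_len(n_windows(train)), val_idx)
  Xtr <- train$windows[tr_idx, , , drop = FALSE]
  Ytr <- Yall[tr_idx, , drop = FALSE]
  Xval <- train$windows[val_idx, , , drop = FALSE]
  Yval <- Yall[val_idx, , drop = FALSE]
  has_val <- length(val_idx) > 0L

  params <- model_params(model)
  opt <- adam_init(params)
  lr <- cfg$lr
  best_val <- Inf; best_params <- params; best_epoch <- 0L
  es_wait <- 0L; lr_wait <- 0L
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     val_loss = numeric(0), lr = numeric(0))
  n_tr <- nrow(Ytr)

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n_tr)
    epoch_loss <- 0; n_batches <- 0L
    for (b0 in seq(1L, n_tr, by = cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n_tr)]
      Xb <- Xtr[idx, , , drop = FALSE]
      Yb <- Ytr[idx, , drop = FALSE]
      fw <- model_forward(model, Xb, train = TRUE)
      model <- fw$model
      probs <- softmax_rows(fw$logits)
      loss <- cross_entropy(probs, Yb)
      if (!is.finite(loss)) {
        stop(sprintf("non-finite training loss at epoch %d; aborting", epoch),
             call. = FALSE)
      }
      dlogits <- (probs - Yb) / nrow(Yb)
      grads <- model_backward(model, fw$caches, dlogits)
      params <- model_params(model)
      upd <- adam_step(opt, params, grads, lr, cfg$beta1, cfg$beta2)
      opt <- upd$state
      model <- model_set_params(model, upd$params)
      epoch_loss <- epoch_loss + loss; n_batches <- n_batches + 1L
    }
    epoch_loss <- epoch_loss / n_batches
    val_loss <- if (has_val) eval_loss(model, Xval, Yval) else epoch_loss
    hist <- rbind(hist, data.frame(epoch = epoch, loss = epoch_loss,
                                   val_loss = val_loss, lr = lr))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val %.4f  lr %.2g",
                      epoch, epoch_loss, val_loss, lr))
    }
    if (val_loss < best_val - 1e-9) {
      best_val <- val_loss
      best_params <- model_params(model)
      best_epoch <- epoch
      es_wait <- 0L; lr_wait <- 0L
    } else {
      es_wait <- es_wait + 1L
      lr_wait <- lr_wait + 1L
      if (lr_wait >= cfg$lr_reduce_patience) {
        lr <- lr * cfg$lr_reduce_factor
        lr_wait <- 0L
      }
      if (es_wait >= cfg$early_stop_patience) break
    }
  }
  model <- model_set_params(model, best_params)
  model$trained <- TRUE
  attr(hist, "stop_epoch") <- nrow(hist)
  attr(hist, "best_epoch") <- best_epoch
  attr(hist, "batch_size") <- cfg$batch_size
  list(model = model, history = hist)
}

#' Fine-tune a trained model on per-subject calibration windows
#'
#' Continues optimization from the pretrained weights with the learning rate
#' reset to 0.001 and batch size 128 (the calibration recipe), under the
#' same early-stopping criteria.
#'
#' @param model A trained `eeg_model`.
#' @param calibration Normalized `window_set` drawn from a single subject.
#' @param cfg A `training_config`; defaults to the calibration recipe.
#' @param skip If `TRUE`, return the model unchanged (identity path).
#' @return List with `model` and `history` as in [train_model()].
#' @export
fine_tune <- function(model, calibration,
                      cfg = training_config(batch_size = 128),
                      skip = FALSE) {
  if (skip) return(list(model = model, history = NULL))
  stopifnot(inherits(model, "eeg_model"))
  if (is.null(calibration) || n_windows(calibration) == 0L) {
    stop("calibration set is empty", call. = FALSE)
  }
  if (length(unique(calibration$subject_ids)) != 1L) {
    stop("calibration windows must come from a single subject", call. = FALSE)
  }
  train_model(model, calibration, cfg)
}
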