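#' Architecture specification
#'
#' The five classifier templates. All share the same skeleton: an optional
#' convolutional block (Conv1D + ReLU, batch normalization, max pooling over
#' time), a recurrent stack whose intermediate layers emit full sequences and
#' whose final layer emits its last state, one or two ReLU dense layers, and
#' a softmax output. Per-template regularization:
#'
#' * `CNN-1-LSTM` - 1 conv block, 1 LSTM, 1 dense; dropout 0.20 before output.
#' * `CNN-2-LSTM` - 2 stacked LSTMs; dropout 0.50 between LSTMs, 0.20 before
#'   output.
#' * `CNN-2-Bi-LSTM` - 2 bidirectional LSTMs; dropout 0.50 between and 0.50
#'   before output.
#' * `CNN-3-LSTM` - 3 stacked LSTMs, 2 dense; dropouts 0.10/0.30/0.10 after
#'   the LSTMs and 0.10 before output.
#' * `3-LSTM` - no conv block, 3 stacked LSTMs, 1 dense; same dropouts as
#'   CNN-3-LSTM.
#'
#' Layer widths are not fixed by the templates; the `"paper_default"` profile
#' uses conv filters 64 (kernel 3, pool 2), recurrent units 128/64/32 by
#' depth and dense width 64 (128, 64 for CNN-3-LSTM), while `"tiny"` (the
#' test default) uses 8 filters and 16/16/16 units.
#'
#' @param name One of `"CNN-1-LSTM"`, `"CNN-2-LSTM"`, `"CNN-2-Bi-LSTM"`,
#'   `"CNN-3-LSTM"`, `"3-LSTM"`.
#' @param n_classes Number of output classes.
#' @param profile `"tiny"` or `"paper_default"`, or `NULL` when widths are
#'   given explicitly.
#' @param conv_filters,conv_kernel,pool_size Convolutional block widths.
#' @param recurrent_units Integer vector, one entry per recurrent layer.
#' @param dense_units Integer vector of dense-layer widths.
#' @return An object of class `arch_spec`.
#' @export
arch_spec <- function(name = c("CNN-1-LSTM", "CNN-2-LSTM", "CNN-2-Bi-LSTM",
                               "CNN-3-LSTM", "3-LSTM"),
                      n_classes, profile = c("tiny", "paper_default"),
                      conv_filters = NULL, conv_kernel = 3, pool_size = 2,
                      recurrent_units = NULL, dense_units = NULL) {
  name <- match.arg(name)
  profile <- match.arg(profile)
  tmpl <- switch(name,
    "CNN-1-LSTM" = list(conv = 1L, depth = 1L, bidir = FALSE,
                        between = numeric(0), pre_out = 0.20, n_dense = 1L),
    "CNN-2-LSTM" = list(conv = 1L, depth = 2L, bidir = FALSE,
                        between = 0.50, pre_out = 0.20, n_dense = 1L),
    "CNN-2-Bi-LSTM" = list(conv = 1L, depth = 2L, bidir = TRUE,
                           between = 0.50, pre_out = 0.50, n_dense = 1L),
    "CNN-3-LSTM" = list(conv = 1L, depth = 3L, bidir = FALSE,
                        between = c(0.10, 0.30, 0.10), pre_out = 0.10,
                        n_dense = 2L),
    "3-LSTM" = list(conv = 0L, depth = 3L, bidir = FALSE,
                    between = c(0.10, 0.30, 0.10), pre_out = 0.10,
                    n_dense = 1L))
  if (is.null(conv_filters)) {
    conv_filters <- if (profile == "paper_default") 64L else 8L
  }
  if (is.null(recurrent_units)) {
    recurrent_units <- if (profile == "paper_default") {
      c(128L, 64L, 32L)[seq_len(tmpl$depth)]
    } else {
      rep(16L, tmpl$depth)
    }
  }
  if (length(recurrent_units) != tmpl$depth) {
    stop(sprintf("%s requires %d recurrent layers", name, tmpl$depth),
         call. = FALSE)
  }
  if (is.null(dense_units)) {
    dense_units <- if (profile == "paper_default") {
      if (tmpl$n_dense == 2L) c(128L, 64L) else 64L
    } else {
      rep(16L, tmpl$n_dense)
    }
  }
  if (length(dense_units) != tmpl$n_dense) {
    stop(sprintf("%s requires %d dense layers", name, tmpl$n_dense),
         call. = FALSE)
  }
  structure(list(name = name, n_classes = as.integer(n_classes),
                 conv_blocks = tmpl$conv,
                 conv_filters = as.integer(conv_filters),
                 conv_kernel = as.integer(conv_kernel),
                 pool_size = as.integer(pool_size),
                 recurrent_units = as.integer(recurrent_units),
                 bidirectional = tmpl$bidir,
                 between_dropout = tmpl$between,
                 pre_output_dropout = tmpl$pre_out,
                 dense_units = as.integer(dense_units)),
            class = "arch_spec")
}

#' Build a classifier from an architecture specification
#'
#' @param spec An `arch_spec`.
#' @param input_shape `c(window_size, n_channels)`.
#' @param seed Seed for weight initialization.
#' @return An object of class `eeg_model` (untrained).
#' @export
build_model <- function(spec, input_shape, seed = 1L) {
  stopifnot(inherits(spec, "arch_spec"), length(input_shape) == 2)
  ws <- as.integer(input_shape[1]); nc <- as.integer(input_shape[2])
  if (ws < 1L || nc < 1L) stop("input_shape must be positive", call. = FALSE)

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)

  layers <- list()
  feat <- nc; t_len <- ws
  if (spec$conv_blocks == 1L) {
    if (t_len < spec$conv_kernel) {
      stop("window shorter than the convolution kernel", call. = FALSE)
    }
    layers <- c(layers, list(layer_conv1d(feat, spec$conv_filters,
                                          spec$conv_kernel)))
    t_len <- t_len - spec$conv_kernel + 1L
    feat <- spec$conv_filters
    layers <- c(layers, list(layer_batchnorm(feat)))
    t_len <- t_len %/% spec$pool_size
    if (t_len < 1L) stop("window too short after pooling", call. = FALSE)
    layers <- c(layers, list(layer_maxpool(spec$pool_size)))
  }
  depth <- length(spec$recurrent_units)
  for (i in seq_len(depth)) {
    ret_seq <- i < depth
    u <- spec$recurrent_units[i]
    if (spec$bidirectional) {
      layers <- c(layers, list(layer_bilstm(feat, u, ret_seq)))
      feat <- 2L * u
    } else {
      layers <- c(layers, list(layer_lstm(feat, u, ret_seq)))
      feat <- u
    }
    if (i <= length(spec$between_dropout) && spec$between_dropout[i] > 0) {
      layers <- c(layers, list(layer_dropout(spec$between_dropout[i])))
    }
  }
  for (u in spec$dense_units) {
    layers <- c(layers, list(layer_dense(feat, u, "relu")))
    feat <- u
  }
  if (spec$pre_output_dropout > 0) {
    layers <- c(layers, list(layer_dropout(spec$pre_output_dropout)))
  }
  layers <- c(layers, list(layer_dense(feat, spec$n_classes, "linear")))

  structure(list(layers = layers, spec = spec,
                 input_shape = c(ws, nc), n_classes = spec$n_classes,
                 class_levels = NULL, trained = FALSE),
            class = "eeg_model")
}

#' @export
print.eeg_model <- function(x, ...) {
  pc <- count_parameters(x)
  cat(sprintf("<eeg_model> %s, input %d x %d, %d classes%s\n",
              x$spec$name, x$input_shape[1], x$input_shape[2], x$n_classes,
              if (x$trained) " (trained)" else ""))
  cat(sprintf("  layers: %s\n",
              paste(vapply(x$layers, `[[`, "", "type"), collapse = " -> ")))
  cat(sprintf("  parameters: %d total, %d trainable\n", pc$total,
              pc$trainable))
  invisible(x)
}

## full forward pass; returns logits, caches, and the (possibly updated)
## model when batch-norm running statistics moved
model_forward <- function(model, X, train = FALSE) {
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    res <- layer_forward(model$layers[[i]], X, train)
    if (!is.null(res$layer)) model$layers[[i]] <- res$layer
    caches[[i]] <- res$cache
    X <- res$out
  }
  list(logits = X, caches = caches, model = model)
}

model_backward <- function(model, caches, dOut) {
  grads <- list()
  for (i in rev(seq_along(model$layers))) {
    res <- layer_backward(model$layers[[i]], caches[[i]], dOut)
    grads <- c(grads,
               layer_grad_list(model$layers[[i]], res$grads,
                               sprintf("L%02d", i)))
    dOut <- res$dX
  }
  grads
}

model_params <- function(model) {
  out <- list()
  for (i in seq_along(model$layers)) {
    out <- c(out, layer_param_list(model$layers[[i]], sprintf("L%02d", i)))
  }
  out
}

model_set_params <- function(model, values) {
  for (i in seq_along(model$layers)) {
    model$layers[[i]] <- layer_set_params(model$layers[[i]], values,
                                          sprintf("L%02d", i))
  }
  model
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Count model parameters
#'
#' Trainable parameters are the layer weights; batch-normalization running
#' statistics are counted as non-trainable.
#'
#' @param model An `eeg_model`.
#' @return List with `total` and `trainable` counts.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "eeg_model"))
  trainable <- sum(vapply(model_params(model), length, 0L))
  non_trainable <- 0L
  for (l in model$layers) {
    if (l$type == "batchnorm") {
      non_trainable <- non_trainable +
        sum(vapply(l$buffers, length, 0L))
    }
  }
  list(total = trainable + non_trainable, trainable = trainable)
}

#' Model size in megabytes
#'
#' `total_params * bytes_per_param / 2^20`, rounded to two decimals —
#' the float32 size-accounting convention.
#'
#' @param total_params Parameter count.
#' @param bytes_per_param Bytes per parameter (default 4, float32).
#' @return Size in MB, rounded to 2 decimals.
#' @export
model_size_mb <- function(total_params, bytes_per_param = 4) {
  stopifnot(total_params >= 0)
  round(total_params * bytes_per_param / 2^20, 2)
}

#' Predict classes for a window set
#'
#' Runs the model in inference mode (dropout off, batch normalization using
#' running statistics). The window set must be normalized with the model's
#' training statistics.
#'
#' @param object A trained `eeg_model`.
#' @param ws A normalized `window_set`.
#' @param ... Unused.
#' @return List with `classes` (factor, training levels) and `probs`
#'   (matrix, rows summing to 1).
#' @export
predict.eeg_model <- function(object, ws, ...) {
  stopifnot(inherits(ws, "window_set"))
  if (dim(ws$windows)[3] != object$input_shape[2] ||
      dim(ws$windows)[2] != object$input_shape[1]) {
    stop("window shape does not match the model input shape", call. = FALSE)
  }
  logits <- model_forward(object, ws$windows, train = FALSE)$logits
  probs <- softmax_rows(logits)
  idx <- max.col(probs, ties.method = "first")
  lev <- if (is.null(object$class_levels)) as.character(seq_len(object$n_classes))
         else object$class_levels
  list(classes = factor(lev[idx], levels = lev), probs = probs)
}
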