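## closed-form parameter formulas, independent of the engine's bookkeeping
closed_form_counts <- function(spec, input_shape) {
  ws <- input_shape[1]; feat <- input_shape[2]
  trainable <- 0; non_trainable <- 0
  if (spec$conv_blocks == 1L) {
    trainable <- trainable + (spec$conv_kernel * feat + 1) * spec$conv_filters
    feat <- spec$conv_filters
    trainable <- trainable + 2 * feat        # batch-norm gamma, beta
    non_trainable <- non_trainable + 2 * feat # running mean, var
  }
  for (u in spec$recurrent_units) {
    lstm <- 4 * ((feat + u) * u + u)
    if (spec$bidirectional) {
      trainable <- trainable + 2 * lstm
      feat <- 2 * u
    } else {
      trainable <- trainable + lstm
      feat <- u
    }
  }
  for (u in spec$dense_units) {
    trainable <- trainable + (feat + 1) * u
    feat <- u
  }
  trainable <- trainable + (feat + 1) * spec$n_classes
  list(total = trainable + non_trainable, trainable = trainable)
}

arch_names <- c("CNN-1-LSTM", "CNN-2-LSTM", "CNN-2-Bi-LSTM", "CNN-3-LSTM",
                "3-LSTM")

test_that("engine parameter counts equal the closed-form layer formulas", {
  for (nm in arch_names) {
    for (profile in c("tiny", "paper_default")) {
      spec <- arch_spec(nm, n_classes = 30, profile = profile)
      m <- build_model(spec, c(32, 14), seed = 1)
      got <- count_parameters(m)
      want <- closed_form_counts(spec, c(32, 14))
      expect_equal(got$total, want$total, info = paste(nm, profile))
      expect_equal(got$trainable, want$trainable, info = paste(nm, profile))
    }
  }
  ## individual layer formulas
  expect_equal(length(eegfdf:::layer_conv1d(14, 4, 3)$params$W) +
                 length(eegfdf:::layer_conv1d(14, 4, 3)$params$b), 172)
  l <- eegfdf:::layer_lstm(4, 8)
  expect_equal(sum(vapply(l$params, length, 0L)), 416)
  bl <- eegfdf:::layer_bilstm(4, 8)
  expect_equal(sum(vapply(bl$fwd$params, length, 0L)) +
                 sum(vapply(bl$bwd$params, length, 0L)), 832)
})

test_that("bidirectional recurrent layers double the recurrent parameters", {
  uni <- arch_spec("CNN-2-LSTM", 10, recurrent_units = c(16, 16))
  bi <- arch_spec("CNN-2-Bi-LSTM", 10, recurrent_units = c(16, 16))
  m_uni <- build_model(uni, c(32, 14), seed = 1)
  m_bi <- build_model(bi, c(32, 14), seed = 1)
  rec_params <- function(m, type) {
    sum(vapply(m$layers, function(l) {
      if (l$type == "lstm") sum(vapply(l$params, length, 0L))
      else if (l$type == "bilstm") {
        sum(vapply(l$fwd$params, length, 0L)) +
          sum(vapply(l$bwd$params, length, 0L))
      } else 0L
    }, 0L))
  }
  ## first bi layer is exactly 2x; the second grows further because its
  ## input is the concatenated 2u-wide sequence
  expect_gte(rec_params(m_bi), 2 * rec_params(m_uni))
})

test_that("architecture templates have the documented structure", {
  pure <- build_model(arch_spec("3-LSTM", 5), c(8, 14), seed = 1)
  expect_false(any(vapply(pure$layers, `[[`, "", "type") == "conv1d"))
  expect_equal(sum(vapply(pure$layers, `[[`, "", "type") == "lstm"), 3L)

  bi <- build_model(arch_spec("CNN-2-Bi-LSTM", 5), c(32, 14), seed = 1)
  expect_equal(sum(vapply(bi$layers, `[[`, "", "type") == "bilstm"), 2L)

  drop_rates <- function(m) vapply(Filter(function(l) l$type == "dropout",
                                          m$layers), `[[`, 0, "rate")
  expect_equal(drop_rates(build_model(arch_spec("CNN-1-LSTM", 5), c(32, 14))),
               0.20)
  expect_equal(drop_rates(build_model(arch_spec("CNN-2-LSTM", 5), c(32, 14))),
               c(0.50, 0.20))
  expect_equal(drop_rates(bi), c(0.50, 0.50))
  expect_equal(drop_rates(build_model(arch_spec("CNN-3-LSTM", 5), c(32, 14))),
               c(0.10, 0.30, 0.10, 0.10))
  expect_error(build_model(arch_spec("CNN-1-LSTM", 5, pool_size = 40),
                           c(32, 14)), "short")
})

test_that("float32 size accounting matches the published arithmetic", {
  expect_equal(model_size_mb(2453590), 9.36)
  expect_equal(model_size_mb(1372310), 5.23)
  expect_equal(model_size_mb(262144), 1.00)
})

test_that("analytic gradients match finite differences for every template", {
  set.seed(42)
  for (nm in arch_names) {
    depth <- length(arch_spec(nm, 3)$recurrent_units)
    nd <- length(arch_spec(nm, 3)$dense_units)
    spec <- arch_spec(nm, n_classes = 3, conv_filters = 4,
                      recurrent_units = rep(5, depth),
                      dense_units = rep(6, nd))
    m <- build_model(spec, c(10, 4), seed = 3)
    for (i in seq_along(m$layers)) {           # deterministic loss surface
      if (m$layers[[i]]$type == "dropout") m$layers[[i]]$rate <- 0
    }
    N <- 5
    X <- array(rnorm(N * 10 * 4), c(N, 10, 4))
    Y <- eegfdf:::one_hot(factor(sample(1:3, N, replace = TRUE),
                                 levels = 1:3), 3)
    fw <- eegfdf:::model_forward(m, X, train = TRUE)
    probs <- eegfdf:::softmax_rows(fw$logits)
    grads <- eegfdf:::model_backward(m, fw$caches, (probs - Y) / N)
    params <- eegfdf:::model_params(m)
    loss_at <- function(p) {
      f <- eegfdf:::model_forward(eegfdf:::model_set_params(m, p), X,
                                  train = TRUE)
      eegfdf:::cross_entropy(eegfdf:::softmax_rows(f$logits), Y)
    }
    rels <- c()
    for (k in names(params)) {
      for (i in sample(length(params[[k]]), min(2, length(params[[k]])))) {
        h <- 1e-5
        p2 <- params; p2[[k]][i] <- p2[[k]][i] + h; up <- loss_at(p2)
        p2[[k]][i] <- p2[[k]][i] - 2 * h; dn <- loss_at(p2)
        num <- (up - dn) / (2 * h)
        ana <- grads[[k]][i]
        ## near-zero gradients are dominated by finite-difference noise
        if (abs(num) + abs(ana) > 1e-4) {
          rels <- c(rels, abs(num - ana) / (abs(num) + abs(ana)))
        } else {
          expect_lt(abs(num - ana), 1e-6)
        }
      }
    }
    ## a perturbation occasionally crosses a ReLU/max-pool kink, where the
    ## loss is not differentiable and finite differences disagree by design;
    ## all but at most one sampled coordinate must match tightly
    expect_lte(sum(rels > 1e-3), 1)
    expect_lt(stats::median(rels), 1e-5)
  }
})

test_that("softmax outputs are proper probabilities", {
  fx <- separable_dataset(n_subjects = 1, n_classes = 3, trials_per_class = 2,
                          seed = 51)
  ws <- segment(fx$ds$recordings, windowing_scheme("B"),
                class_universe = fx$cfg$classes)
  ws <- apply_normalizer(fit_normalizer(ws), ws)
  m <- build_model(arch_spec("CNN-1-LSTM", 3), c(8, 14), seed = 2)
  p <- predict(m, ws)
  expect_true(all(abs(rowSums(p$probs) - 1) < 1e-6))
  expect_equal(ncol(p$probs), 3L)
  p2 <- predict(m, ws)
  expect_identical(p$probs, p2$probs)       # inference determinism
})

test_that("training learns a separable problem and is seed-deterministic", {
  fx <- separable_dataset(n_subjects = 2, n_classes = 3, trials_per_class = 3,
                          seed = 61)
  ws <- segment(fx$ds$recordings, windowing_scheme("A"),
                class_universe = fx$cfg$classes)
  st <- fit_normalizer(ws)
  ws <- apply_normalizer(st, ws)
  m <- build_model(arch_spec("CNN-1-LSTM", 3), c(32, 14), seed = 1)
  cfg <- training_config(max_epochs = 50, batch_size = 256, seed = 1)
  fit <- train_model(m, ws, cfg)
  ## validation accuracy on the held-in data proxies the separability oracle
  p <- predict(fit$model, ws)
  expect_gte(mean(as.character(p$classes) == as.character(ws$labels)), 0.95)
  expect_lte(nrow(fit$history), 50)

  fit2 <- train_model(build_model(arch_spec("CNN-1-LSTM", 3), c(32, 14),
                                  seed = 1), ws, cfg)
  expect_identical(fit$history, fit2$history)
})

test_that("plateau schedule and early stopping honour their patience", {
  fx <- separable_dataset(n_subjects = 1, n_classes = 3, trials_per_class = 2,
                          seed = 71, n_samples = 128)
  ws <- segment(fx$ds$recordings, windowing_scheme("B"),
                class_universe = fx$cfg$classes)
  ws <- apply_normalizer(fit_normalizer(ws), ws)
  m <- build_model(arch_spec("CNN-1-LSTM", 3), c(8, 14), seed = 1)
  ## a vanishing learning rate freezes the weights, so validation loss is
  ## flat after the first epoch: stopping and LR decay depend on patience only
  cfg <- training_config(lr = 1e-12, max_epochs = 60, early_stop_patience = 7,
                         lr_reduce_factor = 0.1, lr_reduce_patience = 3,
                         seed = 2)
  fit <- train_model(m, ws, cfg)
  h <- fit$history
  expect_lte(nrow(h), 1 + 7)                       # best + patience
  expect_equal(h$lr[5] / h$lr[1], 0.1, tolerance = 1e-9)  # one decay step
  expect_equal(attr(h, "batch_size"), 256L)
})

test_that("training refuses degenerate inputs", {
  fx <- separable_dataset(n_subjects = 1, n_classes = 2, trials_per_class = 2,
                          seed = 81, n_samples = 64)
  ws <- segment(fx$ds$recordings, windowing_scheme("B"),
                class_universe = fx$cfg$classes)
  wsn <- apply_normalizer(fit_normalizer(ws), ws)
  m <- build_model(arch_spec("CNN-1-LSTM", 2), c(8, 14), seed = 1)
  expect_error(train_model(m, ws), "normalized")
  single <- subset_windows(wsn, wsn$labels == "A")
  expect_error(train_model(m, single, training_config(max_epochs = 1)),
               "single class")
})

test_that("fine-tuning keeps its contracts", {
  fx <- separable_dataset(n_subjects = 2, n_classes = 3, trials_per_class = 2,
                          seed = 91, n_samples = 128)
  ws <- segment(fx$ds$recordings, windowing_scheme("B"),
                class_universe = fx$cfg$classes)
  wsn <- apply_normalizer(fit_normalizer(ws), ws)
  m <- build_model(arch_spec("CNN-1-LSTM", 3), c(8, 14), seed = 1)
  fit <- train_model(m, wsn, training_config(max_epochs = 5, seed = 1))
  ## identity path when skipped
  same <- fine_tune(fit$model, NULL, skip = TRUE)
  expect_identical(same$model, fit$model)
  ## calibration must be single-subject; batch size 128 is recorded
  cal <- subset_windows(wsn, wsn$subject_ids == "S02")
  ft <- fine_tune(fit$model, cal,
                  training_config(batch_size = 128, max_epochs = 3, seed = 2))
  expect_equal(attr(ft$history, "batch_size"), 128L)
  expect_error(fine_tune(fit$model, wsn), "single subject")
  expect_error(fine_tune(fit$model, subset_windows(wsn, integer(0))), "empty")
})
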