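## small labelled window set without touching signal content
toy_windows <- function(n_per_class = 100, classes = c("A", "B", "C"),
                        subjects = NULL, scheme = windowing_scheme("B"),
                        seed = 1) {
  set.seed(seed)
  n <- n_per_class * length(classes)
  labels <- rep(classes, each = n_per_class)
  if (is.null(subjects)) subjects <- rep("S01", n)
  eegfdf:::window_set(array(rnorm(n * scheme$ws * 2),
                            c(n, scheme$ws, 2)),
                      labels, classes, subjects,
                      paste0("r", seq_len(n)),
                      rep(1L, n), scheme)
}

test_that("stratified random splits hold out the right class counts", {
  ws <- toy_windows(100)
  plan <- make_random_splits(ws, seeds = 1:5, test_frac = 0.10)
  expect_length(plan$folds, 5)
  for (fold in plan$folds) {
    eegfdf:::check_partition(fold, 300)
    per_class <- table(ws$labels[fold$test])
    expect_true(all(abs(per_class - 10) <= 1))
    expect_equal(sum(per_class), 30)
  }
  ## same seed reproduces; different seeds differ
  plan2 <- make_random_splits(ws, seeds = 1:5, test_frac = 0.10)
  expect_identical(plan$folds[[1]]$test, plan2$folds[[1]]$test)
  expect_false(identical(plan$folds[[1]]$test, plan$folds[[2]]$test))
  expect_error(make_random_splits(ws, test_frac = 1.2), "test_frac")
  expect_error(make_random_splits(toy_windows(5), test_frac = 0.1),
               "at least")
})

test_that("grouped k-fold partitions windows and isolates groups", {
  ws <- toy_windows(200)
  plan <- make_group_kfold(ws, k = 10)
  tests <- lapply(plan$folds, `[[`, "test")
  expect_equal(sort(unlist(tests)), 1:600)
  expect_equal(unique(vapply(tests, length, 0L)), 60L)
  for (fold in plan$folds) {
    expect_length(intersect(fold$train, fold$test), 0)
  }

  ## subject-level grouping keeps each subject on one side
  ws_s <- toy_windows(60, subjects = rep(sprintf("S%02d", 1:20), 9))
  plan_s <- make_group_kfold(ws_s, k = 10, group_key = "subject")
  for (fold in plan_s$folds) {
    expect_length(intersect(unique(ws_s$subject_ids[fold$train]),
                            unique(ws_s$subject_ids[fold$test])), 0)
  }
  expect_error(make_group_kfold(ws_s, k = 30, group_key = "subject"),
               "exceeds")
})

test_that("overlapping windows are refused by the leakage-aware strategies", {
  ws_a <- toy_windows(30, scheme = windowing_scheme("A"))
  expect_error(make_group_kfold(ws_a, k = 5), "temporal-leakage")
  expect_error(make_loso_folds(ws_a), "temporal-leakage")
  ## explicit opt-out still works
  expect_s3_class(make_group_kfold(ws_a, k = 5, paper_faithful = FALSE),
                  "split_plan")
})

test_that("LOSO folds hold out one subject with a stratified calibration cut", {
  classes <- c("A", "B")
  subjects <- rep(sprintf("S%02d", 1:4), each = 320)
  labels <- rep(rep(classes, each = 160), 4)
  n <- length(labels)
  ws <- eegfdf:::window_set(array(0, c(n, 8, 2)), labels, classes, subjects,
                            paste0("r", seq_len(n)), rep(1L, n),
                            windowing_scheme("B"))
  plan <- make_loso_folds(ws, calib_frac = 0.20, seed = 1)
  expect_length(plan$folds, 4)
  for (fold in plan$folds) {
    eegfdf:::check_partition(fold, n)
    held <- c(fold$test, fold$calibration)
    expect_equal(unique(ws$subject_ids[held]), fold$subject)
    expect_false(fold$subject %in% ws$subject_ids[fold$train])
    ## 160 windows per class, 20% calibration: 32 per class
    expect_equal(unname(table(ws$labels[fold$calibration])), c(32L, 32L),
                 ignore_attr = TRUE)
    expect_equal(length(fold$train), n - 320)
  }
  two <- make_loso_folds(subset_windows(ws, ws$subject_ids %in%
                                          c("S01", "S02")))
  expect_length(two$folds, 2)
  one <- subset_windows(ws, ws$subject_ids == "S01")
  expect_error(make_loso_folds(one), "2 subjects")
})

test_that("the metric suite matches direct contingency arithmetic", {
  ## perfect classifier
  perfect <- compute_metrics(diag(c(5L, 8L, 2L)))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$balanced_accuracy, 1)
  expect_equal(perfect$macro_f1, 1)
  expect_equal(perfect$weighted_precision, 1)

  ## worked 3-class example
  m <- compute_metrics(matrix(c(5, 0, 0, 1, 4, 0, 0, 2, 3), 3, byrow = TRUE))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$balanced_accuracy, 0.8)
  expect_equal(unname(m$per_class_recall), c(1.0, 0.8, 0.6))
  expect_equal(m$weighted_precision, 0.8333, tolerance = 1e-4)
  expect_equal(m$macro_f1, 0.7955, tolerance = 1e-4)
})

test_that("metrics agree with a brute-force per-sample oracle", {
  set.seed(12)
  for (i in 1:500) {
    C <- sample(2:6, 1)
    counts <- matrix(rpois(C * C, lambda = 3), C)
    if (sum(counts) == 0) counts[1, 1] <- 1
    got <- suppressWarnings(compute_metrics(counts))
    want <- suppressWarnings(brute_force_metrics(counts))
    expect_equal(got$accuracy, want$accuracy, tolerance = 1e-12)
    expect_equal(got$weighted_precision, want$weighted_precision,
                 tolerance = 1e-12)
    expect_equal(got$macro_f1, want$macro_f1, tolerance = 1e-12)
    expect_equal(got$weighted_f1, want$weighted_f1, tolerance = 1e-12)
    expect_equal(got$balanced_accuracy, want$balanced_accuracy,
                 tolerance = 1e-12)
    ## support-weighted recall is accuracy; balanced accuracy is macro recall
    expect_equal(want$weighted_recall, got$accuracy, tolerance = 1e-12)
    live <- is.finite(got$per_class_recall)
    expect_equal(mean(got$per_class_recall[live]), got$balanced_accuracy,
                 tolerance = 1e-12)
  }
})

test_that("uniform random predictions approach chance accuracy", {
  set.seed(3)
  C <- 5; N <- 20000
  truth <- sample(C, N, replace = TRUE)
  pred <- sample(C, N, replace = TRUE)
  m <- compute_metrics(confusion_matrix(truth, pred,
                                        class_labels = as.character(1:5)))
  expect_equal(m$accuracy, 1 / C, tolerance = 0.02)
})

test_that("zero-support classes are excluded from macro averages with warning", {
  counts <- matrix(0L, 3, 3)
  counts[1, 1] <- 4; counts[2, 2] <- 2; counts[2, 1] <- 2
  expect_warning(m <- compute_metrics(counts), "zero support")
  expect_true(is.nan(m$per_class_recall[3]))
  expect_equal(m$balanced_accuracy, mean(c(1, 0.5)))
})

test_that("the CI margin follows the Student-t convention", {
  expect_equal(ci_margin(c(3, 3, 3, 3)), 0)
  expect_equal(ci_margin(c(0, 1)), 6.353, tolerance = 1e-3)
  v <- c(0.3, 0.5, 0.8, 0.2, 0.9)
  expect_equal(ci_margin(v + 10), ci_margin(v))
  expect_error(ci_margin(1), "at least 2")
})

test_that("summary-level Welch t reproduces raw-data computation", {
  set.seed(8)
  for (i in 1:25) {
    a <- rnorm(5, mean = 90, sd = runif(1, 0.5, 4))
    b <- rnorm(5, mean = 85, sd = runif(1, 0.5, 4))
    got <- welch_t_from_summary(mean(a), ci_margin(a), mean(b), ci_margin(b),
                                n = 5)
    ref <- t.test(a, b)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-9)
  }
  ## equal means give t = 0; swapping groups flips the sign
  expect_equal(welch_t_from_summary(50, 1, 50, 2, 5)$t, 0)
  w1 <- welch_t_from_summary(60, 1, 50, 2, 5)
  w2 <- welch_t_from_summary(50, 2, 60, 1, 5)
  expect_equal(w1$t, -w2$t)
  expect_equal(w1$df, w2$df)
})

test_that("effect-size conversions follow both design conventions", {
  expect_equal(cohen_d(4.12, 5, "independent_equal_n"), 2.61,
               tolerance = 5e-3)
  expect_equal(cohen_d(42.64, 20, "paired"), 9.54, tolerance = 5e-3)
  expect_equal(cohen_d(0, 10, "paired"), 0)
  expect_equal(cohen_d(0, 10, "independent_equal_n"), 0)
})

test_that("run_strategy produces the documented result-table shape", {
  fx <- separable_dataset(n_subjects = 2, n_classes = 3, trials_per_class = 2,
                          seed = 101, n_samples = 128)
  res <- run_strategy(fx$ds$manifest, fx$ds$recordings, "random_multiseed",
                      arch = arch_spec("CNN-1-LSTM", 3),
                      filter = filter_spec("full_band"),
                      train_cfg = training_config(max_epochs = 3, seed = 1),
                      seeds = 1:2)
  expect_equal(nrow(res$per_fold), 2L)
  expect_true(all(c("accuracy", "balanced_accuracy", "macro_f1",
                    "weighted_precision") %in% names(res$per_fold)))
  expect_equal(nrow(res$aggregate), 5L)
  expect_length(res$confusions, 2L)
  expect_true(all(res$per_fold$accuracy >= 0 & res$per_fold$accuracy <= 1))
})

test_that("the leakage audit catches overlapping train/test windows", {
  ws <- toy_windows(10, scheme = windowing_scheme("A"))
  ## windows share recording id and overlapping sample ranges
  ws$recording_ids <- rep("r1", 30)
  ws$starts <- rep(1L, 30)
  fold <- list(train = 1:20, test = 21:30)
  expect_error(eegfdf:::audit_leakage(ws, fold), "leakage audit")
  ## disjoint sample intervals pass
  ws$starts <- seq(1L, by = 40L, length.out = 30)
  expect_true(eegfdf:::audit_leakage(ws, fold))
})
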