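#' Build a confusion matrix
#'
#' @param truth,predicted Factors (or vectors coercible to factors) over the
#'   same class levels; rows of the result are true classes, columns
#'   predictions.
#' @param class_labels Ordered class labels; defaults to the union of levels.
#' @return An object of class `confusion_matrix` (integer C x C matrix).
#' @export
confusion_matrix <- function(truth, predicted, class_labels = NULL) {
  if (is.null(class_labels)) {
    class_labels <- sort(union(unique(as.character(truth)),
                               unique(as.character(predicted))))
  }
  t_f <- factor(as.character(truth), levels = class_labels)
  p_f <- factor(as.character(predicted), levels = class_labels)
  cm <- table(truth = t_f, predicted = p_f)
  structure(matrix(as.integer(cm), nrow = length(class_labels),
                   dimnames = list(truth = class_labels,
                                   predicted = class_labels)),
            class = c("confusion_matrix", "matrix"))
}

as_confusion_matrix <- function(counts, class_labels = NULL) {
  if (!is.matrix(counts) || nrow(counts) != ncol(counts)) {
    stop("confusion counts must be a square matrix", call. = FALSE)
  }
  if (any(counts < 0)) stop("negative confusion counts", call. = FALSE)
  if (is.null(class_labels)) class_labels <- as.character(seq_len(nrow(counts)))
  structure(matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = list(truth = class_labels,
                                   predicted = class_labels)),
            class = c("confusion_matrix", "matrix"))
}

#' Metric suite from a confusion matrix
#'
#' Computes accuracy (correct / N), weighted precision (support-weighted
#' per-class precision), per-class recall, weighted and macro F1, and
#' balanced accuracy (the unweighted mean of per-class recalls, identical to
#' macro-averaged recall). Classes with zero support are excluded from macro
#' averages with a warning; their per-class values are `NaN`.
#'
#' @param cm A `confusion_matrix` or square count matrix.
#' @return List of class `metric_report`.
#' @export
compute_metrics <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) cm <- as_confusion_matrix(cm)
  counts <- unclass(cm)
  N <- sum(counts)
  if (N < 1) stop("empty confusion matrix", call. = FALSE)
  C <- nrow(counts)
  tp <- diag(counts)
  support <- rowSums(counts)          # tp + fn
  predicted <- colSums(counts)        # tp + fp
  w <- support / N

  precision <- ifelse(predicted > 0, tp / predicted, NaN)
  recall <- ifelse(support > 0, tp / support, NaN)
  f1 <- ifelse(is.finite(precision) & is.finite(recall) &
                 (precision + recall) > 0,
               2 * precision * recall / (precision + recall), 0)
  f1[!is.finite(precision) | !is.finite(recall)] <- NaN

  live <- support > 0
  if (!all(live)) {
    warning("classes with zero support excluded from macro averages: ",
            paste(rownames(counts)[!live], collapse = ", "), call. = FALSE)
  }
  ## per-class precision can be NaN (class never predicted); treated as 0
  ## inside weighted/macro sums, matching the guarded-division convention
  prec_w <- ifelse(is.finite(precision), precision, 0)
  f1_w <- ifelse(is.finite(f1), f1, 0)

  structure(list(
    accuracy = sum(tp) / N,
    weighted_precision = sum(w[live] * prec_w[live]),
    per_class_precision = precision,
    per_class_recall = recall,
    per_class_f1 = f1,
    weighted_f1 = sum(w[live] * f1_w[live]),
    macro_f1 = mean(f1_w[live]),
    balanced_accuracy = mean(recall[live]),
    support = support, n = N, n_classes = C),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<metric_report> n = %d, %d classes\n",
    "  accuracy           %.4f\n  balanced accuracy  %.4f\n",
    "  weighted precision %.4f\n  macro F1           %.4f\n",
    "  weighted F1        %.4f\n"),
    x$n, x$n_classes, x$accuracy, x$balanced_accuracy,
    x$weighted_precision, x$macro_f1, x$weighted_f1))
  invisible(x)
}

#' 95% confidence-interval margin of error
#'
#' Student-t margin `t_crit(level, n-1) * sd / sqrt(n)` for the mean of a
#' small sample, the convention used to report mean +/- margin across seeds
#' or subjects.
#'
#' @param values Numeric vector, length >= 2.
#' @param level Confidence level (default 0.95).
#' @return The margin of error (half-width of the CI).
#' @export
ci_margin <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 2L) stop("ci_margin requires at least 2 values", call. = FALSE)
  stats::qt(1 - (1 - level) / 2, df = n - 1) * stats::sd(values) / sqrt(n)
}

#' Welch t-test from mean +/- margin summaries
#'
#' Recovers each group's standard deviation from its reported 95% CI margin
#' (`sd = margin * sqrt(n) / t_crit(0.975, n-1)`), then computes the Welch
#' t-statistic and Welch-Satterthwaite degrees of freedom.
#'
#' @param mean1,margin1 First group's mean and CI margin.
#' @param mean2,margin2 Second group's mean and CI margin.
#' @param n Per-group sample size (equal n).
#' @return List with `t`, `df`, and the recovered `sd1`, `sd2`.
#' @export
welch_t_from_summary <- function(mean1, margin1, mean2, margin2, n) {
  if (n < 2L) stop("n must be at least 2", call. = FALSE)
  tc <- stats::qt(0.975, df = n - 1)
  sd1 <- margin1 * sqrt(n) / tc
  sd2 <- margin2 * sqrt(n) / tc
  se2 <- sd1^2 / n + sd2^2 / n
  t_stat <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / ((sd1^2 / n)^2 / (n - 1) + (sd2^2 / n)^2 / (n - 1))
  list(t = t_stat, df = df, sd1 = sd1, sd2 = sd2)
}

#' Cohen's d from a t statistic
#'
#' `d = t * sqrt(2/n)` for an independent two-group design with equal n;
#' `d = t / sqrt(n)` for a paired design.
#'
#' @param t The t statistic.
#' @param n Per-group (or pair) sample size.
#' @param design `"independent_equal_n"` or `"paired"`.
#' @return Cohen's d.
#' @export
cohen_d <- function(t, n, design = c("independent_equal_n", "paired")) {
  design <- match.arg(design)
  if (n < 2L) stop("n must be at least 2", call. = FALSE)
  switch(design,
         independent_equal_n = t * sqrt(2 / n),
         paired = t / sqrt(n))
}
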