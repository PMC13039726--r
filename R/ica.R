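#' ICA artifact-rejection configuration
#'
#' Controls the first pipeline phase: the multichannel signal is reduced by
#' PCA to the smallest rank explaining at least `variance_retained` of total
#' variance, unmixed into independent components, and components whose
#' artifact statistic exceeds `reject_threshold_sigma` standard deviations of
#' the across-component score distribution are zeroed before reconstruction.
#'
#' @param reject_threshold_sigma Rejection threshold in across-component
#'   standard deviations (default 2.5).
#' @param variance_retained Fraction of variance kept by the PCA reduction
#'   (default 0.9999).
#' @param artifact_statistic `"peak_z"` (peak amplitude relative to the
#'   component's own spread), `"kurtosis_z"`, or `"max_of_both"` (default).
#' @param fit_scope `"per_subject"` (default; one label-blind fit over all of
#'   a subject's recordings) or `"per_recording"`.
#' @param max_iter,tol Fixed-point iteration controls.
#' @param seed Seed for the unmixing initialization.
#' @return An object of class `ica_config`.
#' @export
ica_config <- function(reject_threshold_sigma = 2.5,
                       variance_retained = 0.9999,
                       artifact_statistic = c("max_of_both", "peak_z",
                                              "kurtosis_z"),
                       fit_scope = c("per_subject", "per_recording"),
                       max_iter = 200, tol = 1e-6, seed = 1L) {
  artifact_statistic <- match.arg(artifact_statistic)
  fit_scope <- match.arg(fit_scope)
  if (variance_retained <= 0 || variance_retained > 1) {
    stop("variance_retained must be in (0, 1]", call. = FALSE)
  }
  if (reject_threshold_sigma <= 0) {
    stop("reject_threshold_sigma must be positive", call. = FALSE)
  }
  structure(list(reject_threshold_sigma = reject_threshold_sigma,
                 variance_retained = variance_retained,
                 artifact_statistic = artifact_statistic,
                 fit_scope = fit_scope, max_iter = as.integer(max_iter),
                 tol = tol, seed = as.integer(seed)),
            class = "ica_config")
}

## FastICA with tanh contrast and symmetric decorrelation on whitened data.
## Z: r x T whitened matrix (unit covariance rows). Returns orthogonal W.
fastica_symm <- function(Z, max_iter, tol) {
  r <- nrow(Z); Tn <- ncol(Z)
  W <- matrix(stats::rnorm(r * r), r, r)
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    Gp <- 1 - G^2
    W_new <- (G %*% t(Z)) / Tn - diag(rowMeans(Gp), r) %*% W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(diag(W_new %*% t(W))) - 1))
    W <- W_new
    if (delta < tol) break
  }
  W
}

sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)),
                     length(e$values)) %*% t(e$vectors) %*% W
}

excess_kurtosis <- function(x) {
  x <- x - mean(x)
  mean(x^4) / mean(x^2)^2 - 3
}

ica_clean_group <- function(X, config, channel_names) {
  C <- nrow(X); Tn <- ncol(X)
  if (any(!is.finite(X))) stop("non-finite values in ICA input", call. = FALSE)
  ch_sd <- apply(X, 1, stats::sd)
  if (any(ch_sd == 0)) {
    stop("constant channel prevents component analysis: ",
         channel_names[which(ch_sd == 0)[1]], call. = FALSE)
  }
  mu <- rowMeans(X)
  Xc <- X - mu
  cv <- (Xc %*% t(Xc)) / (Tn - 1)
  e <- eigen(cv, symmetric = TRUE)
  frac <- cumsum(e$values) / sum(e$values)
  r <- which(frac >= config$variance_retained)[1]
  r <- max(r, 2L)
  Kw <- diag(1 / sqrt(e$values[1:r]), r) %*% t(e$vectors[, 1:r, drop = FALSE])
  A_pca <- e$vectors[, 1:r, drop = FALSE] %*% diag(sqrt(e$values[1:r]), r)
  Z <- Kw %*% Xc

  W <- fastica_symm(Z, config$max_iter, config$tol)
  S <- W %*% Z                      # r x T independent components
  A <- A_pca %*% t(W)               # channel-space mixing

  peak <- apply(S, 1, function(s) max(abs(s - mean(s))) / stats::sd(s))
  kurt <- apply(S, 1, excess_kurtosis)
  zscore <- function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  score <- switch(config$artifact_statistic,
                  peak_z = zscore(peak),
                  kurtosis_z = zscore(kurt),
                  max_of_both = pmax(zscore(peak), zscore(kurt)))
  rejected <- which(score > config$reject_threshold_sigma)

  S_clean <- S
  if (length(rejected) > 0L) S_clean[rejected, ] <- 0
  X_clean <- A %*% S_clean + mu

  list(clean = X_clean,
       report = data.frame(component = seq_len(r),
                           peak_stat = peak, kurtosis = kurt, score = score,
                           rejected = seq_len(r) %in% rejected),
       rank = r, rejected = rejected)
}

#' ICA artifact removal across recordings
#'
#' Fits ICA label-blind per subject (default) or per recording, scores every
#' component with the configured artifact statistic, zeroes components beyond
#' the rejection threshold, and reconstructs the cleaned channel-space
#' signal. Groups with fewer than `10 * n_channels^2` samples are skipped
#' with a warning (identity transform) because the unmixing estimate would be
#' unstable.
#'
#' @param recordings List of `eeg_recording`.
#' @param config An `ica_config`.
#' @return List with `recordings` (cleaned) and `report` (per-group
#'   data.frame of component scores and decisions, plus skip flags).
#' @export
ica_clean <- function(recordings, config = ica_config()) {
  stopifnot(length(recordings) > 0L, inherits(config, "ica_config"))
  nc <- n_channels(recordings[[1]])
  if (nc < 2L) stop("ICA requires at least 2 channels", call. = FALSE)

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  groups <- if (config$fit_scope == "per_subject") {
    split(seq_along(recordings),
          vapply(recordings, `[[`, "", "subject_id"))
  } else {
    as.list(seq_along(recordings))
  }

  out <- recordings
  reports <- list()
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    lens <- vapply(recordings[idx], n_samples, 0L)
    X <- do.call(cbind, lapply(recordings[idx], `[[`, "data"))
    gname <- if (config$fit_scope == "per_subject")
      recordings[[idx[1]]]$subject_id else
      sprintf("rec_%d", idx[1])
    if (ncol(X) < 10 * nc^2) {
      warning(sprintf(
        "ICA group %s has %d samples (< %d needed); skipping with identity",
        gname, ncol(X), 10 * nc^2), call. = FALSE)
      reports[[g]] <- data.frame(group = gname, component = NA_integer_,
                                 peak_stat = NA_real_, kurtosis = NA_real_,
                                 score = NA_real_, rejected = NA,
                                 skipped = TRUE)
      next
    }
    res <- ica_clean_group(X, config, recordings[[idx[1]]]$channel_names)
    offs <- c(0L, cumsum(lens))
    for (k in seq_along(idx)) {
      cols <- (offs[k] + 1L):offs[k + 1L]
      out[[idx[k]]]$data <- res$clean[, cols, drop = FALSE]
      rownames(out[[idx[k]]]$data) <- recordings[[idx[k]]]$channel_names
    }
    rep_g <- res$report
    rep_g$group <- gname
    rep_g$skipped <- FALSE
    reports[[g]] <- rep_g
  }
  list(recordings = out, report = do.call(rbind, reports))
}
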