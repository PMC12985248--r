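# Evaluation metrics: pointwise RMSE, heart-rate mean absolute error via
# the R-peak detector, and the Frechet distance between Gaussian fits to
# window distributions.

#' Root-mean-square error between two windows
#'
#' @param x,x_hat Equal-length amplitude vectors (or matrices, one window
#'   per column, reduced jointly).
#' @return Non-negative scalar.
#' @export
metric_rmse <- function(x, x_hat) {
  stopifnot(length(x) == length(x_hat))
  sqrt(mean((x - x_hat)^2))
}

#' Heart rate of an ECG window
#'
#' Detects R-peaks ([detect_rpeaks()]); with at least two peaks the rate is
#' `60 * fs * (n_peaks - 1) / (last - first)` BPM, otherwise `NA`
#' (the window is excluded from HR-MAE).
#'
#' @param window ECG amplitude vector.
#' @param fs Sampling rate in Hz.
#' @param peaks Optional precomputed peak indices (skips detection).
#' @return BPM, or `NA_real_` if fewer than two peaks are found.
#' @export
hr_from_window <- function(window, fs, peaks = NULL) {
  stopifnot(fs > 0)
  if (is.null(peaks)) peaks <- detect_rpeaks(window, fs)
  if (length(peaks) < 2L) return(NA_real_)
  60 * fs * (length(peaks) - 1L) / (peaks[length(peaks)] - peaks[1L])
}

#' Heart-rate mean absolute error over paired window sets
#'
#' @param true_windows,gen_windows L x N matrices (one window per column)
#'   or lists of equal length.
#' @param fs Sampling rate in Hz.
#' @return A list with `hr_mae` (mean absolute BPM deviation over pairs
#'   where both rates are defined) and `n_used`.
#' @export
metric_hr_mae <- function(true_windows, gen_windows, fs) {
  tw <- if (is.list(true_windows)) true_windows else
    lapply(seq_len(ncol(true_windows)), function(j) true_windows[, j])
  gw <- if (is.list(gen_windows)) gen_windows else
    lapply(seq_len(ncol(gen_windows)), function(j) gen_windows[, j])
  stopifnot(length(tw) == length(gw))
  bt <- vapply(tw, hr_from_window, numeric(1), fs = fs)
  bg <- vapply(gw, hr_from_window, numeric(1), fs = fs)
  ok <- !is.na(bt) & !is.na(bg)
  if (!any(ok)) {
    warning("no window pair with two detected peaks in both signals")
    return(list(hr_mae = NA_real_, n_used = 0L))
  }
  list(hr_mae = mean(abs(bt[ok] - bg[ok])), n_used = sum(ok))
}

#' Frechet distance between two sets of signal windows
#'
#' Fits a Gaussian (mean vector, covariance with ridge `ridge * I`) to each
#' set, treating each window as one high-dimensional vector, and returns
#' the squared Wasserstein-2 distance
#' `||mu_r - mu_g||^2 + tr(S_r + S_g - 2 (S_r S_g)^{1/2})`.  The matrix
#' square root is computed through the symmetrized product
#' `S_r^{1/2} S_g S_r^{1/2}`; a tiny negative trace residue is clamped
#' to zero.
#'
#' @param real,generated n x L and m x L matrices (one window per row),
#'   `n, m >= 2`.
#' @param ridge Ridge added to both covariance diagonals (default 1e-6).
#' @return Non-negative scalar.
#' @export
frechet_distance <- function(real, generated, ridge = 1e-6) {
  real <- as.matrix(real); generated <- as.matrix(generated)
  if (nrow(real) < 2L || nrow(generated) < 2L)
    stop("need at least two windows per set")
  stopifnot(ncol(real) == ncol(generated))
  mu_r <- colMeans(real); mu_g <- colMeans(generated)
  d <- ncol(real)
  S_r <- stats::cov(real) + ridge * diag(d)
  S_g <- stats::cov(generated) + ridge * diag(d)
  er <- eigen(S_r, symmetric = TRUE)
  sq_r <- er$vectors %*% (sqrt(pmax(er$values, 0)) * t(er$vectors))
  M <- sq_r %*% S_g %*% sq_r
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  tr_term <- sum(diag(S_r)) + sum(diag(S_g)) - 2 * sum(sqrt(pmax(ev, 0)))
  fd <- sum((mu_r - mu_g)^2) + tr_term
  if (fd < 0 && fd > -1e-6) fd <- 0
  fd
}

#' Evaluate generated windows against real ones
#'
#' @param true_windows L x N matrix of real (normalized) ECG windows.
#' @param gen_windows L x N matrix of generated windows (aligned columns).
#' @param fs Sampling rate in Hz.
#' @return A list of class `"physdiff_metrics"`: `rmse`, `hr_mae`, `fd`,
#'   and the window counts used per metric.
#' @export
evaluate_windows <- function(true_windows, gen_windows, fs = 128) {
  true_windows <- as_mat(true_windows); gen_windows <- as_mat(gen_windows)
  stopifnot(dim(true_windows) == dim(gen_windows))
  hr <- metric_hr_mae(true_windows, gen_windows, fs)
  structure(list(
    rmse = metric_rmse(true_windows, gen_windows),
    hr_mae = hr$hr_mae,
    fd = if (ncol(true_windows) >= 2L)
      frechet_distance(t(true_windows), t(gen_windows)) else NA_real_,
    n_windows = ncol(true_windows), n_windows_hr = hr$n_used),
    class = "physdiff_metrics")
}

#' @export
print.physdiff_metrics <- function(x, ...) {
  cat(sprintf("RMSE   %.4f   (n = %d windows)\n", x$rmse, x$n_windows))
  cat(sprintf("HR-MAE %.3f BPM (n = %d windows with detectable rate)\n",
              x$hr_mae, x$n_windows_hr))
  cat(sprintf("FD     %.4f\n", x$fd))
  invisible(x)
}
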