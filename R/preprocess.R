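# Preprocessing: resampling, windowing, instance min-max normalization,
# simplified Pan-Tompkins R-peak detection, QRS region-of-interest masks.

#' Band-limited resampling
#'
#' Fourier-domain resampling: the spectrum is truncated (downsampling) or
#' zero-padded (upsampling) and inverted at the new length
#' `round(length(x) * fs_out / fs_in)`.  A constant signal stays exactly
#' constant; band-limited content is interpolated without aliasing.
#'
#' @param x Amplitude vector (length >= 2).
#' @param fs_in,fs_out Input/output sampling rates in Hz (> 0).
#' @return Resampled amplitude vector.
#' @export
resample_signal <- function(x, fs_in, fs_out) {
  if (fs_in <= 0 || fs_out <= 0) stop("sampling rates must be positive")
  stopifnot(length(x) >= 2)
  if (fs_in == fs_out) return(x)
  n <- length(x)
  n_out <- round(n * fs_out / fs_in)
  X <- stats::fft(x)
  Y <- complex(length.out = n_out)
  nk <- min(n, n_out)
  hi <- (nk + 1L) %/% 2L                 # positive-frequency bins (excl. DC)
  Y[1L:hi] <- X[1L:hi]
  lo <- nk - hi                          # negative-frequency bins
  if (lo > 0L) Y[(n_out - lo + 1L):n_out] <- X[(n - lo + 1L):n]
  if (nk %% 2L == 0L) {
    # shared Nyquist bin: split (upsampling) or fold (downsampling)
    if (n_out > n) {
      Y[hi + 1L] <- X[hi + 1L] / 2
      Y[n_out - hi + 1L] <- X[hi + 1L] / 2
    } else {
      Y[hi + 1L] <- X[hi + 1L] + if (n > n_out) X[n - hi + 1L] else 0
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Segment a signal into non-overlapping windows
#'
#' @param x Amplitude vector.
#' @param window_len Window length in samples (>= 1).
#' @return A list of `floor(length(x)/window_len)` windows; the trailing
#'   remainder is dropped.
#' @export
segment_signal <- function(x, window_len = 512L) {
  stopifnot(window_len >= 1)
  n_win <- floor(length(x) / window_len)
  if (n_win == 0L) return(list())
  lapply(seq_len(n_win), function(i)
    x[((i - 1L) * window_len + 1L):(i * window_len)])
}

#' Instance-wise min-max normalization to [-1, 1]
#'
#' Maps `x` to `2 * (x - min) / (max - min) - 1`.  A constant window cannot
#' be scaled; it is returned as all zeros with `degenerate = TRUE`.
#'
#' @param x Finite amplitude vector.
#' @return A list with `x` (normalized vector), `norm_params`
#'   (`c(min, max)`, allowing exact inversion via [minmax_denormalize()]),
#'   and `degenerate` (logical).
#' @export
minmax_normalize <- function(x) {
  stopifnot(all(is.finite(x)))
  lo <- min(x); hi <- max(x)
  if (hi == lo)
    return(list(x = rep(0, length(x)), norm_params = c(min = lo, max = hi),
                degenerate = TRUE))
  list(x = 2 * (x - lo) / (hi - lo) - 1, norm_params = c(min = lo, max = hi),
       degenerate = FALSE)
}

#' Invert instance min-max normalization
#'
#' @param x_norm Normalized vector in `[-1, 1]`.
#' @param norm_params `c(min, max)` as returned by [minmax_normalize()].
#' @return The de-normalized vector.
#' @export
minmax_denormalize <- function(x_norm, norm_params) {
  lo <- norm_params[[1]]; hi <- norm_params[[2]]
  if (hi == lo) return(rep(lo, length(x_norm)))
  (x_norm + 1) / 2 * (hi - lo) + lo
}

#' Simplified Pan-Tompkins R-peak detection
#'
#' Band-pass (5-15 Hz Butterworth, zero-phase), differentiate, square,
#' 150 ms moving-window integration, adaptive threshold with a 200 ms
#' refractory period, and refinement to the local ECG maximum within
#' +/- 25 ms.
#'
#' @param ecg Amplitude vector (at least 1 s of samples for detection; an
#'   input shorter than the integrator returns an empty result).
#' @param fs Sampling rate in Hz (> 0).
#' @return Sorted integer vector of 1-based R-peak indices (possibly empty).
#' @export
detect_rpeaks <- function(ecg, fs) {
  stopifnot(fs > 0)
  n <- length(ecg)
  wi <- max(1L, round(0.150 * fs))     # integrator width
  if (n <= wi || stats::sd(ecg) == 0) return(integer(0))
  ny <- fs / 2
  bp <- signal::butter(2, c(5, min(15, 0.9 * ny)) / ny, type = "pass")
  f <- signal::filtfilt(bp, ecg)
  d <- c(diff(f), 0)
  sq <- d^2
  integ <- stats::filter(sq, rep(1 / wi, wi), sides = 2)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)
  # adaptive threshold: running signal/noise level estimates
  thr <- 0.25 * stats::quantile(integ, 0.98)
  if (thr <= 0) return(integer(0))
  refr <- round(0.200 * fs)
  # candidate local maxima above threshold
  is_pk <- integ > thr &
    integ >= c(-Inf, integ[-n]) & integ >= c(integ[-1], -Inf)
  cand <- which(is_pk)
  if (length(cand) == 0L) return(integer(0))
  # greedy refractory enforcement, updating the threshold adaptively
  spk <- integ[cand[1]]; npk <- thr
  peaks <- integer(0); last <- -Inf
  for (p in cand) {
    t_adapt <- npk + 0.25 * (spk - npk)
    if (integ[p] < t_adapt) { npk <- 0.125 * integ[p] + 0.875 * npk; next }
    if (p - last < refr) {
      if (length(peaks) && integ[p] > integ[peaks[length(peaks)]]) {
        peaks[length(peaks)] <- p; last <- p
        spk <- 0.125 * integ[p] + 0.875 * spk
      }
      next
    }
    peaks <- c(peaks, p); last <- p
    spk <- 0.125 * integ[p] + 0.875 * spk
  }
  if (length(peaks) == 0L) return(integer(0))
  # refine to the local ECG maximum within +/- 25 ms
  half <- max(1L, as.integer(round(0.025 * fs)))
  refined <- vapply(as.integer(peaks), function(p) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    lo + which.max(ecg[lo:hi]) - 1L
  }, integer(1))
  sort(unique(refined))
}

#' Binary QRS region-of-interest mask
#'
#' `mask[t] = 1` iff some peak `p` satisfies `|t - p| <= half_width`
#' (33 samples per interior peak at the default half-width), clipped at the
#' window edges and unioned over peaks.
#'
#' @param r_peaks 1-based peak indices within `[1, L]`.
#' @param L Window length in samples.
#' @param half_width Half-width of the QRS region in samples (default 16).
#' @return Integer vector of length `L` with values in `{0, 1}`.
#' @export
build_roi_mask <- function(r_peaks, L, half_width = 16L) {
  stopifnot(L >= 1, half_width >= 0)
  if (length(r_peaks)) stopifnot(all(r_peaks >= 1), all(r_peaks <= L))
  mask <- integer(L)
  for (p in r_peaks) {
    lo <- max(1L, p - half_width); hi <- min(L, p + half_width)
    mask[lo:hi] <- 1L
  }
  mask
}

#' Convert paired recordings into model-ready signal windows
#'
#' Resamples to `target_fs`, segments into non-overlapping windows of
#' `window_s` seconds, min-max normalizes each channel per window, and
#' builds the QRS mask.  Ground-truth simulator peaks are used for the mask
#' when present; otherwise peaks are detected with [detect_rpeaks()].
#'
#' @param records A list of paired recordings (see [generate_dataset()]).
#' @param target_fs Target sampling rate in Hz (default 128).
#' @param window_s Window length in seconds (default 4; L = 512 at 128 Hz).
#' @param roi_half_width QRS mask half-width in samples (default 16).
#' @return A list of signal windows, each a list with `ppg`, `ecg` (length-L
#'   vectors in `[-1, 1]`), `mask`, `r_peaks` (1-based, window-local),
#'   `fs`, `norm_ppg`, `norm_ecg`, `degenerate`, `window_index`,
#'   `record_id`, `rhythm`.
#' @export
make_windows <- function(records, target_fs = 128, window_s = 4,
                         roi_half_width = 16L) {
  L <- round(target_fs * window_s)
  out <- list()
  for (rec in records) {
    ecg <- rec$ecg; ppg <- rec$ppg
    peaks <- rec$r_peaks
    if (!is.null(rec$fs) && rec$fs != target_fs) {
      ecg <- resample_signal(ecg, rec$fs, target_fs)
      ppg <- resample_signal(ppg, rec$fs, target_fs)
      if (!is.null(peaks))
        peaks <- pmax(1L, pmin(length(ecg),
                               round((peaks - 1L) * target_fs / rec$fs) + 1L))
    }
    if (is.null(peaks)) peaks <- detect_rpeaks(ecg, target_fs)
    n_win <- floor(min(length(ecg), length(ppg)) / L)
    if (n_win == 0L) next
    for (i in seq_len(n_win)) {
      a <- (i - 1L) * L + 1L; b <- i * L
      pk <- peaks[peaks >= a & peaks <= b] - a + 1L
      ne <- minmax_normalize(ecg[a:b])
      np <- minmax_normalize(ppg[a:b])
      out[[length(out) + 1L]] <- list(
        ppg = np$x, ecg = ne$x,
        mask = build_roi_mask(pk, L, roi_half_width),
        r_peaks = as.integer(pk), fs = target_fs,
        norm_ppg = np$norm_params, norm_ecg = ne$norm_params,
        degenerate = ne$degenerate || np$degenerate,
        window_index = i, record_id = rec$record_id %||% NA_integer_,
        rhythm = rec$rhythm %||% NA_character_)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
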