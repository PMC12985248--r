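# Synthetic paired PPG-ECG generator with known ground truth.
#
# The simulator stands in for clinical waveform databases during development
# and testing: it produces quasi-periodic ECG built from per-beat Gaussian
# wave templates (P, Q, R, S, T), and a PPG whose pulse onsets lag the
# electrical R-peaks by a controllable pulse transit time (PTT).

#' Simulation configuration for paired PPG-ECG records
#'
#' @param heart_rate_bpm Mean heart rate in beats per minute.
#' @param rr_cv Coefficient of variation of the RR intervals (unitless,
#'   in `[0, 1)`).  Atrial-fibrillation-like rhythm forces at least 0.15.
#' @param rhythm `"regular"` or `"af_like"` (irregularly irregular RR
#'   intervals, the simulator's emulation of atrial fibrillation).
#' @param ptt_s Pulse transit time in seconds: the delay from each R-peak to
#'   the onset of the corresponding PPG pulse.
#' @param fs Sampling rate in Hz.
#' @param duration_s Record duration in seconds.
#' @param noise_sd Standard deviation of additive white noise on the PPG.
#' @param baseline_wander_amp Amplitude of the low-frequency baseline
#'   wander added to the PPG.
#' @param seed Integer seed; every random draw for a record flows from it.
#'
#' @return An object of class `"sim_config"` (a named list).
#' @export
sim_config <- function(heart_rate_bpm = 75, rr_cv = 0.03,
                       rhythm = c("regular", "af_like"),
                       ptt_s = 0.25, fs = 128, duration_s = 60,
                       noise_sd = 0.02, baseline_wander_amp = 0.1,
                       seed = 1L) {
  rhythm <- match.arg(rhythm)
  stopifnot(heart_rate_bpm > 0, rr_cv >= 0, rr_cv < 1, ptt_s >= 0,
            fs > 0, duration_s > 0, noise_sd >= 0, baseline_wander_amp >= 0)
  if (rhythm == "af_like") rr_cv <- max(rr_cv, 0.15)
  # templates contain energy up to roughly 40 Hz; require Nyquist above that
  if (fs < 80) stop("fs too low for the ECG wave templates (need >= 80 Hz)")
  structure(list(heart_rate_bpm = heart_rate_bpm, rr_cv = rr_cv,
                 rhythm = rhythm, ptt_s = ptt_s, fs = fs,
                 duration_s = duration_s, noise_sd = noise_sd,
                 baseline_wander_amp = baseline_wander_amp,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Per-beat wave parameters for unit RR (offsets and widths in seconds
# relative to the R-peak, amplitudes in arbitrary units, R dominant positive).
.ecg_waves <- data.frame(
  wave   = c("P", "Q", "R", "S", "T"),
  offset = c(-0.200, -0.045, 0.000, 0.045, 0.300),
  width  = c(0.045, 0.012, 0.016, 0.015, 0.070),
  amp    = c(0.12, -0.12, 1.00, -0.18, 0.28)
)

#' Generate a synthetic ECG with known R-peak locations
#'
#' RR intervals are drawn from a Gaussian with mean `60/heart_rate_bpm`
#' seconds and standard deviation `rr_cv` times the mean, truncated to
#' `[0.3, 2]` s.  Each beat is the sum of five Gaussian bumps (P, Q, R, S,
#' T) whose offsets scale with the local RR interval.
#'
#' @param config A [sim_config()].
#' @return A list with `ecg` (amplitude vector at `config$fs`) and
#'   `r_peaks` (1-based sample indices of the R waves, strictly increasing).
#' @export
generate_ecg <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$fs
  n <- round(config$duration_s * fs)
  rr_mean <- 60 / config$heart_rate_bpm
  rng <- make_rng(config$seed)
  # draw more beats than can fit, then trim
  n_beats_max <- ceiling(config$duration_s / 0.3) + 2L
  rr <- rng$rnorm(n_beats_max, mean = rr_mean, sd = config$rr_cv * rr_mean)
  rr <- pmin(pmax(rr, 0.3), 2.0)
  beat_t <- 0.5 * rr_mean + cumsum(c(0, rr[-length(rr)]))
  # keep beats whose full template (T wave) fits the record
  keep <- beat_t + 0.45 * rr < config$duration_s & beat_t > 0.25 * rr_mean
  beat_t <- beat_t[keep]
  rr_kept <- rr[keep]
  if (length(beat_t) == 0L)
    stop("duration too short for a single beat (empty record)")
  t <- (seq_len(n) - 1) / fs
  ecg <- numeric(n)
  for (b in seq_along(beat_t)) {
    scale <- rr_kept[b] / 1.0
    for (w in seq_len(nrow(.ecg_waves))) {
      mu <- beat_t[b] + .ecg_waves$offset[w] * scale
      sd_w <- .ecg_waves$width[w] * sqrt(scale)
      lo <- max(1L, floor((mu - 5 * sd_w) * fs) + 1L)
      hi <- min(n, ceiling((mu + 5 * sd_w) * fs) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      ecg[idx] <- ecg[idx] +
        .ecg_waves$amp[w] * exp(-0.5 * ((t[idx] - mu) / sd_w)^2)
    }
  }
  r_peaks <- round(beat_t * fs) + 1L
  r_peaks <- r_peaks[r_peaks >= 1L & r_peaks <= n]
  list(ecg = ecg, r_peaks = as.integer(r_peaks))
}

# Log-normal pulse kernel: steep upstroke, slow decay.  Parameters chosen so
# the steepest discrete upstroke sits at the kernel onset (within 2 samples
# at 128 Hz), which is what defines "pulse onset" throughout the package.
.ppg_kernel <- function(fs, dur_s = 0.7, sigma = 0.9, mode_s = 0.06) {
  tt <- seq(1 / fs, dur_s, by = 1 / fs)
  mu <- log(mode_s) + sigma^2   # mode of the log-normal density = exp(mu - sigma^2)
  k <- exp(-(log(tt) - mu)^2 / (2 * sigma^2)) / tt
  k / max(k)
}

#' Generate a synthetic PPG from R-peak locations
#'
#' Each R-peak contributes one smooth unimodal pulse (log-normal kernel:
#' fast upstroke, slower decay) starting `round(ptt_s * fs)` samples after
#' the peak.  Baseline wander (a low-frequency sinusoid) and white noise are
#' added last.
#'
#' @param r_peaks Sorted 1-based R-peak sample indices.
#' @param config A [sim_config()].
#' @param length_out Output length in samples (must cover `max(r_peaks)`).
#' @return Amplitude vector of length `length_out`.
#' @export
generate_ppg <- function(r_peaks, config, length_out) {
  stopifnot(inherits(config, "sim_config"), length_out >= 1)
  if (length(r_peaks) > 0) {
    stopifnot(!is.unsorted(r_peaks), max(r_peaks) <= length_out)
  }
  fs <- config$fs
  ppg <- numeric(length_out)
  kern <- .ppg_kernel(fs)
  lag <- round(config$ptt_s * fs)
  for (p in r_peaks) {
    onset <- p + lag
    idx <- onset:min(length_out, onset + length(kern) - 1L)
    idx <- idx[idx >= 1L]
    if (length(idx) == 0L) next
    ppg[idx] <- ppg[idx] + kern[seq_along(idx)]
  }
  rng <- make_rng(config$seed + 7919L)  # independent stream from the ECG draws
  if (config$baseline_wander_amp > 0) {
    phase <- rng$runif(1, 0, 2 * pi)
    tt <- (seq_len(length_out) - 1) / fs
    ppg <- ppg + config$baseline_wander_amp * sin(2 * pi * 0.25 * tt + phase)
  } else {
    rng$runif(1)  # keep the stream aligned across configs
  }
  if (config$noise_sd > 0)
    ppg <- ppg + rng$rnorm(length_out, sd = config$noise_sd)
  ppg
}

#' Generate a dataset of paired PPG-ECG records
#'
#' Record `i` uses `seed + i - 1`, so records are individually reproducible
#' and pairwise distinct.
#'
#' @param n_records Number of records (>= 1).
#' @param config A [sim_config()] used as the template for every record.
#' @param seed Dataset-level seed; overrides `config$seed` per record.
#' @param af_fraction If not `NA`, each record's rhythm is drawn Bernoulli
#'   with this probability of `"af_like"` (overriding `config$rhythm`).
#' @param hr_range Optional length-2 vector; each record's mean heart rate
#'   is drawn uniformly from this range (BPM).
#' @param ptt_range Optional length-2 vector; each record's PTT is drawn
#'   uniformly from this range (seconds).
#' @return A list of paired recordings, each a list with fields `ecg`,
#'   `ppg`, `r_peaks`, `rhythm`, `ptt_s`, `fs`, `record_id`.
#' @export
generate_dataset <- function(n_records, config, seed = config$seed,
                             af_fraction = NA, hr_range = NULL,
                             ptt_range = NULL) {
  stopifnot(n_records >= 1)
  meta_rng <- make_rng(seed + 104729L)
  af_draw <- if (!is.na(af_fraction))
    meta_rng$runif(n_records) < af_fraction else NULL
  hr_draw <- if (!is.null(hr_range))
    meta_rng$runif(n_records, hr_range[1], hr_range[2]) else NULL
  ptt_draw <- if (!is.null(ptt_range))
    meta_rng$runif(n_records, ptt_range[1], ptt_range[2]) else NULL
  lapply(seq_len(n_records), function(i) {
    cfg <- config
    cfg$seed <- as.integer(seed + i - 1L)
    if (!is.null(af_draw)) {
      cfg$rhythm <- if (af_draw[i]) "af_like" else "regular"
      if (cfg$rhythm == "af_like") cfg$rr_cv <- max(cfg$rr_cv, 0.15)
    }
    if (!is.null(hr_draw)) cfg$heart_rate_bpm <- hr_draw[i]
    if (!is.null(ptt_draw)) cfg$ptt_s <- ptt_draw[i]
    e <- generate_ecg(cfg)
    n <- length(e$ecg)
    p <- generate_ppg(e$r_peaks, cfg, n)
    list(ecg = e$ecg, ppg = p, r_peaks = e$r_peaks, rhythm = cfg$rhythm,
         ptt_s = cfg$ptt_s, fs = cfg$fs, record_id = i)
  })
}

# Seeded RNG handle isolated from the global .Random.seed.
make_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed %% .Machine$integer.max)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  with_state <- function(fn) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, envir = globalenv())
      out <- fn(...)
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
      out
    }
  }
  list(rnorm = with_state(stats::rnorm),
       runif = with_state(stats::runif),
       sample_int = with_state(function(n, size, replace = TRUE)
         sample.int(n, size, replace = replace)))
}
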