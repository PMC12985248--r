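# Resampling, segmentation, normalization, R-peak detection, ROI masks.

test_that("resampling preserves identity, length ratio, and DC level", {
  x <- sin(seq(0, 20 * pi, length.out = 1280))
  expect_identical(resample_signal(x, 128, 128), x)
  y <- resample_signal(sin(seq(0, 20 * pi, length.out = 2560)), 256, 128)
  expect_length(y, 1280L)
  z <- resample_signal(rep(2.5, 1000), 500, 128)
  expect_length(z, 256L)
  expect_true(all(abs(z - 2.5) < 1e-6))
  expect_error(resample_signal(x, -1, 128), "positive")
})

test_that("segmentation drops the remainder and conserves samples", {
  x <- seq_len(1280)
  w <- segment_signal(x, 512L)
  expect_length(w, 2L)
  expect_identical(w[[1]], 1:512)
  expect_identical(w[[2]], 513:1024)
  expect_length(segment_signal(seq_len(512), 512L), 1L)
  expect_length(segment_signal(seq_len(511), 512L), 0L)
  # conservation: concatenation reproduces the first floor(n/L)*L samples
  x2 <- stats::rnorm(1300)
  expect_identical(unlist(segment_signal(x2, 512L)), x2[1:1024])
})

test_that("min-max normalization maps to [-1, 1] and inverts exactly", {
  r <- minmax_normalize(c(0, 5, 10))
  expect_equal(r$x, c(-1, 0, 1))
  expect_false(r$degenerate)
  # fixed point: already spanning [-1, 1]
  x <- c(-1, -0.2, 0.7, 1)
  expect_equal(minmax_normalize(x)$x, x)
  # degenerate constant window
  rc <- minmax_normalize(rep(3, 8))
  expect_true(rc$degenerate)
  expect_identical(rc$x, rep(0, 8))
  expect_equal(minmax_denormalize(rc$x, rc$norm_params), rep(3, 8))
  # round trip on random windows
  set.seed(5)
  for (i in 1:20) {
    x <- stats::rnorm(512, sd = stats::runif(1, 0.1, 10))
    n <- minmax_normalize(x)
    expect_equal(min(n$x), -1)
    expect_equal(max(n$x), 1)
    expect_lt(max(abs(minmax_denormalize(n$x, n$norm_params) - x)), 1e-10)
  }
})

test_that("R-peak detector recovers clean synthetic peaks (F1 >= 0.95)", {
  cfg <- sim_config(heart_rate_bpm = 60, rr_cv = 0, duration_s = 10,
                    fs = 128, seed = 1)
  e <- generate_ecg(cfg)
  det <- detect_rpeaks(e$ecg, 128)
  tp <- sum(vapply(det, function(p) any(abs(e$r_peaks - p) <= 5), TRUE))
  prec <- tp / length(det); rec <- tp / length(e$r_peaks)
  expect_gte(prec, 0.95)
  expect_gte(rec, 0.95)
})

test_that("detector edge cases: silence, short input, single beat", {
  expect_identical(detect_rpeaks(numeric(512), 128), integer(0))
  expect_identical(detect_rpeaks(numeric(10), 128), integer(0))
  cfg <- sim_config(heart_rate_bpm = 40, rr_cv = 0, duration_s = 3,
                    fs = 128, seed = 1)
  e <- generate_ecg(cfg)
  one <- e$ecg
  k <- e$r_peaks[1]
  det <- detect_rpeaks(one, 128)
  expect_true(any(abs(det - k) <= 5))
})

test_that("ROI mask is the indicator of |t - t_p| <= half_width", {
  m <- build_roi_mask(100L, 512L)
  expect_equal(sum(m), 33)
  expect_equal(which(m == 1L), 84:116)
  expect_identical(build_roi_mask(integer(0), 64L), integer(64))
  # peak 6 samples from the start (position 5 in 0-based coordinates)
  edge <- build_roi_mask(6L, 512L)
  expect_equal(which(edge == 1L), 1:22)
  expect_equal(sum(edge), 22)
  # symmetry about an interior peak
  m2 <- build_roi_mask(250L, 512L)
  expect_identical(m2[250 - 16:1], m2[250 + 1:16])
  # union over close peaks stays binary
  m3 <- build_roi_mask(c(100L, 110L), 512L)
  expect_true(all(m3 %in% c(0L, 1L)))
  expect_equal(which(m3 == 1L), 84:126)
})

test_that("make_windows emits normalized 512-sample windows with masks", {
  w <- tiny_windows()
  expect_gt(length(w), 0)
  for (win in w[1:3]) {
    expect_length(win$ecg, 512L)
    expect_length(win$ppg, 512L)
    expect_equal(range(win$ecg), c(-1, 1))
    expect_equal(range(win$ppg), c(-1, 1))
    expect_true(all(win$mask %in% c(0L, 1L)))
    expect_true(all(win$r_peaks >= 1 & win$r_peaks <= 512))
    # mask matches the ground-truth peaks
    expect_identical(win$mask, build_roi_mask(win$r_peaks, 512L))
  }
})
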