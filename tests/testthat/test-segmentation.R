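test_that("mean short-term energy evaluates the defining formula", {
  e <- short_term_energy(rep(2, 500), n = 100)
  expect_true(all(e$values == 4))            # mean of 2^2
  expect_equal(e$n, 100L)
  e2 <- short_term_energy(c(1, 2, 3, 4), n = 2, hop = 2)
  expect_equal(e2$values, c(2.5, 12.5))      # (1+4)/2, (9+16)/2
  expect_equal(e2$start_sample, c(0L, 2L))
  expect_error(short_term_energy(1:5, n = 10), "shorter")
  # trailing partial window dropped
  e3 <- short_term_energy(rep(1, 250), n = 100, hop = 100)
  expect_length(e3$values, 2L)
})

test_that("channel combination is the root-sum-of-squares and is symmetric", {
  m <- matrix(c(3, 0, 4, 0), nrow = 2)       # rows: samples, cols: channels
  expect_equal(combine_channels(m), c(5, 0))
  one <- matrix(c(1.5, -2), ncol = 1)
  expect_equal(combine_channels(one), c(1.5, 2))
  set.seed(1)
  x <- matrix(rnorm(40), 10, 4)
  expect_equal(combine_channels(x), combine_channels(x[, 4:1]))
})

test_that("threshold calibration implements the ratio-times-max rule", {
  cal1 <- calibrate_thresholds(list(
    list(energy = c(1, 8, 2), start_idx = 2, end_idx = 2)), holdout_ek_max = 5)
  expect_equal(cal1$STS, 5)                  # ratio 1 -> holdout max
  cal2 <- calibrate_thresholds(list(
    list(energy = c(2, 8), start_idx = 1, end_idx = 2),
    list(energy = c(1, 4), start_idx = 1, end_idx = 2)), holdout_ek_max = 10)
  expect_equal(cal2$STS, mean(c(2 / 8, 1 / 4)) * 10)   # = 2.5
  expect_equal(cal2$STE, 10)
  # ratios are scale-free
  cal3 <- calibrate_thresholds(list(
    list(energy = c(20, 80), start_idx = 1, end_idx = 2),
    list(energy = c(10, 40), start_idx = 1, end_idx = 2)), holdout_ek_max = 10)
  expect_equal(cal3$STS, cal2$STS)
  expect_error(calibrate_thresholds(list(), 1), "empty")
})

test_that("look-back/look-ahead counts follow the fs/(2n) rules", {
  p <- segmentation_params(1500, 100)
  expect_equal(p$l, 8L)                      # 7.5 rounded half-to-even
  expect_equal(p$m, 11L)                     # midpoint of (7.5, 15)
  expect_true(1500 / 200 < p$m && p$m < 1500 / 100)
  expect_equal(segmentation_params(2000, 100)$l, 10L)
  expect_error(segmentation_params(150, 100), "degenerate")
  expect_equal(segmentation_params(1500, 100, l = 7, m = 12)$l, 7L)
})

test_that("detection follows the onset/offset rules on a hand-traced series", {
  # 10 quiet windows, 12-window plateau, then a decaying tail
  e <- make_energy(c(rep(0.01, 10), rep(10, 12), 0.02, rep(0.01, 7)))
  params <- segmentation_params(1500, 100)
  calib <- make_calib(sts = 1, ste = 1)
  segs <- detect_segments(e, calib, params)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$start_sample, 1000L)     # rising-edge window (11th)
  expect_equal(segs$end_sample, 2200L)       # first window below STE (23rd)
  # everywhere below threshold -> empty
  quiet <- make_energy(rep(0.5, 30))
  expect_equal(nrow(detect_segments(quiet, calib, params)), 0L)
  # 4-window blip (~267 ms) dropped by the minimum-duration rule
  blip <- make_energy(c(rep(0.01, 10), 10, 10, 10, 10, 0.02, rep(0.01, 10)))
  expect_equal(nrow(detect_segments(blip, calib, params)), 0L)
  expect_equal(nrow(detect_segments(blip, calib, params,
                                    min_duration_s = 0.2)), 1L)
})

test_that("segments are recovered near ground truth and never overlap", {
  fx <- fixture_filtered()
  n_hit <- 0; n_tot <- 0
  for (i in seq_along(fx$recs)) {
    segs <- segment_recording(fx$recs[[i]], fx$calib, fx$params)
    if (nrow(segs) > 1) {
      expect_true(all(diff(segs$start_sample) > 0))
      expect_true(all(segs$start_sample[-1] >= segs$end_sample[-nrow(segs)]))
    }
    b <- fx$ds$recordings[[i]]$bursts
    if (nrow(b) == 0) next
    n_tot <- n_tot + 1
    if (nrow(segs) == 0) next
    j <- which.min(abs(segs$start_sample - b$start_sample))
    err <- max(abs(segs$start_sample[j] - b$start_sample),
               abs(segs$end_sample[j] - b$end_sample))
    if (err <= 2 * fx$params$n) n_hit <- n_hit + 1
  }
  expect_gte(n_hit / n_tot, 0.9)
})

test_that("segmentation is equivariant under amplitude rescaling", {
  fx <- fixture_filtered()
  rec <- fx$recs[[1]]
  segs1 <- segment_recording(rec, fx$calib, fx$params)
  scaled <- rec
  scaled$samples <- rec$samples * 3
  # energies scale by 9; recalibrated thresholds scale along
  calib_scaled <- make_calib(fx$calib$STS * 9, fx$calib$STE * 9)
  segs2 <- segment_recording(scaled, calib_scaled, fx$params)
  expect_equal(segs1, segs2)
  # and Ek itself is quadratic in the scale
  e1 <- short_term_energy(combine_channels(rec), n = 100)
  e2 <- short_term_energy(combine_channels(scaled), n = 100)
  expect_equal(e2$values, 9 * e1$values, tolerance = 1e-12)
})

test_that("per-window onset look-ahead is at least as strict as the mean rule", {
  e <- make_energy(c(rep(0.01, 10), 10, 0.5, 10, 10, 10, 10, 10, 10, 10, 10,
                     10, 10, 0.02, rep(0.01, 7)))
  params <- segmentation_params(1500, 100)
  calib <- make_calib(1, 1)
  s_mean <- detect_segments(e, calib, params, lookahead = "mean")
  s_pw <- detect_segments(e, calib, params, lookahead = "per_window")
  expect_gte(nrow(s_mean), nrow(s_pw))
  if (nrow(s_pw) > 0 && nrow(s_mean) > 0) {
    expect_gte(s_pw$start_sample[1], s_mean$start_sample[1])
  }
})
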