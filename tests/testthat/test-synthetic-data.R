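test_that("recordings have the acquisition geometry and are seed-deterministic", {
  profs <- subject_profiles(2, seed = 1)
  r1 <- generate_recording("falling", profs[[1]], duration_s = 4, seed = 1)
  r2 <- generate_recording("falling", profs[[1]], duration_s = 4, seed = 1)
  expect_equal(dim(r1$samples), c(6000L, 4L))   # 4 s x 1500 Hz, 4 channels
  expect_equal(r1$fs_hz, 1500)
  expect_true(all(is.finite(r1$samples)))
  expect_identical(r1$samples, r2$samples)
  r3 <- generate_recording("falling", profs[[1]], duration_s = 4, seed = 2)
  expect_false(identical(r1$samples, r3$samples))
  expect_error(generate_recording("falling", profs[[1]], duration_s = -1),
               "positive")
})

test_that("burst-free control recordings are baseline noise at the profile SD", {
  profs <- subject_profiles(2, seed = 3)
  r <- generate_recording("walking", profs[[1]], duration_s = 4, seed = 5,
                          amplitude_scale = 0)
  expect_equal(nrow(r$bursts), 0L)
  sds <- apply(r$samples, 2, sd)
  expected <- profs[[1]]$gain * profs[[1]]$baseline_noise_sd
  expect_true(all(abs(sds / expected - 1) < 0.2))
  expect_lt(max(abs(colMeans(r$samples))), 3 * max(expected) / sqrt(6000) * 4)
})

test_that("dataset counts and LOSO tagging match the study structure", {
  ds <- generate_dataset(10, 10, seed = 7)
  expect_length(ds$recordings, 400L)
  expect_equal(sum(ds$manifest$gesture == "falling"), 100L)
  expect_equal(sort(unique(ds$manifest$subject_id)), 1:10)
  tiny <- generate_dataset(2, 1, seed = 0)
  expect_length(tiny$recordings, 8L)
  expect_equal(sum(tiny$manifest$gesture == "falling"), 2L)
  expect_error(generate_dataset(1, 1), ">= 2")
})

test_that("ground-truth burst intervals lie inside their recordings", {
  ds <- fixture_dataset()
  for (r in ds$recordings) {
    if (nrow(r$bursts) == 0) next
    expect_gte(r$bursts$start_sample, 0)
    expect_lt(r$bursts$start_sample, r$bursts$end_sample)
    expect_lte(r$bursts$end_sample, nrow(r$samples))
  }
})

test_that("falling and sitting recordings differ in mean spectral centroid", {
  centroid <- function(rec) {
    b <- rec$bursts
    x <- rec$samples[(b$start_sample + 1):b$end_sample, 1]
    p <- Mod(fft(x))^2
    f <- (seq_along(p) - 1) * rec$fs_hz / length(p)
    keep <- f > 0 & f <= rec$fs_hz / 2
    sum(f[keep] * p[keep]) / sum(p[keep])
  }
  ds <- fixture_dataset()
  cf <- vapply(ds$recordings[ds$manifest$gesture == "falling"], centroid,
               numeric(1))
  cs <- vapply(ds$recordings[ds$manifest$gesture == "sitting"], centroid,
               numeric(1))
  expect_gt(mean(cf) - mean(cs), 40)   # broad-band falls vs low-band sitting
})

test_that("class spectral separation grows with burst amplitude", {
  class_dist <- function(scale) {
    ds <- generate_dataset(2, 2, seed = 13, amplitude_scale = scale)
    mean_spec <- function(g) {
      recs <- ds$recordings[ds$manifest$gesture == g]
      sp <- lapply(recs, function(r) {
        b <- r$bursts
        if (nrow(b) == 0) return(NULL)
        x <- r$samples[(b$start_sample + 1):b$end_sample, 1][1:1500]
        Mod(fft(x))[1:750]
      })
      sp <- Filter(Negate(is.null), sp)
      Reduce(`+`, sp) / length(sp)
    }
    sqrt(sum((mean_spec("falling") - mean_spec("sitting"))^2))
  }
  d <- vapply(c(0.5, 1, 2), class_dist, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("easy and hard noise settings are both constructible and ordered", {
  pe <- subject_profiles(2, seed = 1, noise = "easy")
  ph <- subject_profiles(2, seed = 1, noise = "hard")
  expect_gt(ph[[1]]$baseline_noise_sd, 3 * pe[[1]]$baseline_noise_sd)
  pn <- subject_profiles(2, seed = 1, noise = 0.2)
  expect_gt(pn[[1]]$baseline_noise_sd, 0)
})

test_that("optional mains interference injects a 50 Hz line", {
  profs <- subject_profiles(2, seed = 2)
  r0 <- generate_recording("sitting", profs[[1]], 4, seed = 9,
                           amplitude_scale = 0)
  r1 <- generate_recording("sitting", profs[[1]], 4, seed = 9,
                           amplitude_scale = 0, mains_hz = 50)
  p_at <- function(rec, f_hz) {
    p <- Mod(fft(rec$samples[, 1]))^2
    f <- (seq_along(p) - 1) * rec$fs_hz / length(p)
    p[which.min(abs(f - f_hz))]
  }
  expect_gt(p_at(r1, 50), 50 * p_at(r0, 50))
})
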