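test_that("Hamming window matches its defining cosine form", {
  w301 <- hamming_window(301, 0.46)
  expect_equal(w301[151], 1.0)               # center: (1-a) + a
  w300 <- hamming_window(300, 0.46)
  expect_equal(w300[1], 0.08)                # n = 0: 0.54 - 0.46
  expect_equal(w300, rev(w300))              # symmetry
  n <- 0:299
  expect_equal(w300, 0.54 - 0.46 * cos(2 * pi * n / 299))
  expect_error(hamming_window(1), ">= 2")
  expect_error(hamming_window(300, a = 1.2), "0, 1")
})

test_that("framing yields floor((len - window)/step) + 1 frames", {
  f <- frame_windows(seq_len(600), window = 300, step = 150)
  expect_equal(nrow(f), 3L)
  expect_equal(attr(f, "start_sample"), c(0L, 150L, 300L))
  expect_equal(f[2, ], 151:450)
  f1 <- frame_windows(seq_len(300), window = 300, step = 150)
  expect_equal(nrow(f1), 1L)
  expect_equal(f1[1, ], 1:300)
  expect_warning(f0 <- frame_windows(seq_len(299), window = 300, step = 150),
                 "shorter")
  expect_equal(nrow(f0), 0L)
})

test_that("spectrogram peaks at the tone frequency and is normalized to [0,1]", {
  fs <- 1500
  t <- (0:(fs - 1)) / fs
  x <- sin(2 * pi * 100 * t)
  sp <- compute_spectrogram(x, fs)
  expect_true(all(sp$freq_hz >= 10 & sp$freq_hz <= 500))
  expect_true(all(diff(sp$freq_hz) > 0))
  expect_equal(max(sp$mag), 1)
  expect_gte(min(sp$mag), 0)
  peak_bin <- apply(sp$mag, 1, which.max)
  nearest_100 <- which.min(abs(sp$freq_hz - 100))
  expect_true(all(peak_bin == nearest_100))
  # all-zero input: degenerate, normalization skipped
  spz <- compute_spectrogram(rep(0, 1500), fs)
  expect_true(spz$norm$degenerate)
  expect_true(all(spz$mag == 0))
})

test_that("spectrogram magnitudes equal the DFT of the weighted frame", {
  fs <- 1500
  set.seed(8)
  x <- rnorm(300)
  sp <- compute_spectrogram(x, fs, normalize = FALSE)
  w <- hamming_window(300)
  X <- fft(c(x * w, rep(0, 212)))            # zero-padded to 512
  freq <- (0:511) * fs / 512
  keep <- freq >= 10 & freq <= 500
  expect_equal(as.numeric(sp$mag[1, ]), Mod(X)[keep], tolerance = 1e-12)
  # Parseval on the full transform of the same frame
  expect_equal(sum(Mod(X)^2) / 512, sum((x * w)^2), tolerance = 1e-10)
})

test_that("PCA loadings are orthonormal and ordered by explained variance", {
  set.seed(11)
  frames <- matrix(rnorm(200 * 30), 200, 30)
  pca <- fit_pca(frames, k = 8)
  expect_equal(crossprod(pca$loadings), diag(8), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(pca$var_ratio) <= 1e-12))
  expect_true(all(pca$var_ratio >= 0))
  expect_true(all(diff(pca$cum_ratio) >= 0))
  expect_lte(pca$cum_ratio[8], 1)
  rep8 <- variance_report(pca)
  expect_equal(rep8$cumulative_pct, cumsum(rep8$variance_pct))
  expect_error(fit_pca(frames, k = 31), "bins")
})

test_that("a rank-1 spectrum family is explained by one component", {
  set.seed(5)
  base <- abs(rnorm(40))
  gains <- runif(100, 0.5, 2)
  frames <- outer(gains, base) + matrix(rnorm(100 * 40, sd = 1e-4), 100, 40)
  pca <- fit_pca(frames, k = 3)
  expect_gte(pca$var_ratio[1], 0.99)
})

test_that("projection mean-centres and reconstructs within discarded energy", {
  set.seed(21)
  frames <- matrix(rnorm(20 * 15), 20, 15)
  pca <- fit_pca(frames, k = 8)
  expect_equal(as.numeric(apply_pca(matrix(pca$mean, 1), pca)),
               rep(0, 8), tolerance = 1e-10)
  expect_equal(ncol(apply_pca(frames, pca)), 8L)
  full <- fit_pca(frames, k = 15)
  scores <- apply_pca(frames, pca)
  recon <- sweep(scores %*% t(pca$loadings), 2, pca$mean, `+`)
  err <- sqrt(rowSums((frames - recon)^2))
  discarded <- sqrt(rowSums(apply_pca(frames, full)[, 9:15, drop = FALSE]^2))
  expect_equal(err, discarded, tolerance = 1e-8)
  expect_error(apply_pca(matrix(0, 2, 9), pca), "bins")
})

test_that("time-domain features match hand-evaluated cases", {
  f <- time_domain_features(c(1, -1, 1, -1), eps = 0.1)
  expect_equal(f[["MAV"]], 1)
  expect_equal(f[["VAR"]], 1)
  expect_equal(f[["WL"]], 6)
  expect_equal(f[["RMS"]], 1)
  expect_equal(f[["ZC"]], 3)
  expect_equal(f[["SSC"]], 1)
  g <- time_domain_features(rep(3.5, 4), eps = 0.1)
  expect_equal(unname(g[c("MAV", "VAR", "WL", "RMS", "ZC", "SSC")]),
               c(3.5, 0, 0, 3.5, 0, 0))
  expect_error(time_domain_features(c(1, 2)), "3 samples")
})

test_that("time-domain features scale homogeneously", {
  set.seed(31)
  x <- rnorm(300)
  f1 <- time_domain_features(x, eps = 0.05)
  f2 <- time_domain_features(2 * x, eps = 0.10)   # eps doubled alongside
  expect_equal(f2[["MAV"]], 2 * f1[["MAV"]])
  expect_equal(f2[["WL"]], 2 * f1[["WL"]])
  expect_equal(f2[["RMS"]], 2 * f1[["RMS"]])
  expect_equal(f2[["VAR"]], 4 * f1[["VAR"]])
  expect_equal(f2[["ZC"]], f1[["ZC"]])
  expect_equal(f2[["SSC"]], f1[["SSC"]])
  # power-mean inequality, not RMS >= MAV elementwise
  expect_gte(f1[["RMS"]]^2, f1[["MAV"]]^2)
})

test_that("feature tensors stack frames x components x channels", {
  fx <- fixture_filtered()
  tn <- fixture_tensors()
  rec <- fx$recs[[1]]
  segs <- segment_recording(rec, fx$calib, fx$params)
  ft <- build_feature_tensor(rec, segs, tn$pca)
  expect_gt(length(ft), 0)
  d <- dim(ft[[1]]$spm)
  seg_len <- segs$end_sample[1] - segs$start_sample[1]
  expect_equal(d[1], (seg_len - 300) %/% 150 + 1)
  expect_equal(d[2], 8L)
  expect_equal(d[3], 4L)
  expect_false(ft[[1]]$degenerate)
  expect_equal(sort(unique(ft[[1]]$td$channel)), 1:4)
  # a segment shorter than one window is skipped with a warning
  tiny <- data.frame(start_sample = 0L, end_sample = 200L)
  expect_warning(out <- build_feature_tensor(rec, tiny, tn$pca), "skipped")
  expect_length(out, 0L)
})

test_that("tensor blocks cover the frame axis and pad short segments", {
  a <- array(seq_len(12 * 8 * 4), c(12, 8, 4))
  bl <- tensor_blocks(a, height = 8, block_step = 4)
  expect_length(bl, 2L)
  expect_equal(bl[[1]], a[1:8, , , drop = FALSE])
  expect_equal(bl[[2]], a[5:12, , , drop = FALSE])
  short <- array(1, c(5, 8, 4))
  blp <- tensor_blocks(short, height = 8)
  expect_length(blp, 1L)
  expect_equal(dim(blp[[1]]), c(8L, 8L, 4L))
  expect_true(all(blp[[1]][6:8, , ] == 0))
})
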