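# Shared fixtures, generated once per test run and cached.

.fx <- new.env(parent = emptyenv())

# Small easy-setting dataset: 3 subjects x 4 gestures x 4 reps = 48 recordings
fixture_dataset <- function() {
  if (is.null(.fx$ds)) .fx$ds <- generate_dataset(3, 4, seed = 7)
  .fx$ds
}

# The same dataset band-pass filtered, with calibrated thresholds
fixture_filtered <- function() {
  if (is.null(.fx$filtered)) {
    ds <- fixture_dataset()
    spec <- design_bandpass(ds$manifest$fs_hz[1])
    recs <- lapply(ds$recordings, apply_filter, spec = spec)
    params <- segmentation_params(ds$manifest$fs_hz[1], n = 100)
    calib <- calibrate_from_recordings(recs, params)
    .fx$filtered <- list(recs = recs, params = params, calib = calib,
                         manifest = ds$manifest, ds = ds)
  }
  .fx$filtered
}

# Segment-level reduced-spectrogram tensors + labels for model tests
fixture_tensors <- function() {
  if (is.null(.fx$tensors)) {
    fx <- fixture_filtered()
    tensors <- list(); labels <- character(0); frames <- list()
    for (i in seq_along(fx$recs)) {
      segs <- segment_recording(fx$recs[[i]], fx$calib, fx$params)
      if (nrow(segs) == 0) next
      r <- fx$recs[[i]]
      s <- r$samples[(segs$start_sample[1] + 1):segs$end_sample[1], ,
                     drop = FALSE]
      if (nrow(s) < 300) next
      frames[[length(frames) + 1]] <-
        lapply(1:4, function(ch) compute_spectrogram(s[, ch], r$fs_hz))
      labels <- c(labels, fx$manifest$gesture[i])
    }
    pool <- do.call(rbind, unlist(lapply(frames, function(f)
      lapply(f, `[[`, "mag")), recursive = FALSE))
    pca <- fit_pca(pool, k = 8)
    tensors <- lapply(frames, function(chs) {
      red <- lapply(chs, apply_pca, model = pca)
      array(unlist(red), c(nrow(red[[1]]), 8, 4))
    })
    .fx$tensors <- list(tensors = tensors, labels = labels, pca = pca)
  }
  .fx$tensors
}

# Hand-made energy series / calibration objects for rule-level tests
make_energy <- function(values, n = 100L, hop = n) {
  structure(list(values = values, n = as.integer(n), hop = as.integer(hop),
                 start_sample = (seq_along(values) - 1L) * as.integer(hop)),
            class = "energy_series")
}
make_calib <- function(sts, ste) {
  structure(list(STS = sts, STE = ste, ratio_start = NA, ratio_end = NA,
                 ek_max = NA), class = "threshold_calibration")
}
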