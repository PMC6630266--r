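#' Hamming window weights
#'
#' `W(n) = (1 - a) - a * cos(2 * pi * n / (N - 1))` for `n = 0..N-1`, with
#' the customary `a = 0.46`. The taper suppresses spectral leakage: the
#' first side lobe of its magnitude spectrum sits more than 40 dB below the
#' main lobe, which is why it is preferred over a rectangular window for
#' short-time Fourier analysis of sEMG.
#'
#' @param N window length in samples (>= 2).
#' @param a taper coefficient in (0, 1), default 0.46.
#' @return numeric vector of `N` weights.
#' @export
hamming_window <- function(N, a = 0.46) {
  if (!is.numeric(N) || length(N) != 1L || N < 2) stop("N must be an integer >= 2")
  if (a <= 0 || a >= 1) stop("a must lie in (0, 1)")
  n <- seq_len(N) - 1
  (1 - a) - a * cos(2 * pi * n / (N - 1))
}

#' Slice a signal into sliding analysis windows
#'
#' Frames start at 0, `step`, `2*step`, ...; the count is
#' `floor((len - window) / step) + 1`. The defaults (300-sample window,
#' 150-sample step) are 200 ms / 100 ms at 1500 Hz, short enough to keep
#' classification latency under 300 ms. A signal shorter than one window
#' yields zero frames with a warning.
#'
#' @param signal numeric vector.
#' @param window window length in samples (default 300).
#' @param step hop between frame starts in samples (default 150).
#' @return matrix `n_frames x window`; attribute `start_sample` holds the
#'   0-based start of each frame.
#' @export
frame_windows <- function(signal, window = 300L, step = 150L) {
  window <- as.integer(window); step <- as.integer(step)
  if (step < 1L || window < 1L) stop("window and step must be positive")
  if (step > window) stop("step must not exceed the window length")
  if (length(signal) < window) {
    warning("signal shorter than one window; returning zero frames")
    out <- matrix(numeric(0), nrow = 0, ncol = window)
    attr(out, "start_sample") <- integer(0)
    return(out)
  }
  starts <- seq.int(1L, length(signal) - window + 1L, by = step)
  idx <- outer(starts, 0:(window - 1L), `+`)
  out <- matrix(signal[idx], nrow = length(starts), ncol = window)
  attr(out, "start_sample") <- starts - 1L
  out
}

#' Short-time Fourier spectrogram of an active segment
#'
#' Per sliding frame, the magnitude of the FFT of the Hamming-weighted frame
#' is computed (zero-padded to `nfft`, the next power of two at or above the
#' window length by default). Bins outside the informative 10-500 Hz sEMG
#' band are discarded, and the retained magnitudes are min-max normalized to
#' `[0, 1]` so channels of different magnitude become comparable. An all-zero
#' segment yields an all-zero spectrogram flagged `degenerate` (normalization
#' skipped).
#'
#' @param segment numeric vector, one channel of one active segment.
#' @param fs_hz sampling rate.
#' @param window,step frame length and hop in samples (defaults 300/150).
#' @param a Hamming coefficient.
#' @param nfft FFT length (default next power of two >= `window`).
#' @param band two-element retained frequency band in Hz (default 10-500).
#' @param normalize min-max normalize to `[0, 1]` (default `TRUE`).
#' @param log_mag use `log1p` magnitude before normalization.
#' @return object of class `emg_spectrogram`: `mag` (`n_frames x n_bins`),
#'   `freq_hz`, `frame_times_s`, `norm` record.
#' @export
compute_spectrogram <- function(segment, fs_hz, window = 300L, step = 150L,
                                a = 0.46, nfft = NULL,
                                band = c(10, 500), normalize = TRUE,
                                log_mag = FALSE) {
  frames <- frame_windows(segment, window = window, step = step)
  if (nrow(frames) == 0L) stop("segment spans less than one analysis window")
  if (is.null(nfft)) nfft <- 2^ceiling(log2(window))
  w <- hamming_window(ncol(frames), a = a)
  weighted <- sweep(frames, 2, w, `*`)
  padded <- cbind(weighted, matrix(0, nrow(weighted), nfft - ncol(weighted)))
  spec <- stats::mvfft(t(padded))          # columns = frames
  freq <- (seq_len(nfft) - 1) * fs_hz / nfft
  keep <- which(freq >= band[1] & freq <= min(band[2], fs_hz / 2))
  mag <- t(Mod(spec[keep, , drop = FALSE]))  # frames x bins
  if (log_mag) mag <- log1p(mag)
  rng <- range(mag)
  degenerate <- !(rng[2] > rng[1])
  if (normalize && !degenerate) mag <- (mag - rng[1]) / (rng[2] - rng[1])
  structure(list(
    mag = mag, freq_hz = freq[keep],
    frame_times_s = (attr(frames, "start_sample") + window / 2) / fs_hz,
    norm = list(min = rng[1], max = rng[2], applied = normalize && !degenerate,
                degenerate = degenerate)),
    class = "emg_spectrogram")
}

#' Fit a PCA model on spectrogram frames
#'
#' Reduces the frequency direction of the spectrogram: each frame (a vector
#' over frequency bins) is projected onto `k` orthonormal loadings ordered by
#' explained variance. Fit on training-fold frames only, so held-out subjects
#' never influence the loadings. Eight components (`k = 8`, the default)
#' capture the dominant spectral structure of recorded sEMG; [variance_report()]
#' shows what they capture for a given fit.
#'
#' @param training_frames matrix `n_frames x n_freq_bins` of (normalized)
#'   spectrogram rows pooled over training segments and channels.
#' @param k number of components to keep (default 8).
#' @return object of class `emg_pca`: `mean`, `loadings`
#'   (`n_bins x k`, orthonormal), `var_ratio`, `cum_ratio`, `k`.
#' @export
fit_pca <- function(training_frames, k = 8L) {
  training_frames <- as.matrix(training_frames)
  k <- as.integer(k)
  if (k < 1L || k > ncol(training_frames)) {
    stop("k must lie in 1..number of frequency bins (", ncol(training_frames), ")")
  }
  if (nrow(training_frames) < k) stop("need at least k training frames")
  pc <- stats::prcomp(training_frames, center = TRUE, scale. = FALSE)
  var_all <- pc$sdev^2
  ratio <- var_all / sum(var_all)
  structure(list(mean = pc$center,
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 var_ratio = ratio[seq_len(k)],
                 cum_ratio = cumsum(ratio)[seq_len(k)],
                 all_var_ratio = ratio, k = k),
            class = "emg_pca")
}

#' Explained-variance report of a fitted PCA model
#'
#' @param model an `emg_pca`.
#' @return data frame with `component`, `variance_pct` (variance contribution
#'   rate, percent) and `cumulative_pct`.
#' @export
variance_report <- function(model) {
  stopifnot(inherits(model, "emg_pca"))
  data.frame(component = seq_len(model$k),
             variance_pct = 100 * model$var_ratio,
             cumulative_pct = 100 * model$cum_ratio)
}

#' Project a spectrogram onto a PCA model
#'
#' Frames are mean-centered with the model's training mean and projected onto
#' the loadings, giving a reduced spectrogram of `k` scores per frame.
#'
#' @param spec an `emg_spectrogram` (or a frames x bins matrix).
#' @param model an `emg_pca` whose bin count matches.
#' @return matrix `n_frames x k`.
#' @export
apply_pca <- function(spec, model) {
  stopifnot(inherits(model, "emg_pca"))
  mag <- if (inherits(spec, "emg_spectrogram")) spec$mag else as.matrix(spec)
  if (ncol(mag) != length(model$mean)) {
    stop("spectrogram has ", ncol(mag), " bins but the PCA model expects ",
         length(model$mean))
  }
  sweep(mag, 2, model$mean) %*% model$loadings
}

#' Classic myoelectric time-domain features of one analysis window
#'
#' Computes, for a single channel window `x` of length `n`:
#' mean absolute value `MAV = mean(|x|)`; population variance
#' `VAR = mean((x - mean(x))^2)`; waveform length
#' `WL = sum(|x[i+1] - x[i]|)`; root mean square `RMS = sqrt(mean(x^2))`;
#' zero crossings `ZC` = number of adjacent sign changes whose amplitude step
#' `|x[i] - x[i+1]|` reaches the dead-band `eps`; and slope sign change
#' `SSC` = mean over interior points of the indicator that
#' `(x[i] - x[i-1]) * (x[i+1] - x[i]) < 0`.
#'
#' @param window numeric vector of at least 3 samples (SSC needs interior
#'   points).
#' @param eps zero-crossing dead-band; if `NULL`, `eps_rel * RMS` is used.
#' @param eps_rel relative dead-band (default 0.01), keeping the feature
#'   invariant to the arbitrary amplitude units of sEMG hardware.
#' @return named numeric vector `MAV`, `VAR`, `WL`, `RMS`, `ZC`, `SSC`.
#' @export
time_domain_features <- function(window, eps = NULL, eps_rel = 0.01) {
  x <- as.numeric(window)
  n <- length(x)
  if (n < 3L) stop("window must contain at least 3 samples")
  rms <- sqrt(mean(x^2))
  if (is.null(eps)) eps <- eps_rel * rms
  if (eps < 0) stop("eps must be non-negative")
  mav <- mean(abs(x))
  vr <- mean((x - mean(x))^2)
  dx <- diff(x)
  wl <- sum(abs(dx))
  zc <- sum(x[-n] * x[-1] < 0 & abs(dx) >= eps)
  d1 <- dx[-(n - 1)]; d2 <- dx[-1]
  ssc <- mean(d1 * d2 < 0)
  c(MAV = mav, VAR = vr, WL = wl, RMS = rms, ZC = as.numeric(zc), SSC = ssc)
}

#' Time-domain feature table over sliding windows
#'
#' Applies [time_domain_features()] to every sliding window of every channel.
#'
#' @param samples numeric matrix (rows = samples, cols = channels) or vector.
#' @param window,step sliding window length and hop in samples.
#' @param eps_rel relative zero-crossing dead-band.
#' @return data frame: `window_idx`, `channel`, `start_sample`, and the six
#'   features.
#' @export
time_domain_table <- function(samples, window = 300L, step = 150L,
                              eps_rel = 0.01) {
  x <- as.matrix(samples)
  out <- list()
  for (ch in seq_len(ncol(x))) {
    fr <- suppressWarnings(frame_windows(x[, ch], window = window, step = step))
    if (nrow(fr) == 0L) next
    feats <- t(apply(fr, 1, time_domain_features, eps_rel = eps_rel))
    out[[ch]] <- data.frame(window_idx = seq_len(nrow(fr)), channel = ch,
                            start_sample = attr(fr, "start_sample"), feats)
  }
  if (length(out) == 0L) {
    warning("no channel spans a full window")
    return(data.frame())
  }
  do.call(rbind, out)
}

#' Build per-segment feature tensors for a recording
#'
#' For each active segment: per channel, the spectrogram is computed and
#' projected onto the supplied PCA model, and the channels are stacked into
#' a tensor `n_frames x k x n_channels`; a parallel time-domain feature
#' table is computed over the same sliding windows. Segments shorter than
#' one analysis window are skipped with a warning.
#'
#' @param rec an [emg_recording()] (normally band-pass filtered).
#' @param segments data frame with `start_sample`, `end_sample` (0-based,
#'   half-open), e.g. from [segment_recording()].
#' @param pca an `emg_pca` fitted on training-fold frames.
#' @param window,step analysis window and hop in samples.
#' @param ... further arguments to [compute_spectrogram()].
#' @return list of per-segment lists: `spm` (array `frames x k x channels`),
#'   `td` (time-domain table), `start_sample`, `end_sample`, `degenerate`.
#' @export
build_feature_tensor <- function(rec, segments, pca, window = 300L,
                                 step = 150L, ...) {
  stopifnot(inherits(rec, "emg_recording"))
  n_ch <- ncol(rec$samples)
  out <- list()
  for (i in seq_len(nrow(segments))) {
    s0 <- segments$start_sample[i]; s1 <- segments$end_sample[i]
    seg <- rec$samples[(s0 + 1):s1, , drop = FALSE]
    if (nrow(seg) < window) {
      warning("segment ", i, " shorter than one analysis window; skipped")
      next
    }
    degenerate <- FALSE
    per_ch <- vector("list", n_ch)
    for (ch in seq_len(n_ch)) {
      sp <- compute_spectrogram(seg[, ch], fs_hz = rec$fs_hz, window = window,
                                step = step, ...)
      if (sp$norm$degenerate) degenerate <- TRUE
      per_ch[[ch]] <- apply_pca(sp, pca)
    }
    nf <- nrow(per_ch[[1]])
    spm <- array(unlist(per_ch), dim = c(nf, pca$k, n_ch))
    out[[length(out) + 1]] <- list(
      spm = spm,
      td = time_domain_table(seg, window = window, step = step),
      start_sample = s0, end_sample = s1, degenerate = degenerate)
  }
  out
}

#' Cut a segment tensor into fixed-height network inputs
#'
#' The convolutional classifier takes fixed-size inputs of `height` frames;
#' a segment's frame axis is cut into overlapping blocks (`block_step`
#' frames apart). Segments with fewer than `height` frames are zero-padded
#' at the end into a single block.
#'
#' @param tensor array `n_frames x k x n_channels`.
#' @param height block height in frames (default 8).
#' @param block_step hop between blocks in frames (default 4).
#' @return list of arrays `height x k x n_channels`.
#' @export
tensor_blocks <- function(tensor, height = 8L, block_step = 4L) {
  d <- dim(tensor)
  if (d[1] < height) {
    pad <- array(0, dim = c(height - d[1], d[2], d[3]))
    full <- array(0, dim = c(height, d[2], d[3]))
    full[seq_len(d[1]), , ] <- tensor
    return(list(full))
  }
  starts <- seq.int(1L, d[1] - height + 1L, by = block_step)
  if (utils::tail(starts, 1) + height - 1L < d[1]) {
    starts <- c(starts, d[1] - height + 1L)  # cover the segment tail
  }
  lapply(starts, function(s) tensor[s:(s + height - 1L), , , drop = FALSE])
}
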