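#' Mean short-term energy of a single-channel signal
#'
#' Slides an `n`-sample window along the signal and returns, per window, the
#' mean of squared samples: `Ek = (1/n) * sum(x[i]^2)` over the `n` samples
#' starting at the window's first sample. This is the detection statistic of
#' the energy-threshold segmenter. The default hop equals `n`
#' (non-overlapping blocks); a trailing partial window is dropped.
#'
#' @param signal numeric vector (single channel).
#' @param n window size in samples (default 100).
#' @param hop hop between window starts in samples (default `n`).
#' @return object of class `energy_series`: `values` (Ek, one per window),
#'   `n`, `hop` and `start_sample` (0-based start of each window).
#' @export
short_term_energy <- function(signal, n = 100L, hop = n) {
  n <- as.integer(n); hop <- as.integer(hop)
  if (n < 1L || hop < 1L) stop("n and hop must be positive")
  if (length(signal) < n) stop("signal shorter than one energy window (n = ", n, ")")
  starts <- seq.int(1L, length(signal) - n + 1L, by = hop)
  csq <- cumsum(c(0, signal^2))
  values <- (csq[starts + n] - csq[starts]) / n
  structure(list(values = values, n = n, hop = hop,
                 start_sample = starts - 1L),
            class = "energy_series")
}

#' Combine channels into a single detection signal
#'
#' The segmenter operates on one signal; multichannel recordings are reduced
#' to the per-sample root-sum-of-squares across channels, a symmetric rule
#' that responds to activity on any channel without per-channel conflict
#' resolution.
#'
#' @param rec an [emg_recording()] (or a numeric matrix, columns = channels).
#' @return numeric vector of combined samples.
#' @export
combine_channels <- function(rec) {
  x <- if (inherits(rec, "emg_recording")) rec$samples else as.matrix(rec)
  if (ncol(x) < 1L) stop("need at least one channel")
  sqrt(rowSums(x^2))
}

#' Calibrate static onset/offset thresholds
#'
#' From manually (or ground-truth) segmented calibration intervals, computes
#' the mean ratio of the onset-window energy to the interval's maximum
#' energy, and likewise for the offset window; each mean ratio is then
#' multiplied by the maximum mean short-term energy `Ek_max` observed on the
#' held-out (rest) data, giving the static threshold of the starting point
#' (STS) and of the ending point (STE). Ratios are scale-free, so the
#' thresholds inherit the amplitude scale of the rest data.
#'
#' @param calibration list of calibration intervals; each element a list with
#'   `energy` (an `energy_series` or numeric Ek vector over the interval),
#'   `start_idx` and `end_idx` (1-based window indices of the manually marked
#'   onset and offset within that energy vector).
#' @param holdout_ek_max maximum mean short-term energy over the rest data.
#' @return object of class `threshold_calibration` with `STS`, `STE`,
#'   `ratio_start`, `ratio_end`, `ek_max`.
#' @export
calibrate_thresholds <- function(calibration, holdout_ek_max) {
  if (length(calibration) < 1L) stop("calibration set is empty")
  ratios <- vapply(calibration, function(iv) {
    e <- if (inherits(iv$energy, "energy_series")) iv$energy$values else
      as.numeric(iv$energy)
    emax <- max(e)
    if (!is.finite(emax) || emax <= 0) stop("calibration interval has non-positive max energy")
    c(e[iv$start_idx] / emax, e[iv$end_idx] / emax)
  }, numeric(2))
  rs <- mean(ratios[1, ]); re <- mean(ratios[2, ])
  structure(list(STS = rs * holdout_ek_max, STE = re * holdout_ek_max,
                 ratio_start = rs, ratio_end = re,
                 ek_max = holdout_ek_max),
            class = "threshold_calibration")
}

#' Look-back/look-ahead window counts for segment detection
#'
#' The look-back count is tied to the energy window size and sampling rate
#' as `l = fs / (2n)`, and the look-ahead count `m` must satisfy
#' `fs/(2n) < m < fs/n`. At the default fs = 1500 Hz and n = 100 the raw
#' `l` is 7.5; it is integerised by round-half-to-even (giving 8), and `m`
#' defaults to the rounded midpoint of its open interval (11), both
#' overridable.
#'
#' @param fs_hz sampling rate.
#' @param n energy window size in samples.
#' @param l,m optional explicit overrides.
#' @return object of class `segmentation_params` with `l`, `m`, `n`, `fs_hz`.
#' @export
segmentation_params <- function(fs_hz, n = 100L, l = NULL, m = NULL) {
  if (fs_hz <= 0 || n <= 0) stop("fs_hz and n must be positive")
  lo <- fs_hz / (2 * n); hi <- fs_hz / n
  if (hi - lo < 2) stop("degenerate look-ahead interval: fs/n - fs/(2n) < 2")
  if (is.null(l)) l <- as.integer(round(lo))
  if (is.null(m)) {
    m <- as.integer(round((lo + hi) / 2))
    m <- max(min(m, as.integer(ceiling(hi)) - 1L), as.integer(floor(lo)) + 1L)
  }
  structure(list(l = as.integer(l), m = as.integer(m), n = as.integer(n),
                 fs_hz = fs_hz),
            class = "segmentation_params")
}

#' Detect active segments in an energy series
#'
#' Onset rule: window `k` starts a segment when `Ek > STS`, the mean of the
#' preceding `l` energies is below `Ek`, and the look-ahead condition over
#' the next `m` windows holds against STS (by default the mean of the next
#' `m` energies exceeds STS; `lookahead = "per_window"` requires every one of
#' them to exceed it). Offset rule: the first subsequent window with
#' `Ek < STE` whose following `l` energies average below `Ek`. Segments are
#' mapped back to sample indices (0-based, half-open), are non-overlapping
#' and sorted; detections shorter than `min_duration_s` are discarded, since
#' sub-300 ms events cannot fill one feature window. Quiet input yields an
#' empty list.
#'
#' @param energy an `energy_series` from [short_term_energy()].
#' @param calib a `threshold_calibration`.
#' @param params a `segmentation_params`.
#' @param min_duration_s minimum segment duration in seconds (default 0.3).
#' @param lookahead `"mean"` (default) or `"per_window"` onset look-ahead.
#' @param signal optional combined single-channel signal the energy series
#'   was computed from; when supplied, each window-level boundary is mapped
#'   to samples by locating the threshold crossing with a short (`n/4`)
#'   energy window around it, instead of snapping to the window grid.
#' @return data frame with columns `start_sample`, `end_sample` (0-based,
#'   half-open).
#' @export
detect_segments <- function(energy, calib, params, min_duration_s = 0.3,
                            lookahead = c("mean", "per_window"),
                            signal = NULL) {
  stopifnot(inherits(energy, "energy_series"),
            inherits(calib, "threshold_calibration"),
            inherits(params, "segmentation_params"))
  lookahead <- match.arg(lookahead)
  e <- energy$values
  K <- length(e)
  l <- params$l; m <- params$m
  sts <- calib$STS; ste <- calib$STE

  seg_start <- integer(0); seg_end <- integer(0)
  k <- 1L
  while (k <= K) {
    onset_ok <- FALSE
    if (e[k] > sts) {
      prev <- e[max(1L, k - l):(k - 1L)]
      prev_ok <- if (k == 1L) TRUE else mean(prev) < e[k]
      nxt <- e[min(k + 1L, K):min(k + m, K)]
      ahead_ok <- if (k == K) TRUE else {
        if (lookahead == "mean") mean(nxt) > sts else all(nxt > sts)
      }
      onset_ok <- prev_ok && ahead_ok
    }
    if (!onset_ok) { k <- k + 1L; next }
    k_on <- k
    k_off <- K  # default: active until end of recording
    j <- k_on + 1L
    while (j <= K) {
      if (e[j] < ste) {
        follow <- e[min(j + 1L, K):min(j + l, K)]
        follow_ok <- if (j == K) TRUE else mean(follow) < e[j]
        if (follow_ok) { k_off <- j; break }
      }
      j <- j + 1L
    }
    start_smp <- energy$start_sample[k_on]
    # offset window is the first BELOW STE: the segment ends where it
    # starts (end of the last active window at the default hop = n); if no
    # drop was found the activity runs to the end of the series.
    end_smp <- if (k_off == K && e[K] >= ste) {
      energy$start_sample[K] + energy$n
    } else {
      max(energy$start_sample[k_off],
          energy$start_sample[k_on] + energy$n)
    }
    if (!is.null(signal)) {
      start_smp <- refine_boundary(signal, start_smp, sts, energy$n,
                                   rising = TRUE)
      end_smp <- refine_boundary(signal, end_smp, ste, energy$n,
                                 rising = FALSE)
      if (end_smp <= start_smp) end_smp <- start_smp + energy$n
    }
    seg_start <- c(seg_start, start_smp)
    seg_end <- c(seg_end, min(end_smp, if (!is.null(signal)) length(signal)
                              else energy$start_sample[K] + energy$n))
    k <- k_off + 1L
  }
  keep <- (seg_end - seg_start) / params$fs_hz >= min_duration_s
  data.frame(start_sample = seg_start[keep], end_sample = seg_end[keep])
}

# Map a window-level boundary to sample resolution: scan a short (n/4)
# energy window across +/- n samples around the coarse boundary and place
# the boundary at the threshold crossing (first crossing for onsets, last
# for offsets). Falls back to the coarse boundary if no crossing is found.
refine_boundary <- function(signal, coarse, threshold, n, rising) {
  w <- max(10L, n %/% 4L)
  lo <- max(0L, coarse - n)
  hi <- min(length(signal) - w, coarse + n)
  if (hi <= lo) return(coarse)
  pos <- lo:hi                       # 0-based window starts
  csq <- cumsum(c(0, signal^2))
  e_short <- (csq[pos + w + 1L] - csq[pos + 1L]) / w
  if (rising) {
    i <- which(e_short > threshold)[1]
    if (is.na(i)) coarse else pos[i]
  } else {
    i <- which(e_short > threshold)
    if (length(i) == 0) coarse else min(pos[i[length(i)]] + w,
                                        length(signal))
  }
}

#' Segment a multichannel recording
#'
#' Convenience wrapper: combines channels (root-sum-of-squares), computes
#' the mean short-term energy series and runs [detect_segments()].
#'
#' @inheritParams detect_segments
#' @param rec an [emg_recording()].
#' @param hop energy-window hop (default the window size `params$n`).
#' @return data frame of segments as in [detect_segments()].
#' @export
segment_recording <- function(rec, calib, params, hop = params$n,
                              min_duration_s = 0.3,
                              lookahead = c("mean", "per_window")) {
  combined <- combine_channels(rec)
  energy <- short_term_energy(combined, n = params$n, hop = hop)
  detect_segments(energy, calib, params, min_duration_s = min_duration_s,
                  lookahead = match.arg(lookahead), signal = combined)
}

#' Calibrate thresholds from annotated recordings
#'
#' Mirrors the partial/rest calibration protocol: a fraction of the supplied
#' recordings (with their ground-truth burst annotations standing in for
#' manual segmentation) provides the onset/offset energy ratios; the
#' remaining recordings supply the maximum mean short-term energy `Ek_max`.
#' Intended to be run on training-fold recordings only.
#'
#' @param recordings list of [emg_recording()] with non-empty `bursts`.
#' @param params a `segmentation_params`.
#' @param calibration_frac fraction of recordings used for ratio calibration
#'   (default 0.2, at least one).
#' @param hop energy hop (default `params$n`).
#' @return a `threshold_calibration`.
#' @export
calibrate_from_recordings <- function(recordings, params,
                                      calibration_frac = 0.2,
                                      hop = params$n) {
  annotated <- Filter(function(r) !is.null(r$bursts) && nrow(r$bursts) > 0,
                      recordings)
  if (length(annotated) < 2L) stop("need >= 2 annotated recordings to calibrate")
  n_cal <- max(1L, floor(calibration_frac * length(annotated)))
  # evenly spaced picks so calibration covers the gesture mix, not just the
  # first recordings in list order
  cal_idx <- unique(round(seq(1, length(annotated), length.out = n_cal)))
  cal_recs <- annotated[cal_idx]
  rest_recs <- annotated[-cal_idx]
  if (length(rest_recs) == 0L) rest_recs <- cal_recs

  calibration <- lapply(cal_recs, function(r) {
    es <- short_term_energy(combine_channels(r), n = params$n, hop = hop)
    w_start <- findInterval(r$bursts$start_sample[1], es$start_sample)
    w_end <- findInterval(r$bursts$end_sample[1] - 1L, es$start_sample)
    w_start <- max(1L, w_start); w_end <- min(length(es$values), w_end)
    list(energy = es, start_idx = w_start, end_idx = w_end)
  })
  ek_max <- max(vapply(rest_recs, function(r) {
    max(short_term_energy(combine_channels(r), n = params$n, hop = hop)$values)
  }, numeric(1)))
  calibrate_thresholds(calibration, ek_max)
}
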