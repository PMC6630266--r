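#' Design the cascaded Butterworth band-pass filter
#'
#' sEMG carries its information in roughly 10-500 Hz, so denoising is a
#' band-pass built as a cascade of a third-order Butterworth high-pass at
#' 10 Hz and a third-order Butterworth low-pass at 500 Hz. A third-order
#' Butterworth rolls off at 18 dB per octave. Discretisation is by bilinear
#' transform with frequency pre-warping (as realised by [signal::butter()]),
#' which keeps the -3 dB points at the nominal cutoffs. No mains notch is
#' included: the emulated acquisition hardware shields power-line
#' interference, so a 50 Hz tone inside the passband is deliberately kept.
#'
#' @param fs_hz sampling rate in Hz; must exceed 1000 so the 500 Hz cutoff
#'   sits below Nyquist.
#' @param hp_cutoff_hz,lp_cutoff_hz high-pass and low-pass cutoffs (defaults
#'   10 and 500 Hz).
#' @param hp_order,lp_order stage orders (default 3 each).
#' @return an object of class `filter_spec`: realized coefficients for each
#'   stage (`hp`, `lp` as `b`/`a` polynomial vectors), cutoffs, orders and
#'   design rate.
#' @export
design_bandpass <- function(fs_hz, hp_cutoff_hz = 10, lp_cutoff_hz = 500,
                            hp_order = 3L, lp_order = 3L) {
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 1000) {
    stop("fs_hz must be > 1000 Hz")
  }
  if (!(0 < hp_cutoff_hz && hp_cutoff_hz < lp_cutoff_hz &&
        lp_cutoff_hz < fs_hz / 2)) {
    stop("need 0 < hp_cutoff < lp_cutoff < fs/2: cannot place ",
         lp_cutoff_hz, " Hz below Nyquist at fs = ", fs_hz, " Hz")
  }
  hp <- signal::butter(hp_order, hp_cutoff_hz / (fs_hz / 2), type = "high")
  lp <- signal::butter(lp_order, lp_cutoff_hz / (fs_hz / 2), type = "low")
  for (st in list(hp, lp)) {
    poles <- polyroot(rev(st$a))
    if (any(Mod(poles) >= 1)) stop("realized filter stage is unstable")
  }
  structure(list(hp = list(b = hp$b, a = hp$a),
                 lp = list(b = lp$b, a = lp$a),
                 hp_cutoff_hz = hp_cutoff_hz, lp_cutoff_hz = lp_cutoff_hz,
                 hp_order = hp_order, lp_order = lp_order, fs_hz = fs_hz),
            class = "filter_spec")
}

#' Apply the band-pass cascade to a recording
#'
#' Filters each channel independently through the high-pass then the
#' low-pass stage. The default is a causal single pass, preserving the
#' real-time framing of online fall detection; `zero_phase = TRUE` applies
#' each stage forward-backward ([signal::filtfilt()]), which removes phase
#' distortion but doubles the effective order and attenuation.
#'
#' @param rec an [emg_recording()] whose `fs_hz` matches the design rate.
#' @param spec a `filter_spec` from [design_bandpass()].
#' @param zero_phase logical; forward-backward filtering if `TRUE`.
#' @return the recording with filtered samples (metadata unchanged).
#' @export
apply_filter <- function(rec, spec, zero_phase = FALSE) {
  stopifnot(inherits(rec, "emg_recording"), inherits(spec, "filter_spec"))
  if (!isTRUE(all.equal(rec$fs_hz, spec$fs_hz))) {
    stop("recording sampling rate (", rec$fs_hz,
         ") does not match the filter design rate (", spec$fs_hz, ")")
  }
  if (any(!is.finite(rec$samples))) stop("input contains NaN/Inf samples")
  hp <- signal::Arma(b = spec$hp$b, a = spec$hp$a)
  lp <- signal::Arma(b = spec$lp$b, a = spec$lp$a)
  run <- if (zero_phase) {
    function(x) signal::filtfilt(lp, signal::filtfilt(hp, x))
  } else {
    function(x) as.numeric(signal::filter(lp, signal::filter(hp, x)))
  }
  out <- rec
  out$samples <- apply(rec$samples, 2, run)
  colnames(out$samples) <- rec$channel_names
  if (!all(is.finite(out$samples))) stop("filtering produced non-finite output")
  out
}

#' Magnitude response of the band-pass cascade
#'
#' Evaluates the realized cascade (or a single stage) at the requested
#' frequencies and returns magnitudes in dB. Zero magnitude (e.g. DC through
#' the high-pass stage) is reported as `-Inf`.
#'
#' @param spec a `filter_spec`.
#' @param freqs_hz frequencies in `[0, fs/2)`.
#' @param stage `"cascade"` (default), `"hp"` or `"lp"`.
#' @return numeric vector of magnitudes in dB.
#' @export
frequency_response <- function(spec, freqs_hz, stage = c("cascade", "hp", "lp")) {
  stopifnot(inherits(spec, "filter_spec"))
  stage <- match.arg(stage)
  if (any(freqs_hz < 0) || any(freqs_hz >= spec$fs_hz / 2)) {
    stop("frequencies must lie in [0, fs/2)")
  }
  z <- exp(-1i * 2 * pi * freqs_hz / spec$fs_hz)
  evalp <- function(coef, z) {
    acc <- rep(0 + 0i, length(z))
    for (c_k in coef) acc <- acc * z + c_k  # Horner in z^-1, coef order b0..bn
    acc
  }
  # polynomials are in z^-1 with coefficients b[1] + b[2] z^-1 + ...;
  # Horner above needs reversed order
  h_of <- function(st) {
    num <- evalp(rev(st$b), z)
    den <- evalp(rev(st$a), z)
    num / den
  }
  h <- switch(stage,
              cascade = h_of(spec$hp) * h_of(spec$lp),
              hp = h_of(spec$hp),
              lp = h_of(spec$lp))
  mag <- Mod(h)
  # an analytically zero response (e.g. DC through the high-pass) leaves a
  # ~1e-13 floating-point residue; snap it to the zero-magnitude sentinel
  mag[mag < 1e-9] <- 0
  db <- ifelse(mag == 0, -Inf, 20 * log10(mag))
  as.numeric(db)
}
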