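#' Construct an sEMG recording object
#'
#' Container for a multichannel surface-EMG recording: a samples matrix
#' (rows = time, columns = channels, arbitrary amplitude units), the sampling
#' rate, the subject identity and the gesture label. Optionally carries
#' ground-truth burst annotations (used by the synthetic generator and by
#' segmentation tests).
#'
#' @param samples numeric matrix, `n_samples x n_channels`; all values finite.
#' @param fs_hz sampling rate in Hz; must exceed 1000 so the 10-500 Hz
#'   analysis band fits below Nyquist.
#' @param subject_id integer subject identifier.
#' @param gesture one of `"walking"`, `"squatting"`, `"sitting"`, `"falling"`,
#'   or `NA` for unlabelled data.
#' @param channel_names character vector of muscle names, one per column.
#' @param bursts optional data frame with columns `start_sample`, `end_sample`
#'   (0-based, half-open) giving ground-truth activity intervals.
#' @return an object of class `emg_recording`.
#' @export
emg_recording <- function(samples, fs_hz = 1500, subject_id = NA_integer_,
                          gesture = NA_character_,
                          channel_names = default_channel_names(ncol(samples)),
                          bursts = NULL) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 1L) stop("recording must contain at least one sample")
  if (!all(is.finite(samples))) stop("recording contains non-finite samples")
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 1000) {
    stop("fs_hz must be a single value > 1000 Hz (10-500 Hz band below Nyquist)")
  }
  if (length(channel_names) != ncol(samples)) {
    stop("channel_names length must equal the number of channels")
  }
  if (!is.null(bursts)) {
    bursts <- as.data.frame(bursts)
    stopifnot(all(c("start_sample", "end_sample") %in% names(bursts)))
    if (nrow(bursts) > 0 &&
        (any(bursts$start_sample < 0) ||
         any(bursts$end_sample > nrow(samples)) ||
         any(bursts$start_sample >= bursts$end_sample))) {
      stop("burst intervals must satisfy 0 <= start < end <= n_samples")
    }
  }
  colnames(samples) <- channel_names
  structure(list(samples = samples, fs_hz = fs_hz,
                 subject_id = as.integer(subject_id),
                 gesture = gesture, channel_names = channel_names,
                 bursts = bursts),
            class = "emg_recording")
}

#' Gesture classes of the activity-recognition task
#'
#' The four classes recognised by the pipeline. `falling` is the designated
#' positive class for sensitivity/specificity.
#' @return character vector of the four gesture labels.
#' @export
gesture_classes <- function() c("walking", "squatting", "sitting", "falling")

#' Default muscle names for the four-channel montage
#'
#' Electrodes over the four leg muscles that drive flexion/extension:
#' rectus femoris, vastus medialis, tibialis anterior, gastrocnemius.
#' @param n number of channels requested.
#' @return character vector of length `n`.
#' @export
default_channel_names <- function(n = 4L) {
  full <- c("rectus_femoris", "vastus_medialis",
            "tibialis_anterior", "gastrocnemius")
  if (n <= 4L) full[seq_len(n)] else paste0("ch", seq_len(n))
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d samples x %d channels @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs_hz,
              nrow(x$samples) / x$fs_hz))
  cat(sprintf("  subject: %s  gesture: %s\n",
              ifelse(is.na(x$subject_id), "?", x$subject_id),
              ifelse(is.na(x$gesture), "?", x$gesture)))
  if (!is.null(x$bursts) && nrow(x$bursts) > 0) {
    cat(sprintf("  %d annotated burst(s)\n", nrow(x$bursts)))
  }
  invisible(x)
}
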