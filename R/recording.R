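#' Standard eight-channel montage
#'
#' Channel labels of the fixed montage used throughout the package, in
#' montage order: two electrodes per scalp region (frontal, central,
#' parietal, occipital) of the international 10-20 system.
#'
#' @format Character vector of length 8.
#' @export
MONTAGE <- c("F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2")

#' Scalp region to channel mapping
#'
#' @format Named list mapping region codes `F`, `C`, `P`, `O` to their
#'   channel pairs.
#' @export
REGIONS <- list(
  F = c("F3", "F4"),
  C = c("C3", "C4"),
  P = c("P3", "P4"),
  O = c("O1", "O2")
)

#' EEG frequency bands (Hz)
#'
#' Canonical band edges used by the synthetic generator and band-power
#' helpers. Gamma is capped at 45 Hz so the full band survives the 95 Hz
#' low-pass and sampling rates down to 200 Hz.
#'
#' @format Named list of `c(low, high)` pairs in Hz.
#' @export
EEG_BANDS <- list(
  delta = c(1, 4),
  theta = c(4, 8),
  alpha = c(8, 13),
  beta  = c(13, 30),
  gamma = c(30, 45)
)

#' Construct a multichannel EEG recording
#'
#' A recording is one subject x task signal block: a channels x time matrix
#' in microvolts with channel labels from the fixed montage, a sampling
#' rate, and provenance metadata.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param channels Character vector of channel labels, one per row of
#'   `data`, in montage order.
#' @param fs_hz Sampling rate in Hz.
#' @param subject_id Integer subject label (0-based).
#' @param task_id One of `"rest"`, `"level1"`, `"level2"`, `"level3"`.
#' @param meta Free-form provenance list.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(data, channels, fs_hz, subject_id, task_id,
                      meta = list()) {
  data <- as.matrix(data)
  if (nrow(data) != length(channels))
    stopf("data has %d rows but %d channel labels given",
          nrow(data), length(channels))
  if (any(!is.finite(data)))
    stopf("recording contains non-finite samples")
  if (fs_hz <= 0) stopf("fs_hz must be positive")
  unknown <- setdiff(channels, MONTAGE)
  if (length(unknown))
    warnf("channel labels outside the montage: %s",
          paste(unknown, collapse = ", "))
  structure(
    list(
      data = data, channels = as.character(channels), fs_hz = fs_hz,
      subject_id = as.integer(subject_id), task_id = as.character(task_id),
      meta = meta
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> subject %d, task %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, x$task_id, nrow(x$data), ncol(x$data), x$fs_hz,
    ncol(x$data) / x$fs_hz
  ))
  cat("  channels:", paste(x$channels, collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

n_samples <- function(rec) ncol(rec$data)

task_levels <- c("rest", "level1", "level2", "level3")

check_task_id <- function(task_id) {
  if (!task_id %in% task_levels)
    stopf("unknown task_id '%s' (expected one of %s)", task_id,
          paste(task_levels, collapse = ", "))
  task_id
}

# Region code of a montage channel label ("F3" -> "F").
channel_region <- function(labels) substr(labels, 1, 1)
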