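#' @name preprocess
#' @title Signal conditioning pipeline
#' @description
#' Fixed conditioning order for every analysis in the package:
#' notch -> band-pass -> task selection -> segmentation -> region
#' selection -> common average reference -> z-score normalization.
#' Filters are applied zero-phase (forward-backward); CAR is computed
#' over whichever channels survive region selection; normalization
#' statistics come from training data only.
NULL

#' Apply the powerline notch filter
#'
#' Zero-phase second-order IIR notch at `spec$notch_hz`.
#'
#' @param rec An [recording()].
#' @param spec A [filter_spec()].
#' @return A filtered recording of identical shape.
#' @export
notch_filter <- function(rec, spec = filter_spec()) {
  check_spec_fs(spec, rec$fs_hz, need_bp = FALSE)
  d <- notch_design(spec$notch_hz, rec$fs_hz, spec$notch_q)
  out <- rec
  out$data <- filter_rows(rec$data, function(x) filtfilt(d$b, d$a, x))
  out
}

#' Apply the Butterworth band-pass cascade
#'
#' Zero-phase cascade of a Butterworth high-pass at `bp_low_hz` (removes
#' DC and drift) and a Butterworth low-pass at `bp_high_hz`.
#'
#' @inheritParams notch_filter
#' @return A filtered recording of identical shape.
#' @export
bandpass_filter <- function(rec, spec = filter_spec()) {
  check_spec_fs(spec, rec$fs_hz, need_notch = FALSE)
  hp <- butter_design(spec$order, spec$bp_low_hz, rec$fs_hz, "high")
  lp <- butter_design(spec$order, spec$bp_high_hz, rec$fs_hz, "low")
  out <- rec
  out$data <- filter_rows(rec$data, function(x)
    filtfilt(lp$b, lp$a, filtfilt(hp$b, hp$a, x)))
  out
}

resolve_regions <- function(regions) {
  regions <- unique(as.character(regions))
  if (length(regions) == 0) stopf("invalid-selection: no regions requested")
  bad <- setdiff(regions, names(REGIONS))
  if (length(bad))
    stopf("invalid-selection: unknown region code(s) %s",
          paste(bad, collapse = ", "))
  # fixed montage order regardless of request order
  MONTAGE[channel_region(MONTAGE) %in% regions]
}

#' Restrict to scalp regions
#'
#' Keeps the channel pairs of the requested regions, in montage order.
#' Works on a recording or on a segment set.
#'
#' @param x An [recording()] or segment set.
#' @param regions Character vector from `F`, `C`, `P`, `O`.
#' @return Object of the same class with reduced channels.
#' @export
select_regions <- function(x, regions) UseMethod("select_regions")

#' @export
select_regions.eeg_recording <- function(x, regions) {
  keep <- resolve_regions(regions)
  idx <- match(keep, x$channels)
  if (anyNA(idx))
    stopf("invalid-selection: channels %s absent from recording",
          paste(keep[is.na(idx)], collapse = ", "))
  x$data <- x$data[idx, , drop = FALSE]
  x$channels <- keep
  x
}

#' @export
select_regions.segment_set <- function(x, regions) {
  keep <- resolve_regions(regions)
  idx <- match(keep, x$channels)
  if (anyNA(idx))
    stopf("invalid-selection: channels %s absent from segment set",
          paste(keep[is.na(idx)], collapse = ", "))
  x$data <- x$data[idx, , , drop = FALSE]
  x$channels <- keep
  x
}

#' Common average reference
#'
#' Subtracts, at every time sample, the instantaneous mean over all
#' available channels from each channel, removing signal components
#' common to the montage. Requires at least two channels; afterwards the
#' per-sample sum over channels is zero up to rounding.
#'
#' @param x An [recording()] or segment set.
#' @return Re-referenced object of the same class.
#' @export
apply_car <- function(x) UseMethod("apply_car")

car_matrix <- function(m) {
  if (nrow(m) < 2) stopf("invalid-CAR: need >= 2 channels, got %d", nrow(m))
  sweep(m, 2, colMeans(m), "-")
}

#' @export
apply_car.eeg_recording <- function(x) {
  x$data <- car_matrix(x$data)
  x
}

#' @export
apply_car.segment_set <- function(x) {
  if (dim(x$data)[1] < 2)
    stopf("invalid-CAR: need >= 2 channels, got %d", dim(x$data)[1])
  mu <- colMeans(x$data)               # window x n means over channels
  x$data <- x$data - aperm(
    array(mu, c(dim(x$data)[2], dim(x$data)[3], dim(x$data)[1])),
    c(3, 1, 2)
  )
  x
}

#' Construct a segment set
#'
#' The unit container of the classification stages: a stack of
#' fixed-length multichannel epochs with subject labels and lossless
#' provenance back to `(recording, task, start sample)`.
#'
#' @param data Numeric array, channels x window x n_segments.
#' @param channels Channel labels.
#' @param fs_hz Sampling rate in Hz.
#' @param subject Integer vector of 0-based subject labels, length n.
#' @param task Character vector of task ids, length n.
#' @param start Integer vector of 0-based window start samples, length n.
#' @param recording_id Character vector identifying the source recording.
#' @param window,step Segmentation parameters in samples.
#' @param normalized Logical flag set by [apply_normalization()].
#' @return An object of class `segment_set`.
#' @export
segment_set <- function(data, channels, fs_hz, subject, task, start,
                        recording_id, window, step, normalized = FALSE) {
  stopifnot(length(dim(data)) == 3)
  n <- dim(data)[3]
  if (dim(data)[1] != length(channels))
    stopf("channel count mismatch")
  if (length(subject) != n || length(task) != n || length(start) != n ||
      length(recording_id) != n)
    stopf("provenance length mismatch")
  structure(
    list(data = data, channels = as.character(channels), fs_hz = fs_hz,
         subject = as.integer(subject), task = as.character(task),
         start = as.integer(start), recording_id = as.character(recording_id),
         window = as.integer(window), step = as.integer(step),
         normalized = normalized),
    class = "segment_set"
  )
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf(
    "<segment_set> %d segments x %d channels x %d samples, %d subjects, tasks: %s%s\n",
    n_segments(x), length(x$channels), x$window,
    length(unique(x$subject)), paste(unique(x$task), collapse = "/"),
    if (x$normalized) " (normalized)" else ""
  ))
  invisible(x)
}

#' Number of segments in a segment set
#' @param s A segment set.
#' @return Integer count.
#' @export
n_segments <- function(s) dim(s$data)[3]

#' Subset a segment set by segment index
#' @param s A segment set.
#' @param idx Integer or logical index over segments.
#' @return A segment set with the selected segments.
#' @export
subset_segments <- function(s, idx) {
  s$data <- s$data[, , idx, drop = FALSE]
  s$subject <- s$subject[idx]
  s$task <- s$task[idx]
  s$start <- s$start[idx]
  s$recording_id <- s$recording_id[idx]
  s
}

#' Concatenate segment sets
#' @param sets List of segment sets with identical channels, window and
#'   sampling rate.
#' @return A single combined segment set.
#' @export
concat_segments <- function(sets) {
  sets <- sets[vapply(sets, n_segments, 1L) > 0]
  if (!length(sets)) stopf("nothing to concatenate")
  ref <- sets[[1]]
  for (s in sets[-1]) {
    if (!identical(s$channels, ref$channels) || s$window != ref$window ||
        s$fs_hz != ref$fs_hz)
      stopf("segment sets are not compatible")
  }
  segment_set(
    array(unlist(lapply(sets, `[[`, "data")),
          c(length(ref$channels), ref$window,
            sum(vapply(sets, n_segments, 1L)))),
    ref$channels, ref$fs_hz,
    unlist(lapply(sets, `[[`, "subject")),
    unlist(lapply(sets, `[[`, "task")),
    unlist(lapply(sets, `[[`, "start")),
    unlist(lapply(sets, `[[`, "recording_id")),
    ref$window, ref$step,
    normalized = ref$normalized
  )
}

#' Sliding-window segmentation
#'
#' Cuts a recording into half-open windows `[k*step, k*step + window)` in
#' 0-based sample coordinates. A recording shorter than one window yields
#' an empty set with a warning. Default window/step give 1 s epochs with
#' half overlap at 1 kHz.
#'
#' @param rec An [recording()].
#' @param window Window length in samples.
#' @param step Hop in samples (`0 < step <= window`).
#' @return A [segment_set()] with `floor((T - window)/step) + 1` segments.
#' @export
segment_recording <- function(rec, window = 1000, step = 500) {
  if (window <= 0 || step <= 0)
    stopf("invalid-segmentation: window and step must be positive")
  if (step > window)
    stopf("invalid-segmentation: step must not exceed window")
  T <- n_samples(rec)
  rid <- sprintf("s%d_%s", rec$subject_id, rec$task_id)
  if (T < window) {
    warnf("recording %s too short for one window (%d < %d samples)",
          rid, T, window)
    return(segment_set(
      array(0, c(nrow(rec$data), window, 0)), rec$channels, rec$fs_hz,
      integer(0), character(0), integer(0), character(0), window, step
    ))
  }
  n <- (T - window) %/% step + 1L
  starts <- (seq_len(n) - 1L) * step
  data <- array(0, c(nrow(rec$data), window, n))
  for (i in seq_len(n))
    data[, , i] <- rec$data[, (starts[i] + 1L):(starts[i] + window)]
  segment_set(data, rec$channels, rec$fs_hz,
              rep(rec$subject_id, n), rep(rec$task_id, n), starts,
              rep(rid, n), window, step)
}

#' Fit z-score normalization statistics
#'
#' Per-channel mean and standard deviation pooled over all samples of all
#' training segments. Standard deviations are floored at `1e-8` so a
#' constant channel maps to zeros rather than NaN.
#'
#' @param train A non-empty segment set (training data only, to keep the
#'   transform leakage-free).
#' @return An object of class `normalization_stats` with `mu` and `sigma`
#'   per channel.
#' @export
fit_normalization <- function(train) {
  if (n_segments(train) == 0) stopf("invalid-fit: empty segment set")
  C <- dim(train$data)[1]
  flat <- matrix(aperm(train$data, c(2, 3, 1)), ncol = C)  # samples x C
  mu <- colMeans(flat)
  sigma <- pmax(apply(flat, 2, sd), 1e-8)
  structure(list(mu = mu, sigma = sigma, channels = train$channels),
            class = "normalization_stats")
}

#' Apply z-score normalization
#'
#' Transforms every value `x` to `(x - mu)/sigma` with the per-channel
#' statistics of `stats` (typically fitted on training data).
#'
#' @param s A segment set.
#' @param stats A `normalization_stats` from [fit_normalization()].
#' @return The normalized segment set.
#' @export
apply_normalization <- function(s, stats) {
  C <- dim(s$data)[1]
  if (C != length(stats$mu))
    stopf("shape error: segment set has %d channels, stats %d",
          C, length(stats$mu))
  if (!identical(s$channels, stats$channels))
    stopf("shape error: channel labels differ between stats and data")
  s$data <- (s$data - stats$mu) / stats$sigma  # recycles over channel dim
  s$normalized <- TRUE
  s
}

#' Filter and segment a set of recordings
#'
#' Applies the fixed front half of the pipeline (notch -> band-pass ->
#' segmentation) to each recording and concatenates the epochs. Region
#' selection, CAR, and normalization are applied downstream where the
#' study case and the data split are known.
#'
#' @param recs List of [recording()]s.
#' @param spec A [filter_spec()].
#' @param window,step Segmentation parameters in samples.
#' @return A combined [segment_set()].
#' @export
preprocess_recordings <- function(recs, spec = filter_spec(),
                                  window = 1000, step = 500) {
  sets <- lapply(recs, function(r)
    segment_recording(bandpass_filter(notch_filter(r, spec), spec),
                      window, step))
  concat_segments(sets)
}
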