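#' @name io
#' @title Signal file I/O and cohort manifests
#' @description
#' Recordings are exchanged as EDF (European Data Format: 16-bit samples,
#' one data record per second, physical range fixed at +/-500 microvolts)
#' or as a per-channel CSV dialect (header row of channel labels, one
#' sample per row, '.' decimal separator). A JSON manifest ties a cohort
#' of files together.
NULL

EDF_PHYS_MIN <- -500
EDF_PHYS_MAX <- 500
EDF_DIG_MIN <- -32768L
EDF_DIG_MAX <- 32767L

edf_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = -width)  # left-justified, space padded
}

edf_num <- function(x, width) edf_field(format(x, scientific = FALSE), width)

#' Write a recording to disk
#'
#' @param rec An [recording()].
#' @param path Output file path.
#' @param format `"edf"` or `"csv"`.
#' @return Invisibly, a one-row manifest entry data frame.
#' @export
write_recording <- function(rec, path, format = c("edf", "csv")) {
  format <- match.arg(format)
  if (format == "edf") write_edf(rec, path) else write_csv_rec(rec, path)
  invisible(manifest_entry(rec, path, format))
}

manifest_entry <- function(rec, path, format) {
  data.frame(
    subject_id = rec$subject_id, task_id = rec$task_id, path = path,
    duration_s = n_samples(rec) / rec$fs_hz, fs_hz = rec$fs_hz,
    channels = paste(rec$channels, collapse = ";"), format = format,
    stringsAsFactors = FALSE
  )
}

write_edf <- function(rec, path) {
  fs <- as.integer(round(rec$fs_hz))
  ns <- nrow(rec$data)
  n <- n_samples(rec)
  n_rec <- n %/% fs
  if (n_rec * fs != n) {
    warnf("truncating %d trailing samples to whole EDF records", n - n_rec * fs)
    n <- n_rec * fs
  }
  if (n_rec < 1) stopf("recording shorter than one EDF record")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field(sprintf("S%03d", rec$subject_id), 80),
    edf_field(rec$task_id, 80),
    edf_field("01.01.26", 8), edf_field("00.00.00", 8),
    edf_num(256L + ns * 256L, 8),
    edf_field("", 44),
    edf_num(n_rec, 8), edf_num(1L, 8), edf_num(ns, 4)
  )
  sig_hdr <- paste0(
    paste(vapply(rec$channels, edf_field, "", width = 16), collapse = ""),
    strrep(edf_field("", 80), ns),
    strrep(edf_field("uV", 8), ns),
    strrep(edf_num(EDF_PHYS_MIN, 8), ns),
    strrep(edf_num(EDF_PHYS_MAX, 8), ns),
    strrep(edf_num(EDF_DIG_MIN, 8), ns),
    strrep(edf_num(EDF_DIG_MAX, 8), ns),
    strrep(edf_field("", 80), ns),
    strrep(edf_num(fs, 8), ns),
    strrep(edf_field("", 32), ns)
  )
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)
  gain <- (EDF_DIG_MAX - EDF_DIG_MIN) / (EDF_PHYS_MAX - EDF_PHYS_MIN)
  dig <- round((rec$data[, seq_len(n), drop = FALSE] - EDF_PHYS_MIN) * gain) +
    EDF_DIG_MIN
  if (any(dig < EDF_DIG_MIN | dig > EDF_DIG_MAX))
    warnf("samples outside +/-%g uV clipped in EDF export", EDF_PHYS_MAX)
  dig <- pmin(pmax(dig, EDF_DIG_MIN), EDF_DIG_MAX)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    block <- t(dig[, cols, drop = FALSE])  # per signal sequentially
    writeBin(as.integer(block), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  info <- file.info(path)
  if (is.na(info$size) || info$size < 256)
    stopf("parse error: %s is not a valid EDF file (too short)", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                       # version
  patient <- rd(80)
  rec_field <- rd(80)
  rd(8); rd(8)                # date, time
  rd(8)                       # header bytes
  rd(44)                      # reserved
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1 || is.na(n_rec))
    stopf("parse error: malformed EDF header in %s", path)
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  rd(80 * ns)                 # transducer
  rd(8 * ns)                  # physical dimension
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(80 * ns)                 # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(32 * ns)                 # reserved
  if (anyNA(c(pmin_, pmax_, dmin_, dmax_, spr)))
    stopf("parse error: malformed EDF signal headers in %s", path)
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[s], size = 2, endian = "little",
                     signed = TRUE)
      if (length(raw) < spr[s])
        stopf("parse error: EDF record %d truncated in %s", r, path)
      phys <- (raw - dmin_[s]) / (dmax_[s] - dmin_[s]) *
        (pmax_[s] - pmin_[s]) + pmin_[s]
      data[s, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <- phys
    }
  }
  subject <- if (grepl("^S[0-9]+$", patient))
    as.integer(sub("^S", "", patient)) else -1L
  task <- if (rec_field %in% task_levels) rec_field else NA_character_
  list(data = data, labels = labels, fs = spr[1] / rec_dur,
       subject = subject, task = task)
}

write_csv_rec <- function(rec, path) {
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channels
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a recording from disk
#'
#' Channels are reordered to montage order; labels outside the montage
#' are kept at the end and flagged with a warning. For CSV (which stores
#' no rate or provenance) the sampling rate, subject and task must be
#' supplied or come from a manifest.
#'
#' @param path File path.
#' @param format `"edf"` or `"csv"`.
#' @param fs_hz Sampling rate for CSV input.
#' @param subject_id,task_id Override provenance (required for CSV,
#'   parsed from the header for EDF).
#' @return An [recording()].
#' @export
read_recording <- function(path, format = c("edf", "csv"), fs_hz = 1000,
                           subject_id = NULL, task_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "edf") {
    p <- read_edf(path)
    data <- p$data
    labels <- p$labels
    fs <- p$fs
    subject_id <- subject_id %||% p$subject
    task_id <- task_id %||% p$task
  } else {
    if (file.info(path)$size == 0) stopf("parse error: %s is empty", path)
    df <- tryCatch(read.csv(path, check.names = FALSE),
                   error = function(e) stopf("parse error in %s: %s",
                                             path, conditionMessage(e)))
    if (nrow(df) == 0 || ncol(df) == 0)
      stopf("parse error: %s has no samples", path)
    data <- t(as.matrix(df))
    labels <- names(df)
    fs <- fs_hz
    if (is.null(subject_id) || is.null(task_id))
      stopf("subject_id and task_id are required for CSV input")
  }
  if (is.na(task_id %||% NA))
    stopf("montage error: task id not recoverable from %s", path)
  known <- labels %in% MONTAGE
  ord <- c(match(intersect(MONTAGE, labels), labels), which(!known))
  recording(data[ord, , drop = FALSE], labels[ord], fs, subject_id, task_id,
            meta = list(path = path, format = format))
}

#' Write a cohort manifest
#'
#' @param entries Data frame of manifest entries (from
#'   [write_recording()], row-bound).
#' @param path Output JSON path.
#' @return Invisibly, the path.
#' @export
write_manifest <- function(entries, path) {
  key <- paste(entries$subject_id, entries$task_id)
  if (anyDuplicated(key))
    stopf("manifest error: duplicate (subject_id, task_id) pair(s): %s",
          paste(unique(key[duplicated(key)]), collapse = "; "))
  jsonlite::write_json(
    list(format_version = "1.0", entries = entries),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Read and validate a cohort manifest
#'
#' @param path Manifest JSON path.
#' @param check_files Verify that every referenced file exists.
#' @return Data frame of entries.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- m$entries
  key <- paste(entries$subject_id, entries$task_id)
  if (anyDuplicated(key))
    stopf("manifest error: duplicate (subject_id, task_id) pairs")
  if (check_files) {
    paths <- entries$path
    rel <- !file.exists(paths)
    # paths may be relative to the manifest location
    paths[rel] <- file.path(dirname(path), paths[rel])
    if (any(!file.exists(paths)))
      stopf("manifest error: missing file(s): %s",
            paste(entries$path[!file.exists(paths)], collapse = ", "))
    entries$path <- paths
  }
  entries
}

#' Load a cohort of recordings from a manifest
#'
#' @param path Manifest JSON path.
#' @return List of [recording()]s.
#' @export
read_cohort <- function(path) {
  entries <- read_manifest(path)
  lapply(seq_len(nrow(entries)), function(i) {
    e <- entries[i, ]
    read_recording(e$path, e$format, fs_hz = e$fs_hz,
                   subject_id = e$subject_id, task_id = e$task_id)
  })
}
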