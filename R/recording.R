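#' Construct an EEG recording object
#'
#' An `eeg_recording` bundles a channel-by-sample matrix (microvolts) with
#' its ordered electrode labels, sampling rate and clock origin. All
#' downstream stages (windowing, balancing, streaming) consume this object.
#'
#' @param data numeric matrix, channels in rows, samples in columns (uV).
#' @param channel_labels character vector of unique 10-20 electrode names,
#'   one per row of `data`.
#' @param fs sampling rate in Hz (positive scalar).
#' @param patient_id opaque patient identifier.
#' @param start_time_s recording clock origin in seconds (default 0).
#' @return An object of class `eeg_recording`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(512), 2, 256), c("FP1", "FP2"), fs = 256)
#' n_samples(rec)
eeg_recording <- function(data, channel_labels, fs, patient_id = "p1",
                          start_time_s = 0) {
  if (!is.matrix(data)) data <- rbind(data)
  storage.mode(data) <- "double"
  channel_labels <- toupper(as.character(channel_labels))
  if (length(channel_labels) != nrow(data))
    stop("number of data rows (", nrow(data), ") must equal number of ",
         "channel labels (", length(channel_labels), ")")
  if (nrow(data) < 1L) stop("recording must have at least one channel")
  if (anyDuplicated(channel_labels))
    stop("duplicate channel labels: ",
         paste(unique(channel_labels[duplicated(channel_labels)]), collapse = ", "))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar (Hz)")
  if (!all(is.finite(data))) stop("all samples must be finite")
  rownames(data) <- channel_labels
  structure(
    list(patient_id = as.character(patient_id),
         channel_labels = channel_labels,
         data = data, fs = fs, start_time_s = start_time_s),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> patient %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$patient_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = " "), "\n")
  invisible(x)
}

#' @rdname eeg_recording
#' @param rec an `eeg_recording`.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Duration of a recording in seconds
#' @param rec an `eeg_recording`.
#' @return Numeric scalar, seconds.
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$fs

# ---------------------------------------------------------------------------
# Recording I/O: CSV channel matrix, EDF, and an RDS array container.
# ---------------------------------------------------------------------------

#' Read an EEG recording from disk
#'
#' Three formats are supported: `"csv"` (first column time or sample index,
#' remaining columns one electrode each with a header row of names), `"edf"`
#' (16-bit European Data Format) and `"container"` (a serialized array
#' container used for lossless internal round-trips).
#'
#' @param path file path.
#' @param format_id one of `"csv"`, `"edf"`, `"container"`.
#' @param patient_id patient identifier to attach (CSV carries none).
#' @return An [eeg_recording()].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, format_id = c("csv", "edf", "container"),
                           patient_id = NULL) {
  format_id <- match.arg(format_id)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format_id,
    csv = read_recording_csv(
      path, patient_id %||% tools::file_path_sans_ext(basename(path))),
    edf = read_recording_edf(path, patient_id),
    container = {
      rec <- readRDS(path)
      if (!inherits(rec, "eeg_recording"))
        stop("container does not hold an eeg_recording: ", path)
      if (!is.null(patient_id)) rec$patient_id <- patient_id
      rec
    })
}

read_recording_csv <- function(path, patient_id) {
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  hdr <- gsub('^"|"$', "", trimws(hdr))
  if (length(hdr) < 2L)
    stop("CSV schema error: need a time/index column plus >=1 channel column")
  labels <- toupper(hdr[-1L])
  if (anyDuplicated(labels))
    stop("CSV schema error: duplicate channel header: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  df <- read.csv(path, check.names = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) stop("CSV parse error: non-numeric sample value")
  tcol <- df[[1L]]
  # Infer fs from the time column spacing when it looks like seconds;
  # integer 0,1,2,... index columns fall back to fs = 256.
  fs <- 256
  if (is.numeric(tcol) && length(tcol) > 1L) {
    dt <- diff(tcol)
    if (all(dt > 0) && max(abs(dt - dt[1L])) < 1e-9 * max(1, abs(dt[1L])) &&
        dt[1L] < 1) {
      fs <- 1 / dt[1L]
    }
  }
  eeg_recording(t(mat), labels, fs = fs, patient_id = patient_id)
}

#' Write an EEG recording to disk
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @param format_id one of `"csv"`, `"edf"`, `"container"`. CSV and the
#'   container are lossless for sample values; EDF quantizes to 16 bits.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format_id = c("csv", "edf", "container")) {
  format_id <- match.arg(format_id)
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(rec$channel_labels) == 0L) stop("recording has no channels")
  switch(format_id,
    csv = {
      df <- data.frame(t = (seq_len(ncol(rec$data)) - 1L) / rec$fs,
                       t(rec$data), check.names = FALSE)
      names(df) <- c("t", rec$channel_labels)
      write.csv(df, path, row.names = FALSE)
    },
    edf = write_recording_edf(rec, path),
    container = saveRDS(rec, path))
  invisible(path)
}

# --- Minimal EDF (16-bit) support ------------------------------------------
# Fixed-layout ASCII header (256 bytes + 256 per signal), one data record per
# second, little-endian int16 samples scaled through physical min/max.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

write_recording_edf <- function(rec, path) {
  ns <- nrow(rec$data)
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires integer fs")
  fs <- as.integer(round(fs))
  n_rec <- ceiling(ncol(rec$data) / fs)
  pad <- n_rec * fs - ncol(rec$data)
  x <- if (pad > 0) cbind(rec$data, matrix(0, ns, pad)) else rec$data
  pmin_ <- apply(x, 1, min); pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(edf_pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8); wr(rec$patient_id, 80); wr("seizewin", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 + 256 * ns, 8); wr("", 44); wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  for (lab in rec$channel_labels) wr(lab, 16)
  for (i in seq_len(ns)) wr("AgAgCl electrode", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(format(pmin_[i], digits = 7), 8)
  for (i in seq_len(ns)) wr(format(pmax_[i], digits = 7), 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns)) {
      dig <- round((x[i, cols] - pmin_[i]) * scale[i] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

read_recording_edf <- function(path, patient_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)
  pid <- rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("EDF parse error: bad signal count")
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  out <- matrix(0, ns, n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, endian = "little",
                     signed = TRUE)
      phys <- (dig - dmin[i]) * (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i]) +
        pmin_[i]
      out[i, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <- phys
    }
  }
  eeg_recording(out, labels, fs = spr[1L] / rec_dur,
                patient_id = patient_id %||% pid)
}

# ---------------------------------------------------------------------------
# Seizure annotations
# ---------------------------------------------------------------------------

#' Validate and normalize seizure annotations
#'
#' Annotations are events `[onset_s, offset_s)` on a 0.01 s grid (the
#' clinical annotation precision). Within each patient, events must be
#' strictly disjoint; they are returned sorted by onset within patient.
#'
#' @param df data frame with columns `patient_id`, `seizure_id`, `onset_s`,
#'   `offset_s`.
#' @param duration_bounds_s allowed event duration range; set `NULL` to skip
#'   (clinical data can fall outside the synthetic 6-140 s envelope).
#' @return The normalized annotation data frame (class `seizure_annotations`).
#' @export
as_seizure_annotations <- function(df, duration_bounds_s = NULL) {
  need <- c("patient_id", "seizure_id", "onset_s", "offset_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation columns missing: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  df$patient_id <- as.character(df$patient_id)
  df$seizure_id <- as.character(df$seizure_id)
  # round-half-up onto the 0.01 s grid
  grid <- function(x) floor(x * 100 + 0.5) / 100
  df$onset_s <- grid(as.numeric(df$onset_s))
  df$offset_s <- grid(as.numeric(df$offset_s))
  if (any(df$offset_s <= df$onset_s))
    stop("annotation validation error: offset_s must exceed onset_s (seizure ",
         paste(df$seizure_id[df$offset_s <= df$onset_s], collapse = ", "), ")")
  if (!is.null(duration_bounds_s)) {
    dur <- df$offset_s - df$onset_s
    bad <- dur < duration_bounds_s[1] | dur > duration_bounds_s[2]
    if (any(bad))
      stop("annotation validation error: duration outside [",
           duration_bounds_s[1], ", ", duration_bounds_s[2], "] s for ",
           paste(df$seizure_id[bad], collapse = ", "))
  }
  df <- df[order(df$patient_id, df$onset_s), , drop = FALSE]
  rownames(df) <- NULL
  for (p in unique(df$patient_id)) {
    sub <- df[df$patient_id == p, , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$onset_s[-1L] < sub$offset_s[-nrow(sub)]))
      stop("annotation validation error: overlapping seizures for patient ", p)
  }
  class(df) <- c("seizure_annotations", "data.frame")
  df
}

#' Read seizure annotations from CSV
#'
#' @param path CSV file with columns `patient_id`, `seizure_id`, `onset_s`,
#'   `offset_s`.
#' @inheritParams as_seizure_annotations
#' @return A `seizure_annotations` data frame, sorted by onset within patient.
#' @export
read_annotations <- function(path, duration_bounds_s = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  as_seizure_annotations(read.csv(path), duration_bounds_s)
}

#' Write seizure annotations to CSV
#' @param ann a `seizure_annotations` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  write.csv(as.data.frame(ann), path, row.names = FALSE)
  invisible(path)
}

#' Expand annotations to a per-sample binary label sequence
#'
#' Sample `i` (0-based) is labeled 1 iff its time `i / fs` falls inside
#' `[onset_s, offset_s)` of some event — the half-open convention means
#' abutting seizures never double-label a sample.
#'
#' @param ann `seizure_annotations` (for a single recording).
#' @param fs sampling rate, Hz.
#' @param n_samples number of samples in the recording.
#' @return Integer vector of 0/1 labels, length `n_samples`.
#' @export
annotations_to_labels <- function(ann, fs, n_samples) {
  labels <- integer(n_samples)
  total <- n_samples / fs
  for (k in seq_len(nrow(ann))) {
    on <- ann$onset_s[k]; off <- ann$offset_s[k]
    if (on < 0 || off > total + 1e-9)
      stop("annotation range error: [", on, ", ", off,
           ") outside recording span [0, ", total, ")")
    i0 <- ceiling(on * fs - 1e-9)          # first sample with i/fs >= onset
    i1 <- ceiling(off * fs - 1e-9) - 1     # last sample with i/fs < offset
    if (i1 >= i0) labels[(i0 + 1L):(i1 + 1L)] <- 1L
  }
  labels
}

#' Reduce a recording to a target electrode set
#'
#' Selects and reorders channels to exactly `target_labels`; extra channels
#' are dropped. The result depends only on the target list, never on the
#' input channel order.
#'
#' @param rec an [eeg_recording()].
#' @param target_labels ordered electrode names, all present in `rec`.
#' @return An [eeg_recording()] with rows exactly `target_labels`.
#' @export
harmonize_montage <- function(rec, target_labels = standard_montage_19()) {
  target_labels <- toupper(target_labels)
  missing <- setdiff(target_labels, rec$channel_labels)
  if (length(missing))
    stop("montage error: electrodes absent from recording: ",
         paste(missing, collapse = ", "))
  idx <- match(target_labels, rec$channel_labels)
  eeg_recording(rec$data[idx, , drop = FALSE], target_labels, rec$fs,
                rec$patient_id, rec$start_time_s)
}
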