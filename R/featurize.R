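# Frame/packet construction: non-overlapping 0.5 s windows, arithmetic-mean
# channel, wavelet augmentation, ictal/interictal balancing and 5-minute
# packetization.

#' Frame extraction configuration
#'
#' @param window_s window length in seconds (non-overlapping frames).
#' @param fs sampling rate, Hz; `window_s * fs` must be an integer >= 2.
#' @param wavelet_name wavelet filter for the frame feature block.
#' @param wavelet_level decomposition depth (1 gives the canonical 134
#'   coefficients for 128-sample windows).
#' @param extension_mode boundary rule; only `"symmetric"` is implemented.
#' @param label_rule a window is labeled ictal when at least this fraction
#'   of its samples is ictal.
#' @param packet_s packet span in seconds (600 frames at defaults).
#' @return A list of class `frame_config`.
#' @export
frame_config <- function(window_s = 0.5, fs = 256, wavelet_name = "db4",
                         wavelet_level = 1L, extension_mode = "symmetric",
                         label_rule = 0.5, packet_s = 300) {
  wlen <- window_s * fs
  if (abs(wlen - round(wlen)) > 1e-9 || round(wlen) < 2)
    stop("window_s * fs must be an integer >= 2 (got ", wlen, ")")
  if (wavelet_level < 1) stop("wavelet_level must be >= 1")
  if (!identical(extension_mode, "symmetric"))
    stop("only symmetric boundary extension is implemented")
  structure(list(window_s = window_s, fs = fs, wavelet_name = wavelet_name,
                 wavelet_level = as.integer(wavelet_level),
                 extension_mode = extension_mode, label_rule = label_rule,
                 packet_s = packet_s),
            class = "frame_config")
}

#' Cut a recording into non-overlapping fixed-length windows
#'
#' Produces `floor(n_samples / (window_s * fs))` windows; a trailing partial
#' window is discarded (frames must be fixed-length for the wavelet stage).
#'
#' @param rec an [eeg_recording()].
#' @param labels per-sample 0/1 label vector aligned with `rec` (e.g. from
#'   [annotations_to_labels()]); NULL for unlabeled data.
#' @param cfg a [frame_config()]; `cfg$fs` must equal `rec$fs`.
#' @param t_offset_s clock time of the first sample (for windows cut from a
#'   segment of a longer recording).
#' @return List of windows, each `list(x, labels, t_start_s)` with `x` a
#'   channel-by-`wlen` matrix.
#' @export
window_signal <- function(rec, labels = NULL, cfg = frame_config(),
                          t_offset_s = 0) {
  if (abs(rec$fs - cfg$fs) > 1e-9)
    stop("configuration error: recording fs ", rec$fs,
         " != frame config fs ", cfg$fs)
  wlen <- round(cfg$window_s * cfg$fs)
  n <- ncol(rec$data)
  if (!is.null(labels) && length(labels) != n)
    stop("labels length ", length(labels), " != sample count ", n)
  n_win <- n %/% wlen
  lapply(seq_len(n_win), function(k) {
    idx <- ((k - 1L) * wlen + 1L):(k * wlen)
    list(x = rec$data[, idx, drop = FALSE],
         labels = if (is.null(labels)) integer(wlen) else labels[idx],
         t_start_s = t_offset_s + (k - 1L) * cfg$window_s)
  })
}

#' Arithmetic-mean channel of a window
#'
#' Unweighted per-sample mean across channels; averaging attenuates
#' channel-local contamination such as blinks before the wavelet stage.
#'
#' @param window channel-by-sample numeric matrix (>= 1 channel).
#' @return Numeric vector, one value per sample.
#' @export
mean_channel <- function(window) {
  if (!is.matrix(window)) window <- rbind(window)
  if (nrow(window) < 1L) stop("mean_channel needs at least one channel")
  colMeans(window)
}

window_rms <- function(x) sqrt(mean(x^2))

#' Assemble feature frames (and optionally sample sequences) from windows
#'
#' Per window: the per-channel summary (RMS amplitude), the mean-channel
#' summary, and the wavelet coefficients of that window's mean channel. The
#' window label is 1 iff at least `cfg$label_rule` of its samples are
#' ictal. When `store_samples` is TRUE the per-sample sequence consumed by
#' sample-granularity classifiers is also built: each sample row carries the
#' C raw channel values, the mean-channel value, and its window's (constant)
#' wavelet block, so the per-row dimension is always C + 1 + 134.
#'
#' @param windows output of [window_signal()].
#' @param cfg a [frame_config()].
#' @param channel_labels electrode names for the window rows.
#' @param store_samples build the per-sample feature matrix as well.
#' @return A `frame_set`: list with `window_features` (T x (C+135) matrix),
#'   `labels`, `t_start_s`, `window_index`, and when requested
#'   `sample_features` / `sample_labels`.
#' @export
assemble_frames <- function(windows, cfg = frame_config(),
                            channel_labels = NULL, store_samples = FALSE) {
  nw <- length(windows)
  if (nw == 0L) {
    return(structure(list(window_features = NULL, labels = integer(0),
                          t_start_s = numeric(0), window_index = integer(0),
                          channel_labels = channel_labels, cfg = cfg,
                          sample_features = NULL, sample_labels = NULL),
                     class = "frame_set"))
  }
  C <- nrow(windows[[1L]]$x)
  wlen <- ncol(windows[[1L]]$x)
  nwav <- n_wavelet_features(cfg)
  channel_labels <- channel_labels %||% rownames(windows[[1L]]$x) %||%
    paste0("ch", seq_len(C))
  Xw <- matrix(0, nw, C + 1L + nwav)
  lab <- integer(nw)
  tt <- numeric(nw)
  Xs <- if (store_samples) matrix(0, nw * wlen, C + 1L + nwav) else NULL
  ys <- if (store_samples) integer(nw * wlen) else NULL
  for (k in seq_len(nw)) {
    w <- windows[[k]]
    m <- mean_channel(w$x)
    wav <- wavelet_features(m, cfg)
    Xw[k, ] <- c(apply(w$x, 1L, window_rms), window_rms(m), wav)
    lab[k] <- as.integer(mean(w$labels) >= cfg$label_rule)
    tt[k] <- w$t_start_s
    if (store_samples) {
      rows <- ((k - 1L) * wlen + 1L):(k * wlen)
      Xs[rows, ] <- cbind(t(w$x), m,
                          matrix(wav, wlen, nwav, byrow = TRUE))
      ys[rows] <- w$labels
    }
  }
  colnames(Xw) <- c(channel_labels, "MEAN", paste0("W", seq_len(nwav)))
  structure(list(window_features = Xw, labels = lab, t_start_s = tt,
                 window_index = seq_len(nw), channel_labels = channel_labels,
                 cfg = cfg, sample_features = Xs, sample_labels = ys),
            class = "frame_set")
}

# ---------------------------------------------------------------------------
# Class balancing and packetization
# ---------------------------------------------------------------------------

# Subtract [a, b] from a set of disjoint intervals (2-column matrix).
interval_subtract <- function(free, a, b) {
  out <- NULL
  for (i in seq_len(nrow(free))) {
    lo <- free[i, 1]; hi <- free[i, 2]
    if (b <= lo || a >= hi) { out <- rbind(out, c(lo, hi)); next }
    if (a > lo) out <- rbind(out, c(lo, a))
    if (b < hi) out <- rbind(out, c(b, hi))
  }
  if (is.null(out)) matrix(numeric(0), 0, 2) else out
}

#' Select balanced ictal/interictal segments of a recording
#'
#' For every annotated seizure, emits the seizure segment plus one
#' equal-duration interictal segment from the same recording, excluded from
#' all seizures plus a `buffer_s` guard on both sides, non-overlapping with
#' previously chosen segments. Selection is deterministic given `seed`: the
#' earliest feasible interictal start at or after a seeded offset is taken
#' (wrapping to the earliest feasible start overall).
#'
#' @param rec an [eeg_recording()].
#' @param ann `seizure_annotations` for this recording.
#' @param buffer_s exclusion margin around seizures, seconds.
#' @param seed integer seed for the interictal placement.
#' @return Data frame of segments with columns `t0`, `t1`, `kind`
#'   (`"ictal"`/`"interictal"`), `seizure_id`, `patient_id`.
#' @export
balance_segments <- function(rec, ann, buffer_s = 30, seed = 1L) {
  total <- duration_s(rec)
  ann <- ann[ann$patient_id == rec$patient_id, , drop = FALSE]
  if (nrow(ann) == 0L) stop("balancing error: no seizures for patient ",
                            rec$patient_id)
  free <- matrix(c(0, total), 1, 2)
  for (k in seq_len(nrow(ann)))
    free <- interval_subtract(free, max(0, ann$onset_s[k] - buffer_s),
                              min(total, ann$offset_s[k] + buffer_s))
  segs <- NULL
  r0 <- with_seed(seed, runif(1, 0, total))
  for (k in seq_len(nrow(ann))) {
    dur <- ann$offset_s[k] - ann$onset_s[k]
    segs <- rbind(segs, data.frame(
      t0 = ann$onset_s[k], t1 = ann$offset_s[k], kind = "ictal",
      seizure_id = ann$seizure_id[k], patient_id = rec$patient_id))
    ok <- free[, 2] - free[, 1] >= dur - 1e-9
    if (!any(ok))
      stop("balancing error: insufficient interictal signal for seizure ",
           ann$seizure_id[k], " (need ", dur, " s)")
    cand <- free[ok, , drop = FALSE]
    cand <- cand[order(cand[, 1]), , drop = FALSE]
    at <- cand[, 1] <= r0 + 1e-12 & cand[, 2] - dur >= r0 - 1e-12
    start <- if (any(at)) r0
             else if (any(cand[, 1] > r0)) cand[cand[, 1] > r0, 1][1]
             else cand[1, 1]
    start <- floor(start * 100) / 100
    segs <- rbind(segs, data.frame(
      t0 = start, t1 = start + dur, kind = "interictal",
      seizure_id = ann$seizure_id[k], patient_id = rec$patient_id))
    free <- interval_subtract(free, start, start + dur)
  }
  segs[order(segs$t0), , drop = FALSE]
}

# Frame one segment of a recording (half-open [t0, t1) in samples).
frame_segment <- function(rec, seg, labels, cfg, store_samples = FALSE) {
  i0 <- floor(seg$t0 * rec$fs) + 1L
  i1 <- floor(seg$t1 * rec$fs)
  sub <- eeg_recording(rec$data[, i0:i1, drop = FALSE], rec$channel_labels,
                       rec$fs, rec$patient_id)
  fw <- window_signal(sub, labels[i0:i1], cfg, t_offset_s = (i0 - 1L) / rec$fs)
  fs_ <- assemble_frames(fw, cfg, rec$channel_labels, store_samples)
  fs_$segment_id <- paste0(seg$seizure_id, "_", seg$kind)
  fs_$seizure_id <- if (seg$kind == "ictal") seg$seizure_id else NA_character_
  fs_$patient_id <- rec$patient_id
  fs_
}

#' Concatenate framed segments into fixed-span packets
#'
#' Frames are concatenated segment-by-segment (times contiguous within each
#' source segment) and cut into packets of `cfg$packet_s / cfg$window_s`
#' frames (600 at defaults). The final partial packet is retained and
#' flagged `partial = TRUE` rather than dropped — discarding it could
#' silently lose seizures.
#'
#' @param frame_sets list of `frame_set` objects (one per segment).
#' @param cfg a [frame_config()].
#' @return List of `eeg_packet` objects with fields `X` (frames x features),
#'   `y`, `t_start_s`, `segment_id`, `seizure_id`, `patient_id`, `partial`,
#'   and optionally `sample_X` / `sample_y`.
#' @export
packetize <- function(frame_sets, cfg = frame_config()) {
  frame_sets <- Filter(function(f) length(f$labels) > 0, frame_sets)
  if (length(frame_sets) == 0L) return(list())
  X <- do.call(rbind, lapply(frame_sets, `[[`, "window_features"))
  y <- unlist(lapply(frame_sets, `[[`, "labels"), use.names = FALSE)
  tt <- unlist(lapply(frame_sets, `[[`, "t_start_s"), use.names = FALSE)
  seg <- unlist(lapply(frame_sets, function(f)
    rep(f$segment_id %||% NA_character_, length(f$labels))))
  sid <- unlist(lapply(frame_sets, function(f)
    rep(f$seizure_id %||% NA_character_, length(f$labels))))
  pid <- unlist(lapply(frame_sets, function(f)
    rep(f$patient_id %||% NA_character_, length(f$labels))))
  has_samples <- !is.null(frame_sets[[1L]]$sample_features)
  if (has_samples) {
    Xs <- do.call(rbind, lapply(frame_sets, `[[`, "sample_features"))
    ys <- unlist(lapply(frame_sets, `[[`, "sample_labels"), use.names = FALSE)
    wlen <- round(cfg$window_s * cfg$fs)
  }
  per <- round(cfg$packet_s / cfg$window_s)
  n <- length(y)
  n_pack <- ceiling(n / per)
  lapply(seq_len(n_pack), function(p) {
    idx <- ((p - 1L) * per + 1L):min(p * per, n)
    pk <- list(X = X[idx, , drop = FALSE], y = y[idx], t_start_s = tt[idx],
               segment_id = seg[idx], seizure_id = sid[idx],
               patient_id = pid[idx], partial = length(idx) < per,
               cfg = cfg)
    if (has_samples) {
      srows <- ((idx[1L] - 1L) * wlen + 1L):(idx[length(idx)] * wlen)
      pk$sample_X <- Xs[srows, , drop = FALSE]
      pk$sample_y <- ys[srows]
    }
    structure(pk, class = "eeg_packet")
  })
}

#' @export
print.eeg_packet <- function(x, ...) {
  cat(sprintf("<eeg_packet> %d frames x %d features, %.0f%% ictal%s\n",
              nrow(x$X), ncol(x$X), 100 * mean(x$y),
              if (x$partial) " (partial)" else ""))
  invisible(x)
}

#' Build balanced training packets from one annotated recording
#'
#' Convenience pipeline: balance -> window -> assemble -> packetize,
#' optionally restricted to a subset of seizures (used by train/test
#' splitting) and/or a reduced montage.
#'
#' @param rec an [eeg_recording()].
#' @param ann `seizure_annotations`.
#' @param cfg a [frame_config()].
#' @param seizure_ids restrict to these seizures (NULL = all of patient).
#' @param channels montage to harmonize to before framing (NULL = keep).
#' @param buffer_s,seed passed to [balance_segments()].
#' @param store_samples keep per-sample sequences in the packets.
#' @return List of `eeg_packet` objects.
#' @export
build_packets <- function(rec, ann, cfg = frame_config(), seizure_ids = NULL,
                          channels = NULL, buffer_s = 30, seed = 1L,
                          store_samples = FALSE) {
  if (!is.null(channels)) rec <- harmonize_montage(rec, channels)
  ann_p <- ann[ann$patient_id == rec$patient_id, , drop = FALSE]
  segs <- balance_segments(rec, ann_p, buffer_s = buffer_s, seed = seed)
  if (!is.null(seizure_ids))
    segs <- segs[segs$seizure_id %in% seizure_ids, , drop = FALSE]
  if (nrow(segs) == 0L) return(list())
  labels <- annotations_to_labels(ann_p, rec$fs, ncol(rec$data))
  fsets <- lapply(seq_len(nrow(segs)), function(i)
    frame_segment(rec, segs[i, ], labels, cfg, store_samples))
  packetize(fsets, cfg)
}
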