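# Synthetic multi-patient scalp EEG with embedded seizures.
#
# The generator is a stand-in for clinical long-term monitoring data: pink
# (1/f) background with an alpha-band component and optional frontal blink
# artifacts, plus seizures rendered as a 3-5 Hz oscillation with a 1 s
# amplitude ramp at onset. It makes no claim of clinical realism; its job is
# to give every downstream stage (framing, balancing, training, event
# evaluation, streaming) a learnable, fully reproducible input.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 100000 * 20011 + index * 7919 + 1) %%
               2147483646) + 1L
}

#' Configuration for the synthetic EEG cohort generator
#'
#' Defaults emulate the statistics of large clinical scalp-EEG seizure
#' corpora at desk scale: 19-channel 10-20 montage at 256 Hz, 6-140 s
#' seizures averaging ~60 s (Beta(2, 2.963) scaled onto \[6, 140\] — a
#' uniform draw on that interval would average 73 s, not the observed ~60),
#' and >= 120 s of interictal signal between events so class balancing
#' always has room to work.
#'
#' @param n_patients number of patients in a cohort.
#' @param seizures_per_patient integer range `c(min, max)` of seizures drawn
#'   per patient.
#' @param fs sampling rate, Hz.
#' @param channels electrode labels (10-20 names).
#' @param seizure_duration_s bounds of the seizure-duration distribution,
#'   seconds.
#' @param duration_beta shape parameters of the scaled Beta duration sampler;
#'   the default has mean 60 s within the 6-140 s bounds.
#' @param background_amp_uV RMS amplitude of the pink-noise background per
#'   channel, microvolts.
#' @param alpha_amp_uV amplitude of the 8-12 Hz background component,
#'   microvolts.
#' @param seizure_band_hz ictal oscillation frequency band, Hz.
#' @param amplitude_gain ictal oscillation amplitude as a multiple of
#'   `background_amp_uV` (the separability dial; 0 = null effect).
#' @param focus_channels electrodes carrying the seizure (NULL = all
#'   channels, emulating generalized onsets).
#' @param nonfocus_weight relative ictal amplitude on channels outside the
#'   focus set.
#' @param artifact_rate blink events per minute on FP1/FP2 (0 disables).
#' @param interictal_gap_s minimum interictal separation between seizures,
#'   seconds.
#' @param duration_s fixed recording length in seconds, or NULL to size each
#'   recording automatically so all seizures plus balancing buffers fit.
#' @param seed cohort master seed; per-patient streams are derived from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_patients = 12,
                         seizures_per_patient = c(2, 3),
                         fs = 256,
                         channels = standard_montage_19(),
                         seizure_duration_s = c(6, 140),
                         duration_beta = c(2, 2.963),
                         background_amp_uV = 20,
                         alpha_amp_uV = 8,
                         seizure_band_hz = c(3, 5),
                         amplitude_gain = 3,
                         focus_channels = NULL,
                         nonfocus_weight = 0,
                         artifact_rate = 2,
                         interictal_gap_s = 120,
                         duration_s = NULL,
                         seed = 1L) {
  stopifnot(fs > 0, n_patients >= 1)
  if (seizure_duration_s[1] < 6 || seizure_duration_s[2] > 140 ||
      diff(seizure_duration_s) < 0)
    stop("seizure duration bounds must lie within [6, 140] s")
  channels <- toupper(channels)
  if (!all(is_valid_1020(channels)))
    stop("unknown 10-20 labels: ",
         paste(channels[!is_valid_1020(channels)], collapse = ", "))
  if (!is.null(focus_channels)) {
    focus_channels <- toupper(focus_channels)
    if (!all(focus_channels %in% channels))
      stop("focus channels must be a subset of the montage")
  }
  w <- seizure_channel_weights(channels, focus_channels, nonfocus_weight)
  if (any(w < 0) || all(w == 0))
    stop("seizure channel weights must be nonnegative and not all zero")
  structure(list(
    n_patients = as.integer(n_patients),
    seizures_per_patient = as.integer(seizures_per_patient),
    fs = fs, channels = channels,
    seizure_duration_s = seizure_duration_s,
    duration_beta = duration_beta,
    background_amp_uV = background_amp_uV,
    alpha_amp_uV = alpha_amp_uV,
    seizure_band_hz = seizure_band_hz,
    amplitude_gain = amplitude_gain,
    focus_channels = focus_channels,
    nonfocus_weight = nonfocus_weight,
    artifact_rate = artifact_rate,
    interictal_gap_s = interictal_gap_s,
    duration_s = duration_s,
    seed = as.integer(seed)), class = "synth_config")
}

seizure_channel_weights <- function(channels, focus, nonfocus_weight) {
  if (is.null(focus)) return(setNames(rep(1, length(channels)), channels))
  w <- setNames(rep(nonfocus_weight, length(channels)), channels)
  w[focus] <- 1
  w
}

# 1/f-weighted noise via spectral shaping; deterministic given the RNG state.
pink_noise <- function(n, fs) {
  white <- rnorm(n)
  spec <- fft(white)
  f <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, fs - f)                    # two-sided frequency magnitude
  w <- 1 / sqrt(pmax(f, 1))               # flat below 1 Hz, 1/f above
  Re(fft(spec * w, inverse = TRUE)) / n
}

blink_waveform <- function(fs, amp = 120) {
  tt <- seq(-0.25, 0.25, by = 1 / fs)
  amp * exp(-(tt / 0.08)^2)
}

#' Generate synthetic interictal (background) EEG
#'
#' Pink-noise background plus an 8-12 Hz alpha component per channel, with
#' optional blink transients on the frontal electrodes FP1/FP2.
#'
#' @param duration_s signal length, seconds (> 0).
#' @param cfg a [synth_config()].
#' @param seed integer seed; the output is a pure function of `(cfg, seed)`.
#' @return Numeric matrix, channels x samples, microvolts.
#' @export
generate_background <- function(duration_s, cfg, seed = cfg$seed) {
  stopifnot(duration_s > 0)
  n <- round(duration_s * cfg$fs)
  C <- length(cfg$channels)
  with_seed(seed, {
    tt <- (seq_len(n) - 1L) / cfg$fs
    x <- matrix(0, C, n, dimnames = list(cfg$channels, NULL))
    for (c in seq_len(C)) {
      p <- pink_noise(n, cfg$fs)
      p <- p / max(sd(p), 1e-12) * cfg$background_amp_uV
      f_alpha <- runif(1, 8, 12)
      alpha <- cfg$alpha_amp_uV * sin(2 * pi * f_alpha * tt + runif(1, 0, 2 * pi))
      x[c, ] <- p + alpha
    }
    if (cfg$artifact_rate > 0) {
      frontal <- intersect(c("FP1", "FP2"), cfg$channels)
      if (length(frontal)) {
        n_blink <- stats::rpois(1, cfg$artifact_rate * duration_s / 60)
        if (n_blink > 0) {
          times <- sort(runif(n_blink, 0.3, duration_s - 0.3))
          bw <- blink_waveform(cfg$fs)
          half <- (length(bw) - 1L) %/% 2L
          for (t0 in times) {
            i0 <- round(t0 * cfg$fs) - half
            idx <- i0:(i0 + length(bw) - 1L)
            keep <- idx >= 1L & idx <= n
            for (ch in frontal)
              x[ch, idx[keep]] <- x[ch, idx[keep]] + bw[keep]
          }
        }
      }
    }
    x
  })
}

sample_seizure_durations <- function(k, cfg) {
  lo <- cfg$seizure_duration_s[1]; hi <- cfg$seizure_duration_s[2]
  d <- lo + (hi - lo) * rbeta(k, cfg$duration_beta[1], cfg$duration_beta[2])
  floor(d * 100 + 0.5) / 100
}

#' Generate one synthetic recording with annotated seizures
#'
#' Seizures are placed with at least `interictal_gap_s` of interictal signal
#' before, between and after events; within each event a band-limited
#' oscillation (default 3-5 Hz) with a 1 s onset amplitude ramp is added on
#' the weighted focus channels. When `cfg$duration_s` is NULL the recording
#' is sized so that every seizure also has room for an equal-duration
#' interictal balancing segment.
#'
#' @param cfg a [synth_config()].
#' @param patient_id identifier attached to recording and annotations.
#' @param seed integer seed.
#' @param n_seizures fixed seizure count, or NULL to draw from
#'   `cfg$seizures_per_patient`.
#' @return List with elements `recording` ([eeg_recording()]) and
#'   `annotations` (`seizure_annotations`).
#' @export
generate_recording <- function(cfg, patient_id = "p1", seed = cfg$seed,
                               n_seizures = NULL) {
  gap <- cfg$interictal_gap_s
  with_seed(seed, {
    lo <- cfg$seizures_per_patient[1]
    hi <- cfg$seizures_per_patient[2]
    k <- n_seizures %||% (lo + sample.int(hi - lo + 1L, 1L) - 1L)
    dur <- sample_seizure_durations(k, cfg)
    jit <- runif(k, 0, 10)
    onset <- numeric(k)
    t <- gap
    for (i in seq_len(k)) {
      onset[i] <- t + jit[i]
      t <- onset[i] + dur[i] + gap
    }
    onset <- floor(onset * 100 + 0.5) / 100
    offset <- onset + dur
    # tail long enough that balancing could place every interictal
    # segment there even if the inter-seizure gaps are all too short
    auto_len <- ceiling(offset[k] + gap + sum(dur) + 70)
    total <- cfg$duration_s %||% auto_len
    if (offset[k] + gap > total)
      stop("configuration error: ", k, " seizures with ", gap,
           " s gaps do not fit in a ", total, " s recording")
    x <- generate_background(total, cfg, seed = derive_seed(seed, 1))
    w <- seizure_channel_weights(cfg$channels, cfg$focus_channels,
                                 cfg$nonfocus_weight)
    fs <- cfg$fs
    for (i in seq_len(k)) {
      f0 <- runif(1, cfg$seizure_band_hz[1], cfg$seizure_band_hz[2])
      phase <- runif(1, 0, 2 * pi)
      i0 <- floor(onset[i] * fs) + 1L
      i1 <- min(ceiling(offset[i] * fs), ncol(x))
      tt <- ((i0:i1) - 1L) / fs
      ramp <- pmin((tt - onset[i]) / 1.0, 1)          # 1 s onset ramp
      amp <- cfg$amplitude_gain * cfg$background_amp_uV
      osc <- amp * ramp * (sin(2 * pi * f0 * (tt - onset[i]) + phase) +
                             0.3 * sin(4 * pi * f0 * (tt - onset[i]) + 2 * phase))
      x[, i0:i1] <- x[, i0:i1] + outer(unname(w), osc)
    }
    ann <- as_seizure_annotations(data.frame(
      patient_id = patient_id,
      seizure_id = sprintf("%s_s%02d", patient_id, seq_len(k)),
      onset_s = onset, offset_s = offset))
    list(recording = eeg_recording(x, cfg$channels, fs, patient_id),
         annotations = ann)
  })
}

#' Generate a synthetic cohort
#'
#' One recording per patient with >= 1 seizure each; per-patient seeds are
#' derived deterministically from the cohort seed so any patient can be
#' regenerated independently.
#'
#' @param cfg a [synth_config()].
#' @return List of class `synth_cohort`; each element is the
#'   [generate_recording()] result for one patient. `annotations(cohort)`
#'   binds all annotation tables.
#' @export
generate_cohort <- function(cfg) {
  out <- lapply(seq_len(cfg$n_patients), function(i) {
    generate_recording(cfg, patient_id = sprintf("p%02d", i),
                       seed = derive_seed(cfg$seed, i))
  })
  names(out) <- vapply(out, function(e) e$recording$patient_id, "")
  structure(out, class = "synth_cohort")
}

#' Pool the annotation tables of a cohort
#' @param cohort a `synth_cohort`.
#' @return A `seizure_annotations` data frame over all patients.
#' @export
cohort_annotations <- function(cohort) {
  as_seizure_annotations(do.call(rbind, lapply(cohort, function(e)
    as.data.frame(e$annotations))))
}

#' Average signal power in a frequency band
#'
#' Periodogram-based band power, used by the seizure-origin analysis and by
#' separability checks on synthetic data.
#'
#' @param x numeric signal vector.
#' @param fs sampling rate, Hz.
#' @param band `c(lo, hi)` frequency band, Hz.
#' @return Mean periodogram power in the band.
#' @export
band_power <- function(x, fs, band) {
  n <- length(x)
  p <- abs(fft(x - mean(x)))^2 / n
  f <- (seq_len(n) - 1L) * fs / n
  sel <- f >= band[1] & f <= band[2]
  if (!any(sel)) return(0)
  mean(p[sel])
}
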