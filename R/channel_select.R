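# Electrode-reduction experiments: predefined combos, correlation ranking,
# seizure-origin (band-power) ranking and Shapley channel attribution.

#' The predefined reduced-montage configurations
#'
#' Five named electrode subsets: the 15 most commonly available positions,
#' two similarity-based frontal-weighted combos, and two correlation-top-K
#' combos.
#'
#' @return Named list of `channel_combo` objects (fields `name`,
#'   `electrodes`, `selection_method`).
#' @export
#' @examples
#' builtin_combos()[["Combo 2"]]$electrodes
builtin_combos <- function() {
  mk <- function(name, electrodes, method) {
    stopifnot(all(is_valid_1020(electrodes)), !anyDuplicated(electrodes))
    structure(list(name = name, electrodes = electrodes,
                   selection_method = method), class = "channel_combo")
  }
  list(
    "Common 15" = mk("Common 15",
      c("C3", "C4", "CZ", "F3", "F4", "F7", "F8", "FP1", "FP2", "FZ",
        "O1", "O2", "P3", "P4", "PZ"), "manual"),
    "Combo 1" = mk("Combo 1", c("FP1", "FP2", "F7", "O1", "F3"),
                   "similarity"),
    "Combo 2" = mk("Combo 2", c("FP1", "FP2", "F7", "O1", "F3", "FZ"),
                   "similarity"),
    "Combo 3" = mk("Combo 3", c("O2", "O1", "F7", "PZ"),
                   "correlation-topK"),
    "Combo 4" = mk("Combo 4", c("O2", "O1", "F7", "PZ", "C3", "CZ"),
                   "correlation-topK"))
}

#' Rank channels by correlation with the seizure labels
#'
#' Absolute Pearson correlation between each channel's samples and the
#' per-sample binary label sequence, in descending order; ties (including
#' constant channels, which get correlation 0 with a warning) break by
#' canonical 10-20 ordering. Because ictal oscillations are zero-mean, the
#' default correlates the instantaneous amplitude `|x - mean(x)|` with the
#' labels; `transform = "raw"` correlates the raw samples instead.
#'
#' @param rec an [eeg_recording()] (or channels-x-samples matrix with
#'   rownames).
#' @param labels per-sample 0/1 labels aligned with the recording.
#' @param transform `"amplitude"` (default) or `"raw"`.
#' @return Data frame `electrode`, `correlation`, sorted descending.
#' @export
correlation_ranking <- function(rec, labels,
                                transform = c("amplitude", "raw")) {
  transform <- match.arg(transform)
  x <- if (inherits(rec, "eeg_recording")) rec$data else rec
  if (length(unique(labels)) < 2L)
    stop("labels must contain both classes")
  if (ncol(x) != length(labels))
    stop("labels length must match sample count")
  r <- apply(x, 1L, function(ch) {
    if (transform == "amplitude") ch <- abs(ch - mean(ch))
    if (sd(ch) < 1e-12) {
      warning("constant channel; correlation set to 0")
      return(0)
    }
    abs(cor(ch, labels))
  })
  df <- data.frame(electrode = rownames(x) %||% paste0("ch", seq_len(nrow(x))),
                   correlation = unname(r), stringsAsFactors = FALSE)
  canon <- canonical_channel_order(df$electrode)
  df <- df[order(-df$correlation, canon), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Rank channels by ictal/interictal band-power ratio
#'
#' The seizure-origin analysis: for each channel, mean band power (default
#' the 3-5 Hz ictal band) during seizures divided by band power outside
#' them; high ratios mark channels close to the seizure focus.
#'
#' @param rec an [eeg_recording()].
#' @param ann `seizure_annotations` for this recording.
#' @param band frequency band, Hz.
#' @return Data frame `electrode`, `power_ratio`, sorted descending.
#' @export
seizure_origin_ranking <- function(rec, ann, band = c(3, 5)) {
  labels <- annotations_to_labels(ann[ann$patient_id == rec$patient_id, ],
                                  rec$fs, ncol(rec$data))
  ict <- labels == 1L
  ratio <- apply(rec$data, 1L, function(ch)
    band_power(ch[ict], rec$fs, band) /
      max(band_power(ch[!ict], rec$fs, band), 1e-12))
  df <- data.frame(electrode = rec$channel_labels, power_ratio = unname(ratio),
                   stringsAsFactors = FALSE)
  canon <- canonical_channel_order(df$electrode)
  df <- df[order(-df$power_ratio, canon), , drop = FALSE]
  rownames(df) <- NULL
  df
}

subset_key <- function(s) paste(sort(s), collapse = "|")

#' Shapley channel attribution
#'
#' Attribution of a performance value function over channel coalitions.
#' `exact = TRUE` enumerates all subsets (feasible for <= ~12 channels and
#' the default for <= 6); otherwise the estimate averages marginal
#' contributions over `n_perm` random channel orderings (deterministic
#' given `seed`). The value function is memoized, so each coalition is
#' evaluated once.
#'
#' @param value_fn function(character vector of channels) -> scalar
#'   performance; must accept `character(0)`.
#' @param channels channel names of the full game.
#' @param n_perm permutations for the sampled estimator.
#' @param seed integer seed.
#' @param exact force exact enumeration on or off.
#' @return Data frame `electrode`, `shapley`, in `channels` order, with
#'   attributes `v_full` and `v_empty` (Shapley efficiency:
#'   `sum(shapley) == v_full - v_empty`).
#' @export
shapley_importance <- function(value_fn, channels, n_perm = 500L, seed = 1L,
                               exact = length(channels) <= 6L) {
  n <- length(channels)
  if (n < 1L) stop("need at least one channel")
  if (!exact && n_perm < 1L) stop("n_perm must be >= 1")
  cache <- new.env(parent = emptyenv())
  v <- function(s) {
    key <- paste0("S:", subset_key(s))
    if (is.null(cache[[key]])) {
      val <- value_fn(s)
      if (!is.finite(val))
        stop("value function failed on subset {", key, "}")
      cache[[key]] <- val
    }
    cache[[key]]
  }
  phi <- setNames(numeric(n), channels)
  if (exact) {
    lf <- lfactorial
    for (mask in 0:(2^n - 1)) {
      inset <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
      S <- channels[inset]
      s_ <- length(S)
      vS <- v(S)
      for (i in which(!inset)) {
        wgt <- exp(lf(s_) + lf(n - s_ - 1) - lf(n))
        phi[channels[i]] <- phi[channels[i]] +
          wgt * (v(c(S, channels[i])) - vS)
      }
    }
  } else {
    with_seed(seed, {
      for (p in seq_len(n_perm)) {
        ord <- sample(channels)
        prev <- character(0)
        v_prev <- v(prev)
        for (ch in ord) {
          cur <- c(prev, ch)
          v_cur <- v(cur)
          phi[ch] <- phi[ch] + (v_cur - v_prev) / n_perm
          prev <- cur
          v_prev <- v_cur
        }
      }
    })
  }
  structure(data.frame(electrode = channels, shapley = unname(phi),
                       stringsAsFactors = FALSE),
            v_full = v(channels), v_empty = v(character(0)))
}

#' Fast surrogate value function for channel games
#'
#' Full BiLSTM retraining per coalition is not desk-scale; the default
#' Shapley value function is instead the held-out window accuracy of a
#' logistic classifier on per-channel window RMS features, computed from
#' balanced frames of the cohort. `v(empty)` is the majority-class
#' accuracy.
#'
#' @param cohort a `synth_cohort` (or list of `list(recording, annotations)`).
#' @param fcfg a [frame_config()].
#' @param train_frac fraction of windows used for fitting.
#' @param seed integer seed for the window split.
#' @return function(channel subset) -> accuracy in `[0, 1]`.
#' @export
make_channel_value_fn <- function(cohort, fcfg = frame_config(),
                                  train_frac = 0.7, seed = 1L) {
  feats <- list(); labs <- list()
  for (e in cohort) {
    pks <- build_packets(e$recording, e$annotations, fcfg, seed = seed)
    C <- length(e$recording$channel_labels)
    for (p in pks) {
      feats[[length(feats) + 1L]] <- p$X[, seq_len(C), drop = FALSE]
      labs[[length(labs) + 1L]] <- p$y
    }
  }
  X <- do.call(rbind, feats)
  y <- unlist(labs)
  n <- nrow(X)
  idx <- with_seed(seed, sample(n))
  tr <- idx[seq_len(round(train_frac * n))]
  te <- setdiff(idx, tr)
  majority <- as.integer(mean(y[tr]) >= 0.5)
  function(subset) {
    if (length(subset) == 0L) return(mean(y[te] == majority))
    cols <- match(toupper(subset), colnames(X))
    if (anyNA(cols)) stop("unknown channels: ",
                          paste(subset[is.na(cols)], collapse = ", "))
    df_tr <- data.frame(y = y[tr], X[tr, cols, drop = FALSE])
    fit <- suppressWarnings(
      stats::glm(y ~ ., data = df_tr, family = stats::binomial()))
    pr <- stats::predict(fit,
                         newdata = data.frame(X[te, cols, drop = FALSE]),
                         type = "response")
    mean(as.integer(pr >= 0.5) == y[te])
  }
}

#' Evaluate one electrode combo with the full pipeline
#'
#' Harmonize each cohort recording to the combo montage, build balanced
#' packets, train on the first Monte Carlo split and evaluate events on its
#' held-out seizures. The feature dimension is `length(electrodes) + 135`.
#'
#' @param cohort a `synth_cohort`.
#' @param combo a `channel_combo` (or character vector of electrodes).
#' @param model_cfg a [model_config()].
#' @param fcfg a [frame_config()].
#' @param run_len consecutive-window detection requirement.
#' @param weights [score_weights()] for the composite score.
#' @param split optional `list(train, test)` of seizure ids; default is the
#'   first repeat of [monte_carlo_splits()] with `model_cfg$seed`.
#' @return An `event_metrics` object (held-out seizures).
#' @export
evaluate_combo <- function(cohort, combo, model_cfg = model_config(),
                           fcfg = frame_config(), run_len = 2L,
                           weights = score_weights(), split = NULL) {
  electrodes <- if (inherits(combo, "channel_combo")) combo$electrodes
                else toupper(combo)
  ann <- cohort_annotations(cohort)
  split <- split %||%
    monte_carlo_splits(ann, k = 1L, seed = model_cfg$seed)$repeats[[1L]]
  run_detection_run(cohort, ann, electrodes, fcfg, model_cfg, split,
                    run_len, weights)$metrics
}
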