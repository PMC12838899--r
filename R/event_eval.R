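# Event-level evaluation: window confusion metrics, detection delay,
# undetected-seizure accounting and the composite 0-10 score
#   score = scale * [ alpha * Acc + beta * (1 - DD / 13) + gamma * Recall ]
# with the delay term floored at zero beyond the 13 s normalization bound.

#' Composite-score weights
#'
#' @param alpha accuracy weight.
#' @param beta delay-term weight.
#' @param gamma recall-term weight. The three must be nonnegative and sum
#'   to 1.
#' @param dd_norm_s delay normalization constant, seconds (13 = maximum
#'   observed delay in the reference experiments).
#' @param scale output scale (score ranges 0..`scale`).
#' @return A `score_weights` list.
#' @export
score_weights <- function(alpha = 0.4, beta = 0.4, gamma = 0.2,
                          dd_norm_s = 13, scale = 10) {
  if (any(c(alpha, beta, gamma) < 0) ||
      abs(alpha + beta + gamma - 1) > 1e-9)
    stop("validation error: weights must be nonnegative and sum to 1")
  if (dd_norm_s <= 0) stop("dd_norm_s must be positive")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 dd_norm_s = dd_norm_s, scale = scale),
            class = "score_weights")
}

#' The six standard weighting schemes W1-W6
#'
#' Triples are applied in the score equation's term order: first weight on
#' accuracy, second on the delay term, third on recall. (The published
#' table captions label the columns differently, but only this term order
#' reproduces the published scores from their own row values.)
#'
#' @return Named list of [score_weights()] for `W1` .. `W6`.
#' @export
#' @examples
#' weighting_schemes()$W1
weighting_schemes <- function() {
  tri <- list(W1 = c(0.4, 0.4, 0.2),
              W2 = c(0.3, 0.5, 0.2),
              W3 = c(0.25, 0.5, 0.25),
              W4 = c(0.3, 0.4, 0.3),
              W5 = c(0.2, 0.6, 0.2),
              W6 = c(0.33, 0.33, 0.34))
  lapply(tri, function(w) score_weights(w[1], w[2], w[3]))
}

#' Composite detection score
#'
#' @param acc window-level accuracy in `[0, 1]`.
#' @param mean_dd_s mean detection delay over detected seizures, seconds;
#'   `NA` (no event detected) contributes the worst delay term, 0.
#' @param recall window-level ictal sensitivity in `[0, 1]`
#'   (equivalently `1 - FN/TS`).
#' @param w a [score_weights()] (default: scheme W1).
#' @return Score on the `[0, scale]` range.
#' @export
#' @examples
#' composite_score(0.8691, 1.04, 0.8614)  # ~8.88
composite_score <- function(acc, mean_dd_s, recall, w = score_weights()) {
  if (!inherits(w, "score_weights")) stop("validation error: invalid weights")
  stopifnot(acc >= 0, acc <= 1, recall >= 0, recall <= 1)
  delay_term <- if (is.na(mean_dd_s)) 0
                else max(0, 1 - mean_dd_s / w$dd_norm_s)
  if (!is.na(mean_dd_s) && mean_dd_s < 0) stop("mean_dd_s must be >= 0")
  w$scale * (w$alpha * acc + w$beta * delay_term + w$gamma * recall)
}

#' Window-level confusion metrics
#'
#' @param pred 0/1 predictions per window.
#' @param truth 0/1 labels per window (same length; must contain at least
#'   one seizure window, otherwise recall is undefined).
#' @return List: `accuracy`, `recall` (= 1 - FN/TS), `precision` (NA when
#'   nothing is predicted positive), `fn`, `ts`.
#' @export
window_confusion <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("shape error: pred length ", length(pred), " != truth length ",
         length(truth))
  pred <- as.integer(pred); truth <- as.integer(truth)
  ts <- sum(truth == 1L)
  if (ts == 0L) stop("recall undefined: no true seizure windows")
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- ts - tp
  list(accuracy = mean(pred == truth),
       recall = 1 - fn / ts,
       precision = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
       fn = fn, ts = ts)
}

# Positive runs over a contiguous window block: returns data frame of
# run start/end times (half-open) and lengths.
positive_runs <- function(t_start, pred, window_s) {
  r <- rle(as.integer(pred))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  data.frame(t0 = t_start[starts[keep]],
             t1 = t_start[ends[keep]] + window_s,
             len = r$lengths[keep])
}

#' Detection delay of one seizure event
#'
#' The detection time is the start of the first run of at least `run_len`
#' consecutive positive windows that intersects the annotated event
#' `[onset, offset)`; the delay is clamped at 0 for runs beginning before
#' onset. The event is `undetected` when no positive window intersects it
#' at all.
#'
#' @param pred_windows data frame with `t_start_s` and `pred` for a
#'   time-contiguous block of windows covering the event span.
#' @param event one-row `seizure_annotations` entry (or a list with
#'   `onset_s`, `offset_s`).
#' @param run_len required consecutive positive windows (1 = raw alarms).
#' @param window_s window length, seconds.
#' @return List: `delay_s` (numeric, `NA` when no qualifying run),
#'   `detected` (qualifying run exists), `any_positive` (any positive
#'   window in-event; `FALSE` means undetected).
#' @export
detection_delay <- function(pred_windows, event, run_len = 2L,
                            window_s = 0.5) {
  tw <- pred_windows$t_start_s
  o <- order(tw)
  tw <- tw[o]; pv <- pred_windows$pred[o]
  onset <- event$onset_s; offset <- event$offset_s
  if (offset <= min(tw) + 1e-9 || onset >= max(tw) + window_s - 1e-9)
    stop("range error: event [", onset, ", ", offset,
         ") outside prediction span")
  in_event <- tw + window_s > onset & tw < offset
  any_pos <- any(pv[in_event] == 1L)
  runs <- positive_runs(tw, pv, window_s)
  runs <- runs[runs$len >= run_len & runs$t1 > onset & runs$t0 < offset, ,
               drop = FALSE]
  if (nrow(runs) == 0L)
    return(list(delay_s = NA_real_, detected = FALSE,
                any_positive = any_pos))
  t_det <- min(runs$t0)
  list(delay_s = max(0, t_det - onset), detected = TRUE, any_positive = TRUE)
}

#' Event-level evaluation of a prediction table
#'
#' Splits predictions into time-contiguous blocks (per patient and source
#' segment), measures each seizure's detection delay within its block,
#' counts undetected seizures (no positive window in-event), flags events
#' whose delay exceeds the 7.41 s near-real-time acceptability bound, and
#' combines everything with the window confusion metrics. Undetected
#' seizures are excluded from the mean delay (they are accounted by the
#' `undetected` count and by recall).
#'
#' @param pred data frame from [predict_packets()] (columns `t_start_s`,
#'   `pred`, `label`, `patient_id`, `segment_id`).
#' @param ann `seizure_annotations` of the evaluated events (>= 1 row).
#' @param run_len consecutive-positive-window requirement.
#' @param window_s window length, seconds.
#' @param weights optional [score_weights()]; adds the composite `score`.
#' @param dd_flag_s delay above which an event is flagged suboptimal.
#' @return An `event_metrics` list: `accuracy`, `recall`, `precision`,
#'   `mean_dd_s`, `undetected`, `n_seizures`, `dd_flags`, `per_event`,
#'   and `score` when weights were given.
#' @export
evaluate_events <- function(pred, ann, run_len = 2L, window_s = 0.5,
                            weights = score_weights(), dd_flag_s = 7.41) {
  if (nrow(ann) == 0L) stop("validation error: no events to evaluate")
  conf <- window_confusion(pred$pred, pred$label)
  per <- lapply(seq_len(nrow(ann)), function(k) {
    ev <- ann[k, ]
    blk <- pred[pred$patient_id == ev$patient_id, , drop = FALSE]
    if (!is.null(blk$segment_id) && !all(is.na(blk$segment_id))) {
      segs <- unique(blk$segment_id[
        blk$t_start_s + window_s > ev$onset_s & blk$t_start_s < ev$offset_s])
      blk <- blk[blk$segment_id %in% segs, , drop = FALSE]
    }
    if (nrow(blk) == 0L)
      return(data.frame(seizure_id = ev$seizure_id, delay_s = NA_real_,
                        detected = FALSE, any_positive = FALSE))
    d <- detection_delay(blk, ev, run_len, window_s)
    data.frame(seizure_id = ev$seizure_id, delay_s = d$delay_s,
               detected = d$detected, any_positive = d$any_positive)
  })
  per <- do.call(rbind, per)
  detected_delays <- per$delay_s[!is.na(per$delay_s)]
  mean_dd <- if (length(detected_delays)) mean(detected_delays) else NA_real_
  out <- list(
    accuracy = conf$accuracy, recall = conf$recall,
    precision = conf$precision,
    mean_dd_s = mean_dd,
    undetected = sum(!per$any_positive),
    n_seizures = nrow(ann),
    dd_flags = per$seizure_id[!is.na(per$delay_s) & per$delay_s > dd_flag_s],
    per_event = per)
  if (!is.null(weights))
    out$score <- composite_score(out$accuracy, out$mean_dd_s, out$recall,
                                 weights)
  structure(out, class = "event_metrics")
}

#' @export
print.event_metrics <- function(x, ...) {
  cat(sprintf("<event_metrics> acc %.4f | recall %.4f | mean DD %s s | undetected %d/%d%s\n",
              x$accuracy, x$recall,
              if (is.na(x$mean_dd_s)) "NA" else sprintf("%.2f", x$mean_dd_s),
              x$undetected, x$n_seizures,
              if (!is.null(x$score)) sprintf(" | score %.2f", x$score) else ""))
  if (length(x$dd_flags))
    cat("  suboptimal (> 7.41 s):", paste(x$dd_flags, collapse = ", "), "\n")
  invisible(x)
}
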