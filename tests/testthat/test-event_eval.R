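# Scoring arithmetic, confusion accounting, detection-delay semantics.

test_that("weighting schemes carry the six published triples in term order", {
  ws <- weighting_schemes()
  expect_named(ws, paste0("W", 1:6))
  expect_equal(unlist(ws$W1[c("alpha", "beta", "gamma")]),
               c(alpha = 0.4, beta = 0.4, gamma = 0.2))
  expect_equal(unlist(ws$W5[c("alpha", "beta", "gamma")]),
               c(alpha = 0.2, beta = 0.6, gamma = 0.2))
  for (w in ws) expect_equal(w$alpha + w$beta + w$gamma, 1.0)
  expect_error(score_weights(0.5, 0.5, 0.5), "sum to 1")
})

test_that("composite_score reproduces the published table rows (+/- 0.02)", {
  rows <- published_score_rows()
  got <- apply(rows, 1, function(r) composite_score(r[1], r[2], r[3]))
  expect_lt(max(abs(got - rows[, 4])), 0.02 + 1e-9)
  # perfect model pins the top of the scale under any normalized weights
  expect_equal(composite_score(1, 0, 1), 10.0)
  expect_equal(composite_score(1, 0, 1, score_weights(0.2, 0.6, 0.2)), 10.0)
})

test_that("baseline full-cohort row needs unrounded inputs (known 0.024 gap)", {
  # From the channel-reduction comparison's 19-electrode row: recomputing
  # the score from its rounded printed inputs gives 8.514 vs printed 8.49;
  # the published value was evidently computed before rounding. Asserted at
  # the observed gap so a regression in the arithmetic still fails.
  expect_equal(composite_score(0.8494, 1.523, 0.7927), 8.49,
               tolerance = 0.025 / 8.49)
})

test_that("composite_score is monotone and bounded on a grid", {
  accs <- seq(0, 1, by = 0.25)
  dds <- seq(0, 13, by = 3.25)
  recs <- seq(0, 1, by = 0.25)
  for (w in weighting_schemes()) {
    s <- outer(accs, dds, Vectorize(function(a, d)
      composite_score(a, d, 0.5, w)))
    expect_true(all(diff(s) >= 0))          # increasing in accuracy
    expect_true(all(t(diff(t(s))) <= 0))    # decreasing in delay
    r <- vapply(recs, function(x) composite_score(0.5, 5, x, w), 0)
    expect_true(all(diff(r) >= 0))
    grid <- as.matrix(expand.grid(accs, dds, recs))
    vals <- apply(grid, 1, function(g) composite_score(g[1], g[2], g[3], w))
    expect_true(all(vals >= 0 & vals <= 10 + 1e-12))
  }
  # delay term floors at 0 beyond the normalization bound
  expect_equal(composite_score(0.5, 26, 0.5),
               composite_score(0.5, 13, 0.5))
})

test_that("window_confusion matches hand counts", {
  expect_equal(window_confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))[
    c("accuracy", "recall", "fn")],
    list(accuracy = 1, recall = 1, fn = 0L))
  r <- window_confusion(c(0, 0, 0, 0), c(1, 1, 0, 0))
  expect_equal(r$accuracy, 0.5)
  expect_equal(r$recall, 0)
  expect_true(is.na(r$precision))
  r2 <- window_confusion(c(1, 0, 0, 1), c(1, 1, 0, 0))
  expect_equal(r2[c("accuracy", "recall", "precision")],
               list(accuracy = 0.5, recall = 0.5, precision = 0.5))
  expect_error(window_confusion(c(1, 0), c(1, 0, 1)), "shape error")
  expect_error(window_confusion(c(1, 0), c(0, 0)), "recall undefined")
})

test_that("detection_delay handles grid arithmetic, clamping, and misses", {
  mk <- function(pred, t0 = 0) data.frame(
    t_start_s = t0 + 0.5 * (seq_along(pred) - 1), pred = pred)
  ev <- list(onset_s = 10.30, offset_s = 20.0)
  # first qualifying run starts at t = 11.0 -> delay 0.70
  p <- mk(c(rep(0, 22), 1, 1, 1, rep(0, 20)))   # windows at 11.0, 11.5, 12.0
  d <- detection_delay(p, ev, run_len = 2)
  expect_equal(d$delay_s, 0.70)
  expect_true(d$detected)
  # run beginning before onset and spanning it clamps to 0
  p2 <- mk(c(rep(0, 18), rep(1, 8), rep(0, 20)))  # run starts at 9.0
  expect_equal(detection_delay(p2, ev, run_len = 2)$delay_s, 0)
  # no positive window inside the event -> undetected
  p3 <- mk(c(1, 1, rep(0, 43)))
  d3 <- detection_delay(p3, ev, run_len = 2)
  expect_false(d3$any_positive)
  expect_true(is.na(d3$delay_s))
  # isolated single positives fail run_len 2 but count as "any positive"
  p4 <- mk(c(rep(0, 22), 1, 0, 1, rep(0, 20)))
  d4 <- detection_delay(p4, ev, run_len = 2)
  expect_false(d4$detected)
  expect_true(d4$any_positive)
  expect_equal(detection_delay(p4, ev, run_len = 1)$delay_s, 0.70)
  # event outside the prediction span
  expect_error(detection_delay(mk(rep(0, 4)), list(onset_s = 50,
                                                   offset_s = 60), 2),
               "range error")
})

test_that("detection_delay equals the brute-force run scan on 1000 fixtures", {
  set.seed(301)
  for (i in 1:1000) {
    n <- sample(10:60, 1)
    pred <- as.integer(runif(n) < runif(1, 0.1, 0.6))
    t0 <- round(runif(1, 0, 50) * 2) / 2
    tw <- t0 + 0.5 * (seq_len(n) - 1)
    onset <- round(runif(1, t0, t0 + 0.5 * n - 1) * 100) / 100
    offset <- min(onset + round(runif(1, 1, 20) * 100) / 100,
                  t0 + 0.5 * n + 0.4)
    rl <- sample(1:3, 1)
    got <- detection_delay(data.frame(t_start_s = tw, pred = pred),
                           list(onset_s = onset, offset_s = offset), rl)
    want <- brute_delay(tw, pred, onset, offset, rl)
    expect_identical(got, want)
  }
})

test_that("evaluate_events aggregates delays, misses, and flags", {
  ann <- as_seizure_annotations(data.frame(
    patient_id = "p", seizure_id = c("a", "b"),
    onset_s = c(10, 200), offset_s = c(20, 212)))
  mkblock <- function(t0, pred, seg) data.frame(
    t_start_s = t0 + 0.5 * (seq_along(pred) - 1), pred = pred,
    label = as.integer(seq_along(pred) > 2), segment_id = seg,
    patient_id = "p")
  # seizure a: detected 1.0 s after onset; seizure b: never positive
  blk_a <- mkblock(10, c(0, 0, rep(1, 18)), "a_ictal")
  blk_b <- mkblock(200, rep(0, 24), "b_ictal")
  m <- evaluate_events(rbind(blk_a, blk_b), ann, run_len = 2)
  expect_equal(m$mean_dd_s, 1.0)
  expect_equal(m$undetected, 1L)
  expect_equal(m$n_seizures, 2L)
  expect_length(m$dd_flags, 0L)
  # ideal: every event detected at onset
  ideal_a <- mkblock(10, rep(1, 20), "a_ictal")
  ideal_b <- mkblock(200, rep(1, 24), "b_ictal")
  mi <- evaluate_events(rbind(ideal_a, ideal_b), ann, run_len = 2)
  expect_equal(mi$mean_dd_s, 0)
  expect_equal(mi$undetected, 0L)
  # a delay beyond 7.41 s is flagged suboptimal
  late <- mkblock(10, c(rep(0, 16), rep(1, 4)), "a_ictal")  # detect at 18.0
  ml <- evaluate_events(rbind(late, ideal_b), ann, run_len = 2)
  expect_equal(ml$per_event$delay_s[1], 8.0)
  expect_equal(ml$dd_flags, "a")
  expect_error(evaluate_events(blk_a, ann[0, ], run_len = 2),
               "no events")
})
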