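# Windowing, mean channel, wavelet features, balancing, packetization.

test_that("wavelet band agrees with the naive double-loop oracle", {
  f <- seizewin:::wavelet_filters("db4")
  set.seed(31)
  for (n in c(16, 128, 101)) {
    x <- rnorm(n)
    d <- dwt_level1(x, "db4")
    expect_equal(d$approx, naive_dwt_band(x, f$dec_lo), tolerance = 1e-12)
    expect_equal(d$detail, naive_dwt_band(x, f$dec_hi), tolerance = 1e-12)
    expect_length(d$approx, (n + 8 - 1) %/% 2)
  }
})

test_that("wavelet_features has the canonical length and limit behavior", {
  cfg <- frame_config()
  expect_length(wavelet_features(rnorm(128), cfg), 134)
  expect_equal(wavelet_features(numeric(128), cfg), numeric(134))
  # constant input: all 67 detail coefficients vanish, approx = c * sqrt(2)
  w <- wavelet_features(rep(3, 128), cfg)
  expect_lt(max(abs(w[68:134])), 1e-9)
  expect_equal(w[1:67], rep(3 * sqrt(2), 67), tolerance = 1e-12)
  expect_error(wavelet_features(rnorm(64), cfg), "shape error")
  # linearity
  set.seed(5)
  x <- rnorm(128); y <- rnorm(128)
  expect_equal(wavelet_features(2 * x - 3 * y, cfg),
               2 * wavelet_features(x, cfg) - 3 * wavelet_features(y, cfg),
               tolerance = 1e-10)
})

test_that("windowing partitions the retained samples exactly", {
  rec <- eeg_recording(matrix(seq_len(2 * 600 * 128), 2, 600 * 128),
                       c("C3", "C4"), 256)
  w <- window_signal(rec, NULL, frame_config())
  expect_length(w, 600)                       # 300 s -> 600 windows
  expect_equal(w[[5]]$t_start_s, 4 * 0.5)     # window k starts at 0.5k
  # partition: concatenating windows reproduces the signal prefix
  expect_equal(unname(do.call(cbind, lapply(w, `[[`, "x"))),
               unname(rec$data))
  # too-short input and trailing partial window
  short <- eeg_recording(matrix(rnorm(2 * 100), 2, 100), c("C3", "C4"), 256)
  expect_length(window_signal(short, NULL, frame_config()), 0L)
  odd <- eeg_recording(matrix(rnorm(2 * 300), 2, 300), c("C3", "C4"), 256)
  expect_length(window_signal(odd, NULL, frame_config()), 2L)
  expect_error(window_signal(eeg_recording(matrix(1:8, 2), c("A1", "A2"), 128),
                             NULL, frame_config()), "configuration error")
})

test_that("mean_channel is the unweighted per-sample mean", {
  x <- rnorm(16)
  expect_equal(mean_channel(rbind(x, x, x)), x)
  expect_equal(mean_channel(rbind(x, -x)), numeric(16))
  expect_equal(mean_channel(cbind(c(1, 2, 6)))[1], 3.0)
})

test_that("frame dimension is C + 135 for all studied montages", {
  cfg <- frame_config()
  for (C in c(4, 5, 6, 15, 19)) {
    rec <- eeg_recording(matrix(rnorm(C * 256), C, 256),
                         standard_montage_19()[seq_len(C)], 256)
    fr <- assemble_frames(window_signal(rec, NULL, cfg), cfg)
    expect_equal(ncol(fr$window_features), C + 135L)
  }
})

test_that("window labels follow the label_rule threshold", {
  cfg <- frame_config()
  rec <- eeg_recording(matrix(rnorm(2 * 256), 2, 256), c("F3", "F4"), 256)
  lab <- c(rep(0L, 128), rep(1L, 60), rep(0L, 68))   # window 2: 47% ictal
  fr <- assemble_frames(window_signal(rec, lab, cfg), cfg)
  expect_equal(fr$labels, c(0L, 0L))
  lab2 <- c(rep(0L, 128), rep(1L, 64), rep(0L, 64))  # exactly 50%
  fr2 <- assemble_frames(window_signal(rec, lab2, cfg), cfg)
  expect_equal(fr2$labels, c(0L, 1L))
})

test_that("sample sequences carry a constant wavelet block per window", {
  cfg <- frame_config()
  rec <- eeg_recording(matrix(rnorm(3 * 256), 3, 256), c("F3", "FZ", "F4"),
                       256)
  fr <- assemble_frames(window_signal(rec, NULL, cfg), cfg,
                        store_samples = TRUE)
  expect_equal(dim(fr$sample_features), c(256L, 3L + 1L + 134L))
  wavblock <- fr$sample_features[1:128, 5:138]
  expect_true(all(apply(wavblock, 2, function(col) all(col == col[1]))))
  # raw sample values retained verbatim
  expect_equal(fr$sample_features[1:128, 1], unname(rec$data[1, 1:128]))
  expect_equal(fr$sample_features[, 4],
               unname(colMeans(rec$data[, 1:256]))[1:256])
})

test_that("balancing pairs each seizure with an equal interictal segment", {
  e <- tiny_cohort()[[1]]
  rec <- e$recording; ann <- e$annotations
  segs <- balance_segments(rec, ann, buffer_s = 30, seed = 5)
  expect_equal(sum(segs$kind == "ictal"), nrow(ann))
  expect_equal(sum(segs$kind == "interictal"), nrow(ann))
  for (sid in ann$seizure_id) {
    pair <- segs[segs$seizure_id == sid, ]
    expect_equal(diff(pair$t1 - pair$t0), 0, tolerance = 1e-9)
  }
  # interictal segments avoid all seizures +/- buffer and each other
  inter <- segs[segs$kind == "interictal", ]
  for (i in seq_len(nrow(inter))) {
    for (k in seq_len(nrow(ann)))
      expect_true(inter$t1[i] <= ann$onset_s[k] - 30 + 1e-9 ||
                    inter$t0[i] >= ann$offset_s[k] + 30 - 1e-9)
    for (j in seq_len(nrow(inter))) if (j != i)
      expect_true(inter$t1[i] <= inter$t0[j] + 1e-9 ||
                    inter$t0[i] >= inter$t1[j] - 1e-9)
  }
  # determinism
  expect_identical(segs, balance_segments(rec, ann, buffer_s = 30, seed = 5))
  # infeasible: recording shorter than twice the seizure
  small <- eeg_recording(rec$data[, 1:(80 * 256)], rec$channel_labels, 256,
                         rec$patient_id)
  long_ann <- as_seizure_annotations(data.frame(
    patient_id = rec$patient_id, seizure_id = "big", onset_s = 10,
    offset_s = 60))
  expect_error(balance_segments(small, long_ann, buffer_s = 30, seed = 1),
               "balancing error.*big")
})

test_that("balanced windows have equal class counts within one window", {
  pks <- tiny_packets()
  y <- unlist(lapply(pks, `[[`, "y"))
  # conservation per recording: here aggregated over the two patients
  expect_lt(abs(sum(y == 1) - sum(y == 0)), 2 * 2 + 1)
  # per-seizure pairing is exact up to one window
  seg <- unlist(lapply(pks, `[[`, "segment_id"))
  for (s in unique(sub("_(ictal|interictal)$", "", seg))) {
    n_ict <- sum(seg == paste0(s, "_ictal"))
    n_int <- sum(seg == paste0(s, "_interictal"))
    expect_lte(abs(n_ict - n_int), 1L)
  }
})

test_that("packetize cuts 600-frame packets and flags the partial tail", {
  cfg <- frame_config()
  mk_fs <- function(n, t0) {
    rec <- eeg_recording(matrix(rnorm(n * 128), 1, n * 128), "CZ", 256)
    assemble_frames(window_signal(rec, NULL, cfg, t_offset_s = t0), cfg)
  }
  pks <- packetize(list(mk_fs(900, 0), mk_fs(600, 1000)), cfg)
  expect_length(pks, 3L)
  expect_equal(vapply(pks, function(p) nrow(p$X), 0L), c(600L, 600L, 300L))
  expect_equal(vapply(pks, `[[`, TRUE, "partial"), c(FALSE, FALSE, TRUE))
  # exact fit -> one full packet
  one <- packetize(list(mk_fs(600, 0)), cfg)
  expect_length(one, 1L)
  expect_false(one[[1]]$partial)
  # timestamps non-decreasing within each source segment
  for (p in pks)
    for (s in unique(p$segment_id))
      expect_true(all(diff(p$t_start_s[p$segment_id %in% s]) >= 0))
})
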