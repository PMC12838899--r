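# End-to-end experiment orchestration: architecture sweeps, reduction
# sweeps, Monte Carlo repeats, report tables.

#' Experiment configuration
#'
#' @param synth a [synth_config()] used to generate the cohort, or NULL if
#'   `cohort` is passed to the runner directly.
#' @param frame a [frame_config()].
#' @param hidden_grid list of hidden-size vectors to sweep.
#' @param lr_grid learning rates to sweep (crossed with `hidden_grid`).
#' @param epochs training epochs per run.
#' @param combos names of [builtin_combos()] entries (or `channel_combo`
#'   objects) for reduction experiments; NULL = all five plus the full
#'   montage baseline.
#' @param channels montage for non-reduction runs.
#' @param weight_scheme one of `"W1"`..`"W6"`.
#' @param k Monte Carlo repeats.
#' @param ratio train fraction at seizure level.
#' @param run_len consecutive-positive-window detection requirement.
#' @param seed master seed (cohort, splits, training).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(synth = synth_config(), frame = frame_config(),
                              hidden_grid = list(32), lr_grid = 0.01,
                              epochs = 10L, combos = NULL,
                              channels = standard_montage_19(),
                              weight_scheme = "W1", k = 5L, ratio = 0.7,
                              run_len = 2L, seed = 1L) {
  if (length(hidden_grid) == 0L || length(lr_grid) == 0L)
    stop("hyperparameter grid must be non-empty")
  if (!weight_scheme %in% names(weighting_schemes()))
    stop("unknown weight scheme: ", weight_scheme)
  structure(list(synth = synth, frame = frame, hidden_grid = hidden_grid,
                 lr_grid = lr_grid, epochs = as.integer(epochs),
                 combos = combos, channels = toupper(channels),
                 weight_scheme = weight_scheme, k = as.integer(k),
                 ratio = ratio, run_len = as.integer(run_len),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# One split -> train -> evaluate run on a given montage. Packets are built
# per patient (train and held-out seizures separately) so the training
# stream never contains test-seizure frames.
run_detection_run <- function(cohort, ann, channels, fcfg, mcfg, split,
                              run_len, weights, store_samples = FALSE) {
  train_pk <- list(); test_pk <- list()
  for (e in cohort) {
    pid <- e$recording$patient_id
    mine <- ann$seizure_id[ann$patient_id == pid]
    tr <- intersect(mine, split$train)
    te <- intersect(mine, split$test)
    if (length(tr))
      train_pk <- c(train_pk, build_packets(
        e$recording, ann, fcfg, seizure_ids = tr, channels = channels,
        seed = mcfg$seed, store_samples = store_samples))
    if (length(te))
      test_pk <- c(test_pk, build_packets(
        e$recording, ann, fcfg, seizure_ids = te, channels = channels,
        seed = derive_seed(mcfg$seed, 1), store_samples = store_samples))
  }
  model <- train_model(train_pk, mcfg)
  pred <- predict_packets(model, test_pk)
  test_ann <- ann[ann$seizure_id %in% split$test, , drop = FALSE]
  metrics <- evaluate_events(pred, test_ann, run_len = run_len,
                             window_s = fcfg$window_s, weights = weights)
  list(model = model, pred = pred, metrics = metrics,
       train_packets = train_pk, test_packets = test_pk)
}

aggregate_runs <- function(metrics_list, weights) {
  acc <- vapply(metrics_list, `[[`, 0, "accuracy")
  rec <- vapply(metrics_list, `[[`, 0, "recall")
  dd <- vapply(metrics_list, `[[`, 0, "mean_dd_s")
  und <- vapply(metrics_list, `[[`, 0L, "undetected")
  sd0 <- function(x) if (length(x) > 1L) sd(x, na.rm = TRUE) else 0
  mean_dd <- mean(dd, na.rm = TRUE)
  list(acc_mean = mean(acc), acc_sd = sd0(acc),
       undetected = sum(und),
       dd_mean = if (is.nan(mean_dd)) NA_real_ else mean_dd,
       dd_sd = sd0(dd),
       recall_mean = mean(rec), recall_sd = sd0(rec),
       score = composite_score(mean(acc),
                               if (is.nan(mean_dd)) NA_real_ else mean_dd,
                               mean(rec), weights))
}

#' Run an architecture/learning-rate sweep with Monte Carlo repeats
#'
#' For every grid cell (hidden sizes x learning rate) and every Monte
#' Carlo repeat: split at seizure level, train, evaluate on held-out
#' seizures. The same `k` splits are shared across grid cells so cells are
#' comparable. Each report row's `score` is the composite score of that
#' row's own mean accuracy/delay/recall (self-consistent by construction).
#'
#' @param cfg an [experiment_config()].
#' @param cohort optional pre-generated `synth_cohort` (default: generate
#'   from `cfg$synth`).
#' @return Data frame, one row per grid cell: `hidden`, `lr`, `acc_mean`,
#'   `acc_sd`, `undetected` (summed over repeats), `dd_mean`, `dd_sd`,
#'   `recall_mean`, `recall_sd`, `score`; per-repeat metrics in
#'   `attr(, "runs")`.
#' @export
run_experiment <- function(cfg = experiment_config(), cohort = NULL) {
  cohort <- cohort %||% generate_cohort(cfg$synth)
  ann <- cohort_annotations(cohort)
  weights <- weighting_schemes()[[cfg$weight_scheme]]
  plan <- monte_carlo_splits(ann, k = cfg$k, ratio = cfg$ratio,
                             seed = cfg$seed)
  rows <- list(); runs <- list()
  for (hid in cfg$hidden_grid) {
    for (lr in cfg$lr_grid) {
      mets <- vector("list", cfg$k)
      for (r in seq_len(cfg$k)) {
        mcfg <- model_config(hidden_sizes = hid, learning_rate = lr,
                             epochs = cfg$epochs,
                             seed = derive_seed(cfg$seed, 100 + r))
        mets[[r]] <- run_detection_run(
          cohort, ann, cfg$channels, cfg$frame, mcfg, plan$repeats[[r]],
          cfg$run_len, weights)$metrics
      }
      agg <- aggregate_runs(mets, weights)
      key <- paste0(paste(hid, collapse = "+"), "h_lr", lr)
      runs[[key]] <- mets
      rows[[key]] <- data.frame(hidden = paste(hid, collapse = "+"),
                                lr = lr, as.data.frame(agg),
                                stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "runs") <- runs
  attr(out, "config") <- cfg
  out
}

#' Run the electrode-reduction sweep
#'
#' One row per channel combination (the five built-ins plus the full
#' 19-channel baseline by default), evaluated with `cfg$k` Monte Carlo
#' repeats each and sorted by descending score. The `total_features`
#' column is `n_electrodes + 135`.
#'
#' @inheritParams run_experiment
#' @return Data frame with columns `set`, `inputs`, `total_features` and
#'   the aggregate metric columns of [run_experiment()].
#' @export
run_reduction_experiment <- function(cfg = experiment_config(),
                                     cohort = NULL) {
  cohort <- cohort %||% generate_cohort(cfg$synth)
  ann <- cohort_annotations(cohort)
  weights <- weighting_schemes()[[cfg$weight_scheme]]
  plan <- monte_carlo_splits(ann, k = cfg$k, ratio = cfg$ratio,
                             seed = cfg$seed)
  combos <- cfg$combos
  if (is.null(combos)) {
    combos <- builtin_combos()
    combos[["Full 19"]] <- structure(
      list(name = "Full 19", electrodes = standard_montage_19(),
           selection_method = "manual"), class = "channel_combo")
  } else if (is.character(combos)) {
    combos <- builtin_combos()[combos]
    if (any(vapply(combos, is.null, TRUE))) stop("unknown combo name")
  }
  nwav <- n_wavelet_features(cfg$frame)
  rows <- list()
  for (cb in combos) {
    mets <- vector("list", cfg$k)
    for (r in seq_len(cfg$k)) {
      mcfg <- model_config(hidden_sizes = cfg$hidden_grid[[1L]],
                           learning_rate = cfg$lr_grid[1L],
                           epochs = cfg$epochs,
                           seed = derive_seed(cfg$seed, 100 + r))
      mets[[r]] <- run_detection_run(
        cohort, ann, cb$electrodes, cfg$frame, mcfg, plan$repeats[[r]],
        cfg$run_len, weights)$metrics
    }
    agg <- aggregate_runs(mets, weights)
    rows[[cb$name]] <- data.frame(
      set = cb$name,
      inputs = sprintf("Raw EEG (%d) + mean + wavelet",
                       length(cb$electrodes)),
      total_features = length(cb$electrodes) + 1L + nwav,
      as.data.frame(agg), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "config") <- cfg
  out
}
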