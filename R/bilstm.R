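# BiLSTM sequence classifier: training protocol, prediction, seizure-level
# Monte Carlo splitting and outlier-aware retraining.

#' BiLSTM model configuration
#'
#' @param hidden_sizes hidden units per stacked bidirectional layer, e.g.
#'   `c(200)` or `c(200, 100)`.
#' @param learning_rate Adam step size; the swept values in the reference
#'   protocol are 0.1, 0.01, 0.001, 0.0001.
#' @param epochs passes over the training packets.
#' @param batch packets (sequences) accumulated per parameter update.
#' @param granularity `"window"` feeds one feature frame per time step;
#'   `"sample"` feeds the 256 Hz per-sample rows, backpropagated in
#'   `chunk_s`-second 0.5 s-aligned chunks.
#' @param chunk_s truncation length for sample-granularity sequences,
#'   seconds (must be a multiple of the window length).
#' @param clip global gradient-norm clip.
#' @param outlier_duplication how many times packets containing outlier
#'   seizures appear in the retraining stream.
#' @param seed RNG seed for initialization and epoch shuffling.
#' @return A list of class `model_config`.
#' @export
model_config <- function(hidden_sizes = c(32), learning_rate = 0.01,
                         epochs = 10L, batch = 1L,
                         granularity = c("window", "sample"),
                         chunk_s = 10, clip = 5,
                         outlier_duplication = 3L, seed = 1L) {
  granularity <- match.arg(granularity)
  if (length(hidden_sizes) == 0L || any(hidden_sizes < 1))
    stop("hidden_sizes must be non-empty with all entries >= 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch = as.integer(batch), granularity = granularity,
                 chunk_s = chunk_s, clip = clip,
                 outlier_duplication = as.integer(outlier_duplication),
                 seed = as.integer(seed)),
            class = "model_config")
}

# Flat parameter vector layout must mirror src/bilstm.cpp exactly.
init_theta <- function(feature_dim, hidden, seed) {
  with_seed(seed, {
    theta <- numeric(0)
    D <- feature_dim
    for (H in hidden) {
      for (d in 1:2) {
        W <- matrix(rnorm(4 * H * D, sd = 1 / sqrt(D)), 4 * H, D)
        U <- matrix(rnorm(4 * H * H, sd = 1 / sqrt(H)), 4 * H, H)
        b <- c(rep(0, H), rep(1, H), rep(0, 2 * H))  # forget bias 1
        theta <- c(theta, as.numeric(W), as.numeric(U), b)
      }
      D <- 2L * H
    }
    HL <- hidden[length(hidden)]
    theta <- c(theta, rnorm(2 * 2 * HL, sd = 1 / sqrt(2 * HL)), c(0, 0))
    theta
  })
}

unpack_theta <- function(theta, feature_dim, hidden) {
  off <- 0L
  take <- function(n) {
    v <- theta[(off + 1L):(off + n)]
    off <<- off + as.integer(n)
    v
  }
  D <- feature_dim
  layers <- vector("list", length(hidden))
  for (l in seq_along(hidden)) {
    H <- hidden[l]
    dirs <- lapply(1:2, function(d)
      list(W = matrix(take(4 * H * D), 4 * H, D),
           U = matrix(take(4 * H * H), 4 * H, H),
           b = take(4 * H)))
    layers[[l]] <- dirs
    D <- 2L * H
  }
  HL <- hidden[length(hidden)]
  list(layers = layers, Wo = matrix(take(4 * HL), 2, 2 * HL), bo = take(2))
}

# Extract training sequences (X, y pairs) from packets at the configured
# granularity. Sample-granularity packets are cut into chunk_s chunks.
packet_sequences <- function(packets, cfg) {
  if (cfg$granularity == "window") {
    return(lapply(packets, function(p) list(X = p$X, y = p$y)))
  }
  out <- list()
  for (p in packets) {
    if (is.null(p$sample_X))
      stop("sample-granularity training requires packets built with ",
           "store_samples = TRUE")
    fcfg <- p$cfg
    rows_per_chunk <- round(cfg$chunk_s * fcfg$fs)
    wlen <- round(fcfg$window_s * fcfg$fs)
    if (rows_per_chunk %% wlen != 0)
      stop("chunk_s must be a multiple of the window length")
    n <- nrow(p$sample_X)
    starts <- seq(1L, n, by = rows_per_chunk)
    for (s in starts) {
      e <- min(s + rows_per_chunk - 1L, n)
      out[[length(out) + 1L]] <-
        list(X = p$sample_X[s:e, , drop = FALSE], y = p$sample_y[s:e])
    }
  }
  out
}

adam_run <- function(theta, seqs, cfg, input_dim, epochs, seed,
                     state = NULL) {
  lr <- cfg$learning_rate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  m <- state$m %||% numeric(length(theta))
  v <- state$v %||% numeric(length(theta))
  step <- state$step %||% 0L
  log_ <- numeric(0)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, ep), sample(seq_along(seqs)))
    ep_loss <- 0
    gacc <- numeric(length(theta)); nacc <- 0L
    for (j in seq_along(ord)) {
      sq <- seqs[[ord[j]]]
      lg <- cpp_bilstm_loss_grad(theta, input_dim, cfg$hidden_sizes,
                                 sq$X, as.integer(sq$y))
      ep_loss <- ep_loss + lg$loss
      gacc <- gacc + lg$grad; nacc <- nacc + 1L
      if (nacc >= cfg$batch || j == length(ord)) {
        g <- gacc / nacc
        gn <- sqrt(sum(g^2))
        if (is.finite(gn) && gn > cfg$clip) g <- g * (cfg$clip / gn)
        step <- step + 1L
        m <- b1 * m + (1 - b1) * g
        v <- b2 * v + (1 - b2) * g^2
        mh <- m / (1 - b1^step)
        vh <- v / (1 - b2^step)
        theta <- theta - lr * mh / (sqrt(vh) + eps)
        gacc[] <- 0; nacc <- 0L
      }
    }
    log_ <- c(log_, ep_loss / length(seqs))
  }
  list(theta = theta, training_log = log_,
       state = list(m = m, v = v, step = step))
}

#' Train a BiLSTM seizure classifier on feature packets
#'
#' One bidirectional recurrent layer pair per entry of
#' `cfg$hidden_sizes`, followed by an affine projection to two classes per
#' time step, trained with per-step softmax cross-entropy and Adam (the
#' learning rate is the controlled hyperparameter). Deterministic given
#' `cfg$seed`.
#'
#' @param packets list of `eeg_packet` (from [build_packets()] /
#'   [packetize()]); all must share one feature dimension and jointly
#'   contain both classes.
#' @param cfg a [model_config()].
#' @return A `bilstm_model`: config, flat parameter vector, feature
#'   dimension, per-epoch mean loss, and the training-split provenance
#'   (patients and seizure ids seen).
#' @export
train_model <- function(packets, cfg = model_config()) {
  if (length(packets) == 0L) stop("no training packets")
  dims <- vapply(packets, function(p) ncol(p$X), 0L)
  if (length(unique(dims)) != 1L)
    stop("shape error: packets disagree on feature dimension: ",
         paste(unique(dims), collapse = ", "))
  seqs <- packet_sequences(packets, cfg)
  ally <- unlist(lapply(seqs, `[[`, "y"), use.names = FALSE)
  if (length(unique(ally)) < 2L)
    stop("training error: training set contains a single class")
  input_dim <- unname(if (cfg$granularity == "window") dims[1L]
                      else ncol(seqs[[1L]]$X))
  theta <- init_theta(input_dim, cfg$hidden_sizes, derive_seed(cfg$seed, 0))
  fit <- adam_run(theta, seqs, cfg, input_dim, cfg$epochs, cfg$seed)
  structure(list(
    config = cfg, theta = fit$theta, feature_dim = input_dim,
    training_log = fit$training_log, opt_state = fit$state,
    train_seizure_ids = sort(unique(stats::na.omit(unlist(
      lapply(packets, `[[`, "seizure_id"))))),
    train_patient_ids = sort(unique(stats::na.omit(unlist(
      lapply(packets, `[[`, "patient_id")))))),
    class = "bilstm_model")
}

#' @export
print.bilstm_model <- function(x, ...) {
  cat(sprintf("<bilstm_model> hidden [%s], %d features, %s granularity, %d epochs (final loss %.4f)\n",
              paste(x$config$hidden_sizes, collapse = ","), x$feature_dim,
              x$config$granularity, length(x$training_log),
              tail(x$training_log, 1)))
  invisible(x)
}

#' Predict per-window seizure decisions for one packet
#'
#' At window granularity each frame is one time step. At sample granularity
#' per-sample decisions are made first and the window decision is the
#' strict majority vote over its samples. `mode = "causal"` restricts the
#' backward recurrent direction to the current time step so that decisions
#' use no future input (the streaming semantics); `"bidirectional"` is the
#' offline default.
#'
#' @param model a `bilstm_model`.
#' @param packet an `eeg_packet` with matching feature dimension.
#' @param mode `"bidirectional"` or `"causal"`.
#' @return Data frame with one row per window: `t_start_s`, `score`
#'   (class-1 probability, averaged over samples at sample granularity),
#'   `pred` (0/1), `label`, `seizure_id`, `segment_id`, `patient_id`.
#' @export
predict_frames <- function(model, packet,
                           mode = c("bidirectional", "causal")) {
  mode <- match.arg(mode)
  cfg <- model$config
  causal <- mode == "causal"
  if (cfg$granularity == "window") {
    if (ncol(packet$X) != model$feature_dim)
      stop("shape error: packet has ", ncol(packet$X),
           " features, model expects ", model$feature_dim)
    pr <- cpp_bilstm_forward(model$theta, model$feature_dim,
                             cfg$hidden_sizes, packet$X, causal)
    score <- pr[, 2L]
    pred <- as.integer(score >= 0.5)
  } else {
    if (is.null(packet$sample_X))
      stop("sample-granularity model needs packets with store_samples = TRUE")
    if (ncol(packet$sample_X) != model$feature_dim)
      stop("shape error: packet has ", ncol(packet$sample_X),
           " features, model expects ", model$feature_dim)
    fcfg <- packet$cfg
    wlen <- round(fcfg$window_s * fcfg$fs)
    rows_per_chunk <- round(cfg$chunk_s * fcfg$fs)
    n <- nrow(packet$sample_X)
    sc <- numeric(n)
    for (s in seq(1L, n, by = rows_per_chunk)) {
      e <- min(s + rows_per_chunk - 1L, n)
      pr <- cpp_bilstm_forward(model$theta, model$feature_dim,
                               cfg$hidden_sizes,
                               packet$sample_X[s:e, , drop = FALSE], causal)
      sc[s:e] <- pr[, 2L]
    }
    nw <- length(packet$y)
    score <- numeric(nw); pred <- integer(nw)
    for (k in seq_len(nw)) {
      rows <- ((k - 1L) * wlen + 1L):(k * wlen)
      votes <- sum(sc[rows] >= 0.5)
      pred[k] <- as.integer(votes > wlen / 2)   # strict majority
      score[k] <- mean(sc[rows])
    }
  }
  data.frame(t_start_s = packet$t_start_s, score = score, pred = pred,
             label = packet$y, seizure_id = packet$seizure_id,
             segment_id = packet$segment_id, patient_id = packet$patient_id,
             stringsAsFactors = FALSE)
}

#' Predict over a list of packets
#' @inheritParams predict_frames
#' @param packets list of `eeg_packet`.
#' @return Row-bound prediction data frame (see [predict_frames()]).
#' @export
predict_packets <- function(model, packets,
                            mode = c("bidirectional", "causal")) {
  mode <- match.arg(mode)
  do.call(rbind, lapply(packets, predict_frames, model = model, mode = mode))
}

#' Seizure-level Monte Carlo train/test splits
#'
#' Each repeat shuffles all seizures and assigns `ratio` of them to the
#' training set, then repairs the assignment so every patient keeps at
#' least one training seizure (a patient with a single seizure therefore
#' always trains on it). Deterministic given `seed`.
#'
#' @param ann pooled `seizure_annotations` over the cohort.
#' @param k number of repeats.
#' @param ratio fraction of seizures assigned to training before repair.
#' @param seed integer seed.
#' @return A `split_plan`: list of `k` elements, each
#'   `list(train, test)` of seizure-id character vectors.
#' @export
monte_carlo_splits <- function(ann, k = 5L, ratio = 0.7, seed = 1L) {
  ids <- ann$seizure_id
  pat <- ann$patient_id
  if (anyDuplicated(ids)) stop("seizure ids must be unique across the cohort")
  counts <- table(pat)
  if (any(counts < 1L)) stop("validation error: patient with 0 seizures")
  reps <- lapply(seq_len(k), function(r) {
    with_seed(derive_seed(seed, r), {
      perm <- sample(ids)
      n_train <- round(ratio * length(ids))
      train <- perm[seq_len(n_train)]
      test <- setdiff(perm, train)
      # repair: every patient contributes >= 1 training seizure
      for (p in unique(pat)) {
        mine <- ids[pat == p]
        if (!any(mine %in% train)) {
          promote <- test[test %in% mine][1L]
          train <- c(train, promote)
          test <- setdiff(test, promote)
        }
      }
      list(train = sort(train), test = sort(test))
    })
  })
  structure(list(repeats = reps, k = k, ratio = ratio, seed = seed),
            class = "split_plan")
}

#' Find training seizures the model never detects
#'
#' A training seizure is an outlier when no positive-predicted window falls
#' inside its annotated interval — seizure-level misses, not sample-level
#' errors.
#'
#' @param model a `bilstm_model`.
#' @param train_packets training packets carrying seizure provenance.
#' @return Character vector of missed seizure ids (possibly empty).
#' @export
find_outlier_seizures <- function(model, train_packets) {
  missed_seizures(predict_packets(model, train_packets))
}

# Seizure ids with zero positive-predicted windows among their ictal frames.
missed_seizures <- function(pred) {
  ict <- pred[!is.na(pred$seizure_id), , drop = FALSE]
  ids <- unique(ict$seizure_id)
  ids[vapply(ids, function(s)
    !any(ict$pred[ict$seizure_id == s] == 1L), TRUE)]
}

#' Retrain with outlier seizures re-emphasized
#'
#' Continues training from the current weights with every packet that
#' contains an outlier seizure duplicated (`cfg$outlier_duplication` copies
#' in the stream). Test data can never enter: any outlier id that is not
#' part of the model's training provenance is rejected.
#'
#' @param model a `bilstm_model`.
#' @param train_packets the training-split packets (same split the model
#'   was trained on).
#' @param outliers seizure ids from [find_outlier_seizures()].
#' @param cfg optional [model_config()] for the retraining phase (defaults
#'   to the model's own config).
#' @return A refreshed `bilstm_model`.
#' @export
retrain_with_outliers <- function(model, train_packets, outliers,
                                  cfg = NULL) {
  cfg <- cfg %||% model$config
  bad <- setdiff(outliers, model$train_seizure_ids)
  if (length(bad))
    stop("validation error: outlier ids not in the training split ",
         "(test-leakage guard): ", paste(bad, collapse = ", "))
  stream <- train_packets
  if (length(outliers)) {
    extra <- Filter(function(p)
      any(p$seizure_id %in% outliers), train_packets)
    for (i in seq_len(cfg$outlier_duplication - 1L))
      stream <- c(stream, extra)
  }
  seqs <- packet_sequences(stream, cfg)
  fit <- adam_run(model$theta, seqs, cfg, model$feature_dim, cfg$epochs,
                  derive_seed(cfg$seed, 9999), state = model$opt_state)
  out <- model
  out$theta <- fit$theta
  out$training_log <- c(model$training_log, fit$training_log)
  out$opt_state <- fit$state
  out
}
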