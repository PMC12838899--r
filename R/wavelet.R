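# Single-level discrete wavelet transform used for frame augmentation.
#
# The frame feature block is the level-1 DWT of the 0.5 s mean-channel
# window: approximation (low-pass) coefficients followed by detail
# (high-pass) coefficients, computed with symmetric boundary extension and
# full-length convolution. For a 128-sample window and the 8-tap db4 filter
# this yields 2 * floor((128 + 8 - 1) / 2) = 134 coefficients — the only
# low-complexity configuration consistent with the per-frame feature totals
# the pipeline is built around (C + 1 + 134).

# Daubechies scaling (reconstruction low-pass) filters, increasing index.
.WAVELET_SCALING <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.48296291314469025, 0.8365163037378079,
          0.2241438680420134, -0.12940952255092145),
  db4 = c(0.23037781330885523, 0.7148465705525415,
          0.6308807679295904, -0.02798376941698385,
          -0.18703481171888114, 0.030841381835986965,
          0.032883011666982945, -0.010597401784997278)
)

wavelet_filters <- function(name) {
  h <- .WAVELET_SCALING[[tolower(name)]]
  if (is.null(h)) stop("unknown wavelet: ", name, " (available: ",
                       paste(names(.WAVELET_SCALING), collapse = ", "), ")")
  L <- length(h)
  dec_lo <- rev(h)
  dec_hi <- (-1)^(seq_len(L)) * h           # quadrature mirror of dec_lo
  list(dec_lo = dec_lo, dec_hi = dec_hi, length = L)
}

symmetric_extend <- function(x, k) {
  n <- length(x)
  if (k > n) stop("extension longer than signal")
  c(rev(x[seq_len(k)]), x, rev(x)[seq_len(k)])
}

# Correlation of the symmetrically extended signal with one filter,
# downsampled at even output positions.
dwt_band <- function(x, filt) {
  L <- length(filt)
  ext <- symmetric_extend(x, L - 1L)
  E <- stats::embed(ext, L)                 # row i = ext[i+L-1], ..., ext[i]
  y <- as.numeric(E %*% rev(filt))          # y[i] = sum_j filt[j] ext[i+j-1]
  y[seq(2L, length(y), by = 2L)]
}

#' Single-level DWT coefficient pair
#'
#' @param x numeric signal vector.
#' @param wavelet filter name (`"db4"`, `"db2"`, `"haar"`).
#' @return List with `approx` and `detail` coefficient vectors, each of
#'   length `floor((length(x) + filter_length - 1) / 2)`.
#' @export
dwt_level1 <- function(x, wavelet = "db4") {
  f <- wavelet_filters(wavelet)
  list(approx = dwt_band(x, f$dec_lo), detail = dwt_band(x, f$dec_hi))
}

#' Wavelet feature vector of one frame
#'
#' Decomposes a fixed-length window (the mean channel of one 0.5 s frame)
#' and concatenates approximation then detail coefficients. At the defaults
#' (128 samples, db4, level 1) the result has exactly 134 values. Levels
#' above 1 cascade on the approximation band and concatenate the final
#' approximation with all detail bands, coarsest first.
#'
#' @param x numeric vector of length `window_s * fs` (128 at defaults).
#' @param cfg a [frame_config()].
#' @return Numeric feature vector; length 134 under default configuration.
#' @export
#' @examples
#' length(wavelet_features(rnorm(128), frame_config()))  # 134
wavelet_features <- function(x, cfg = frame_config()) {
  wlen <- round(cfg$window_s * cfg$fs)
  if (length(x) != wlen)
    stop("shape error: expected ", wlen, "-sample window, got ", length(x))
  approx <- x
  details <- list()
  for (lev in seq_len(cfg$wavelet_level)) {
    d <- dwt_level1(approx, cfg$wavelet_name)
    approx <- d$approx
    details[[lev]] <- d$detail
  }
  c(approx, unlist(rev(details)))
}

#' Number of wavelet features per frame for a configuration
#' @param cfg a [frame_config()].
#' @return Integer coefficient count (134 at defaults).
#' @export
n_wavelet_features <- function(cfg = frame_config()) {
  length(wavelet_features(numeric(round(cfg$window_s * cfg$fs)), cfg))
}
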