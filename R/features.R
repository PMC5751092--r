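# Per-epoch feature engineering: 11 features per channel (154 per epoch for
# the 14-channel orthosis), [-1, 1] min-max normalization with bounds learned
# on training data only, and causal lagged-epoch concatenation.

FEATURE_SET <- c("sd", "entropy", "cv", "mean", "max", "min", "median",
                 "slope", "max_rms", "rms_mean", "fd")

#' Feature column names for a channel set
#'
#' @param channels Character vector of channel names.
#' @return Character vector, channel-major: 11 feature names per channel.
#' @export
feature_names <- function(channels = sist_channels()) {
  as.vector(t(outer(channels, FEATURE_SET, paste, sep = "__")))
}

#' Extract the per-epoch feature vector
#'
#' For each channel of a channels x samples epoch block, computes (in order):
#' standard deviation, Shannon entropy (bits, 10-bin histogram over the
#' epoch's own range), coefficient of variation, mean, maximum, minimum,
#' median, least-squares slope (per second), max-to-RMS ratio, RMS-to-mean
#' ratio and Higuchi fractal dimension (k_max = 8). Near-zero denominators
#' (|mean| or RMS < 1e-12) are replaced by 1e-12 so constant epochs stay
#' finite.
#'
#' @param epoch_block Numeric matrix, channels x samples (e.g. 14 x 100).
#' @param sample_rate Sampling rate in Hz (for the slope's per-second units).
#' @return Named numeric vector of length `11 * nrow(epoch_block)`.
#' @export
extract_features <- function(epoch_block, sample_rate = 500) {
  epoch_block <- as_numeric_matrix(epoch_block, "epoch_block")
  if (!all(is.finite(epoch_block))) abort("`epoch_block` must be finite.")
  out <- .epoch_features_cpp(t(epoch_block), ncol(epoch_block), sample_rate)
  chans <- rownames(epoch_block)
  if (is.null(chans)) chans <- paste0("ch", seq_len(nrow(epoch_block)))
  setNames(as.numeric(out[1, ]), feature_names(chans))
}

#' Feature matrix of a whole trial
#'
#' Denoises (optionally), epochs and featurizes a trial in one pass.
#'
#' @param trial A `sensor_trial` or `epoched_trial`.
#' @param epoch_length Samples per epoch.
#' @param denoise_first Denoise before extraction; ignored for
#'   `epoched_trial`s, which are already denoised.
#' @return Tibble: `epoch` (0-based) plus 154 feature columns.
#' @export
trial_features <- function(trial, epoch_length = 100L, denoise_first = TRUE) {
  sig <- if (inherits(trial, "epoched_trial")) trial$signal
  else if (inherits(trial, "sensor_trial")) {
    if (denoise_first) denoise(trial$signal) else trial$signal
  } else as_numeric_matrix(trial, "trial")
  rate <- if (is.list(trial)) trial$sample_rate else 500
  f <- .epoch_features_cpp(sig, as.integer(epoch_length), rate)
  colnames(f) <- feature_names(colnames(sig) %||% paste0("ch", seq_len(ncol(sig))))
  out <- tibble::as_tibble(f)
  out$epoch <- seq_len(nrow(f)) - 1L
  dplyr::relocate(out, "epoch")
}

#' Fit \[-1, 1\] normalization bounds
#'
#' Learns per-column min/max on training rows only; apply with
#' [apply_normalization()]. Normalized training columns attain both endpoints;
#' test values may fall outside \[-1, 1\] and are not clipped.
#'
#' @param train_features Numeric matrix or data frame of training features.
#' @return A `norm_bounds` tibble with `column`, `min`, `max`.
#' @export
fit_normalization <- function(train_features) {
  x <- as_numeric_matrix(train_features, "train_features")
  structure(tibble::tibble(
    column = colnames(x) %||% paste0("V", seq_len(ncol(x))),
    min = apply(x, 2, min),
    max = apply(x, 2, max)
  ), class = c("norm_bounds", "tbl_df", "tbl", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply fitted normalization bounds
#'
#' x' = 2 (x - min) / (max - min) - 1. Degenerate columns (max = min) map to 0.
#'
#' @param features Numeric matrix or data frame (same columns as the fit).
#' @param bounds A `norm_bounds` object from [fit_normalization()].
#' @return Numeric matrix of normalized features.
#' @export
apply_normalization <- function(features, bounds) {
  x <- as_numeric_matrix(features, "features")
  stopifnot(inherits(bounds, "norm_bounds"), ncol(x) == nrow(bounds))
  rng <- bounds$max - bounds$min
  out <- sweep(x, 2, bounds$min, "-")
  deg <- rng <= 0
  rng[deg] <- 1
  out <- sweep(out, 2, rng, "/") * 2 - 1
  if (any(deg)) out[, deg] <- 0
  out
}

#' Causal lagged-epoch concatenation
#'
#' Row e of the output concatenates feature rows e-k+1 ... e (oldest first).
#' Rows before the k-th pad by repeating the first row, so early epochs see a
#' "frozen" start; every output row depends only on epochs at or before it.
#'
#' @param features Numeric matrix or data frame, epochs x p.
#' @param k Number of lagged epochs, 1..10. `k = 1` returns the input.
#' @return Matrix epochs x (p * k). Columns are suffixed `__lag<j>` with
#'   j = k-1 (oldest) ... 0 (current).
#' @export
lag_concat <- function(features, k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > 10 || k != round(k))
    abort("`k` must be an integer in 1..10.")
  x <- as_numeric_matrix(features, "features")
  k <- as.integer(k)
  if (k == 1L) return(x)
  n <- nrow(x)
  blocks <- lapply((k - 1L):0L, function(lag) {
    idx <- pmax(seq_len(n) - lag, 1L)
    b <- x[idx, , drop = FALSE]
    colnames(b) <- paste0(colnames(x) %||% paste0("V", seq_len(ncol(x))),
                          "__lag", lag)
    b
  })
  do.call(cbind, blocks)
}
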