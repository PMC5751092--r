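# One-pass preparation of trials for learning: denoise, annotate, label,
# featurize; raw signals are dropped so a full 10-subject protocol stays
# small in memory.

#' Prepare trials for training and evaluation
#'
#' For every trial: translation-invariant denoising, automatic knee-angle
#' annotation, majority-vote epoch labels, and the 154-column feature matrix.
#' Raw signals are not retained.
#'
#' @param x A `sist_dataset` or list of `sensor_trial`s.
#' @param epoch_length Samples per epoch.
#' @return A `sist_prepared`: list with `features` (total epochs x 154
#'   matrix), `epochs` (tibble of per-epoch metadata and labels), `trials`
#'   (per-trial index with truth), `regions`/`truth` (per-trial lists),
#'   `epoch_length`, `sample_rate`.
#' @export
prepare_trials <- function(x, epoch_length = 100L) {
  trials <- if (inherits(x, "sist_dataset")) x$trials else x
  stopifnot(length(trials) >= 1, inherits(trials[[1]], "sensor_trial"))
  epoch_length <- as.integer(epoch_length)

  feats <- vector("list", length(trials))
  meta <- vector("list", length(trials))
  regions <- vector("list", length(trials))
  truth <- vector("list", length(trials))
  trows <- vector("list", length(trials))
  row0 <- 0L
  rate <- trials[[1]]$sample_rate

  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    et <- epoch_trial(tr, epoch_length = epoch_length)
    f <- .epoch_features_cpp(et$signal, epoch_length, tr$sample_rate)
    colnames(f) <- feature_names(colnames(et$signal))
    feats[[i]] <- f
    ne <- et$n_epochs
    meta[[i]] <- tibble::tibble(
      trial_id = i, subject_id = tr$subject_id,
      activity_id = tr$activity_id, epoch = seq_len(ne) - 1L,
      sit = et$sit_labels, trans = et$transition_labels)
    regions[[i]] <- et$regions
    truth[[i]] <- tr$transitions
    trows[[i]] <- tibble::tibble(
      trial_id = i, subject_id = tr$subject_id,
      activity_id = tr$activity_id, position_id = tr$position_id,
      n_epochs = ne, row_start = row0 + 1L, row_end = row0 + ne,
      n_sist = sum(tr$transitions$direction == "SiSt"),
      is_transition_trial = any(tr$transitions$direction == "SiSt"))
    row0 <- row0 + ne
  }

  structure(list(
    features = do.call(rbind, feats),
    epochs = dplyr::bind_rows(meta),
    trials = dplyr::bind_rows(trows),
    regions = regions,
    truth = truth,
    epoch_length = epoch_length,
    sample_rate = rate
  ), class = "sist_prepared")
}

#' @export
print.sist_prepared <- function(x, ...) {
  cat(sprintf("<sist_prepared> %d trials, %d epochs x %d features, %d subjects\n",
              nrow(x$trials), nrow(x$features), ncol(x$features),
              length(unique(x$trials$subject_id))))
  invisible(x)
}

# First row index (into the stacked feature matrix) of the trial each row
# belongs to -- the causal floor for lagged indexing.
row_starts <- function(prepared, rows = NULL) {
  rs <- rep(prepared$trials$row_start, prepared$trials$n_epochs)
  if (is.null(rows)) rs else rs[rows]
}

# Materialize lagged feature columns given (feature index, lag) pairs.
# Column j of the result is base[max(r - lag_j, trial_start(r)), feature_j].
lagged_columns <- function(base, starts, pairs) {
  n <- nrow(base)
  ridx <- seq_len(n)
  out <- matrix(0, n, nrow(pairs))
  for (j in seq_len(nrow(pairs))) {
    idx <- pmax(ridx - pairs$lag[j], starts)
    out[, j] <- base[idx, pairs$feature[j]]
  }
  colnames(out) <- paste0(colnames(base)[pairs$feature], "__lag", pairs$lag)
  out
}
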