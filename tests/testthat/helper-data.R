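# Shared fixtures, built in code.

# A small hand-assembled prepared dataset: `n_subj` subjects x `n_trials`
# mini-trials of `n_epochs` epochs over `p` features. Feature 1 separates
# sitting, feature 2 separates transitions; the rest is noise. Each trial
# sits for the first half, transitions for `trans_len` epochs, then stands.
fake_prepared <- function(n_subj = 2, n_trials = 3, n_epochs = 60, p = 10,
                          trans_len = 4, seed = 1, epoch_length = 100) {
  set.seed(seed)
  feats <- list(); meta <- list(); trows <- list()
  regions <- list(); truth <- list()
  row0 <- 0L; tid <- 0L
  for (s in seq_len(n_subj)) for (tr in seq_len(n_trials)) {
    tid <- tid + 1L
    sit <- c(rep(1L, n_epochs / 2), rep(0L, n_epochs / 2))
    trans <- rep(0L, n_epochs)
    t0 <- n_epochs / 2 + 1L
    trans[t0:(t0 + trans_len - 1L)] <- 1L
    sit[trans == 1L] <- 0L
    x <- matrix(rnorm(n_epochs * p, sd = 0.3), n_epochs, p)
    x[, 1] <- x[, 1] + 2 * sit
    x[, 2] <- x[, 2] + 3 * trans
    colnames(x) <- paste0("f", seq_len(p))
    feats[[tid]] <- x
    meta[[tid]] <- tibble::tibble(trial_id = tid, subject_id = s,
                                  activity_id = 2L,
                                  epoch = seq_len(n_epochs) - 1L,
                                  sit = sit, trans = trans)
    on <- (t0 - 1L) * epoch_length
    off <- (t0 - 1L + trans_len) * epoch_length
    regions[[tid]] <- tibble::tibble(onset = on, offset = off,
                                     midpoint = as.integer((on + off) / 2))
    truth[[tid]] <- tibble::tibble(onset = on, offset = off,
                                   direction = "SiSt")
    trows[[tid]] <- tibble::tibble(trial_id = tid, subject_id = s,
                                   activity_id = 2L,
                                   position_id = NA_integer_,
                                   n_epochs = n_epochs,
                                   row_start = row0 + 1L,
                                   row_end = row0 + n_epochs,
                                   n_sist = 1L, is_transition_trial = TRUE)
    row0 <- row0 + n_epochs
  }
  structure(list(features = do.call(rbind, feats),
                 epochs = dplyr::bind_rows(meta),
                 trials = dplyr::bind_rows(trows),
                 regions = regions, truth = truth,
                 epoch_length = as.integer(epoch_length),
                 sample_rate = 500),
            class = "sist_prepared")
}

# light-weight cascade control for the fake data
fake_control <- function(...) {
  cascade_control(mrmr_pool = 20L, mrmr_depth = 8L, ffs_hidden = 20L,
                  ffs_subsample = 500L, elm_hidden = 30L,
                  ffs_max_features = 5L, ...)
}
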