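# Two-stage recognition: stage 1 detects the sitting posture on every epoch;
# stage 2 -- run only while the system believes the user is sitting (with a
# short hangover through the transition onset, when stage 1 naturally flips)
# -- detects the initiation of a sit-to-stand. The gate is the mechanism that
# eliminates false positives during walking and standing.

#' Cascade training/gating configuration
#'
#' @param gate_enter Consecutive sitting decisions required to enter the
#'   SITTING state (C).
#' @param gate_hangover Consecutive non-sitting decisions (with no detection)
#'   after which the SITTING state is left (H); at 0.2 s epochs the default 15
#'   spans 3 s, the maximum transition duration, so stage 2 stays live through
#'   the onset.
#' @param classifier `"elm"` or `"mlp"` for both stages.
#' @param bins Discretization bins for mutual information.
#' @param mrmr_pool Relevance-ranked candidate pool size handed to mRMR.
#' @param mrmr_depth How deep the mRMR ranking is taken (FFS scans this list).
#' @param ffs_patience Consecutive non-improvements before FFS stops.
#' @param ffs_max_features Cap on the FFS-selected set.
#' @param ffs_hidden Hidden neurons of the wrapper ELM.
#' @param ffs_subsample Row cap (stratified) for the wrapper's training split.
#' @param elm_hidden Hidden neurons of the final ELM stages.
#' @param elm_ridge Per-sample ridge penalty of the final ELM stages (0 =
#'   plain pseudoinverse); a small penalty steadies decision scores for
#'   subjects unseen at training.
#' @param mlp_hidden Hidden neurons of the final MLP stages.
#' @param balance_max Class-imbalance cap for stage training: minority-class
#'   rows are oversampled (duplicated) until the majority is at most
#'   `balance_max` times the minority. The least-squares/backprop fits
#'   themselves are unchanged; only the training-set composition is.
#' @param mlp Training configuration ([mlp_control()]) for MLP stages.
#' @return List of class `cascade_control`.
#' @export
cascade_control <- function(gate_enter = 3L, gate_hangover = 15L,
                            classifier = c("elm", "mlp"), bins = 10L,
                            mrmr_pool = 300L, mrmr_depth = 40L,
                            ffs_patience = 8L, ffs_max_features = 30L,
                            ffs_hidden = 100L, ffs_subsample = 20000L,
                            elm_hidden = 300L, mlp_hidden = 30L,
                            elm_ridge = 3e-2, balance_max = 0L,
                            mlp = mlp_control()) {
  stopifnot(gate_enter >= 1, gate_hangover >= 1)
  structure(list(
    gate_enter = as.integer(gate_enter),
    gate_hangover = as.integer(gate_hangover),
    classifier = match.arg(classifier), bins = as.integer(bins),
    mrmr_pool = as.integer(mrmr_pool), mrmr_depth = as.integer(mrmr_depth),
    ffs_patience = as.integer(ffs_patience),
    ffs_max_features = as.integer(ffs_max_features),
    ffs_hidden = as.integer(ffs_hidden),
    ffs_subsample = as.integer(ffs_subsample),
    elm_hidden = as.integer(elm_hidden), mlp_hidden = as.integer(mlp_hidden),
    elm_ridge = elm_ridge, balance_max = as.integer(balance_max), mlp = mlp
  ), class = "cascade_control")
}

# Fit one stage: normalization bounds, mRMR + FFS feature subset, final
# classifier. `rows` flags the stage's training context within `prepared`
# train rows; `val_subject` supplies the wrapper's inner validation split.
fit_stage <- function(prepared, rows, labels, k, control, seed, val_subject) {
  base <- prepared$features
  starts <- row_starts(prepared)
  seeds <- child_seeds(seed, 4L)

  bounds <- fit_normalization(base[rows, , drop = FALSE])
  norm <- apply_normalization(base, bounds)
  # after normalization the training range is [-1, 1] by construction
  disc <- discretize_features(
    norm, bins = control$bins,
    bounds = structure(tibble::tibble(column = colnames(norm),
                                      min = rep(-1, ncol(norm)),
                                      max = rep(1, ncol(norm))),
                       class = c("norm_bounds", class(tibble::tibble()))))

  y <- as.integer(labels[rows])
  n_base <- ncol(base)
  ridx <- seq_len(nrow(base))

  # relevance of every (feature, lag) pair without materializing 154*k columns
  relev <- matrix(0, n_base, k)
  for (l in 0:(k - 1L)) {
    idx <- pmax(ridx - l, starts)
    relev[, l + 1L] <- .mi_columns_cpp(disc[idx, , drop = FALSE][rows, , drop = FALSE],
                                       y, control$bins, 2L)
  }
  pairs_all <- tidyr::expand_grid(lag = 0:(k - 1L), feature = seq_len(n_base))
  pairs_all$relevance <- relev[cbind(pairs_all$feature, pairs_all$lag + 1L)]
  pool <- pairs_all %>%
    arrange(dplyr::desc(.data$relevance), .data$lag, .data$feature) %>%
    utils::head(min(control$mrmr_pool, nrow(pairs_all)))

  disc_pool <- lagged_columns(disc, starts, pool)[rows, , drop = FALSE]
  storage.mode(disc_pool) <- "integer"
  depth <- min(control$mrmr_depth, nrow(pool))
  rk <- .mrmr_rank_cpp(disc_pool, y, depth, control$bins, 2L)
  ranked_pairs <- pool[as.integer(rk$order), c("feature", "lag")]

  # wrapper FFS: validation = one held-out training subject; wrapper training
  # keeps every minority-class row and caps the rest, so the wrapper's F1
  # signal is not drowned by class imbalance
  num_ranked <- lagged_columns(norm, starts, ranked_pairs)
  subj <- prepared$epochs$subject_id
  val_rows <- rows & subj == val_subject
  tr_rows <- rows & subj != val_subject
  if (!any(tr_rows) || !any(val_rows)) {
    # single training subject: fall back to a seeded 75/25 row split
    idx <- which(rows)
    vv <- with_seed(seeds[1], sample(idx, max(1L, length(idx) %/% 4L)))
    val_rows[] <- FALSE; val_rows[vv] <- TRUE
    tr_rows <- rows & !val_rows
  }
  tr_idx <- which(tr_rows)
  if (length(tr_idx) > control$ffs_subsample) {
    tr_idx <- with_seed(seeds[2], {
      pos <- tr_idx[labels[tr_idx] == 1]
      neg <- tr_idx[labels[tr_idx] == 0]
      npos <- min(length(pos), control$ffs_subsample %/% 2L)
      sort(c(sample(pos, npos),
             sample(neg, min(length(neg), control$ffs_subsample - npos))))
    })
  }
  ffs <- forward_select(seq_len(nrow(ranked_pairs)),
                        num_ranked[tr_idx, , drop = FALSE], labels[tr_idx],
                        num_ranked[which(val_rows), , drop = FALSE],
                        labels[which(val_rows)],
                        n_hidden = control$ffs_hidden, seed = seeds[3],
                        patience = control$ffs_patience,
                        max_features = control$ffs_max_features,
                        ridge = control$elm_ridge)
  selected <- ranked_pairs[ffs$selected, ]
  selected$name <- paste0(colnames(prepared$features)[selected$feature],
                          "__lag", selected$lag)

  # oversample the minority class up to a 1 : balance_max ratio so the
  # least-squares fit does not sit the decision surface against the rare class
  x_fit <- num_ranked[rows, ffs$selected, drop = FALSE]
  y_fit <- y
  npos <- sum(y_fit == 1)
  nneg <- sum(y_fit == 0)
  if (control$balance_max > 0 && npos > 0 && nneg > control$balance_max * npos) {
    reps <- floor(nneg / (control$balance_max * npos)) - 1L
    if (reps > 0) {
      extra <- rep(which(y_fit == 1), reps)
      x_fit <- rbind(x_fit, x_fit[extra, , drop = FALSE])
      y_fit <- c(y_fit, y_fit[extra])
    }
  }
  classifier <- if (control$classifier == "elm") {
    train_elm(x_fit, ifelse(y_fit > 0, 1, -1),
              n_hidden = min(control$elm_hidden, nrow(x_fit)),
              seed = seeds[4], ridge = control$elm_ridge)
  } else {
    train_mlp(x_fit, y_fit, n_hidden = control$mlp_hidden,
              control = control$mlp, seed = seeds[4])
  }
  list(classifier = classifier, bounds = bounds, selected = selected,
       ffs_trace = ffs$trace, mrmr = ranked_pairs, k = k)
}

#' Train the two-stage cascade
#'
#' Stage 1 (sitting vs other) is trained on all epochs; stage 2 (transition
#' vs non-transition) on epochs in sitting-or-transition context -- the
#' distribution stage 2 actually sees behind the gate at deployment. Each
#' stage gets its own normalization bounds and mRMR+FFS feature subset,
#' fitted on training data only.
#'
#' @param x A `sist_prepared` (from [prepare_trials()]) or `sist_dataset`.
#' @param k Shared lag count (1..10).
#' @param control A [cascade_control()].
#' @param seed Integer seed; training is deterministic under it.
#' @return A `cascade_model`.
#' @export
train_cascade <- function(x, k = 8L, control = cascade_control(), seed = 1L) {
  if (inherits(x, "sist_dataset")) x <- prepare_trials(x)
  stopifnot(inherits(x, "sist_prepared"))
  if (k < 1 || k > 10) abort("`k` must be in 1..10.")
  k <- as.integer(k)

  sit <- x$epochs$sit
  trans <- x$epochs$trans
  if (!any(sit == 1)) abort("training data contain no 'sitting' epochs.")
  if (!any(sit == 0)) abort("training data contain no 'non-sitting' epochs.")
  if (!any(trans == 1)) abort("training data contain no 'transition' epochs.")

  seeds <- child_seeds(seed, 3L)
  subjects <- sort(unique(x$epochs$subject_id))
  val_subject <- if (length(subjects) > 1)
    with_seed(seeds[1], sample(subjects, 1)) else subjects[1]

  all_rows <- rep(TRUE, nrow(x$epochs))
  stage1 <- fit_stage(x, all_rows, sit, k, control, seeds[2], val_subject)
  ctx <- sit == 1L | trans == 1L
  if (!any(trans[ctx] == 0))
    abort("training data contain no 'non-transition' epochs in sitting context.")
  stage2 <- fit_stage(x, ctx, trans, k, control, seeds[3], val_subject)

  structure(list(stage1 = stage1, stage2 = stage2, k = k, control = control,
                 epoch_length = x$epoch_length, sample_rate = x$sample_rate,
                 seed = as.integer(seed)),
            class = "cascade_model")
}

#' @export
print.cascade_model <- function(x, ...) {
  cat(sprintf(paste0("<cascade_model> %s, k = %d lagged epochs\n",
                     "  stage 1 (sitting): %d features; stage 2 (SiSt): %d features\n"),
              x$control$classifier, x$k, nrow(x$stage1$selected),
              nrow(x$stage2$selected)))
  invisible(x)
}

#' @export
glance.cascade_model <- function(x, ...) {
  tibble::tibble(classifier = x$control$classifier, k = x$k,
                 stage1_features = nrow(x$stage1$selected),
                 stage2_features = nrow(x$stage2$selected),
                 gate_enter = x$control$gate_enter,
                 gate_hangover = x$control$gate_hangover, seed = x$seed)
}

#' Selected features of a trained cascade
#'
#' @param x A `cascade_model`.
#' @param ... Unused.
#' @return Tibble with `stage`, `name`, `feature`, `lag`.
#' @export
tidy.cascade_model <- function(x, ...) {
  dplyr::bind_rows(
    mutate(x$stage1$selected, stage = "sitting", .before = 1),
    mutate(x$stage2$selected, stage = "transition", .before = 1))
}

# score >= 0 means positive for every classifier kind (elm score, mlp prob
# shifted by 0.5, or a user-supplied function returning scores)
stage_scores <- function(classifier, xmat) {
  if (inherits(classifier, "elm")) elm_decide(classifier, xmat)
  else if (inherits(classifier, "mlp")) mlp_prob(classifier, xmat) - 0.5
  else if (is.function(classifier)) classifier(xmat)
  else abort("unsupported stage classifier.")
}

# feature matrix a stage consumes for one trial's base features
stage_matrix <- function(stage, base) {
  if (is.null(stage$selected)) return(base)
  norm <- if (is.null(stage$bounds)) base
  else apply_normalization(base, stage$bounds)
  lagged_columns(norm, rep(1L, nrow(base)), stage$selected)
}

#' Run the cascade over one trial
#'
#' Epochs are processed in time order. Stage 1 classifies every epoch; the
#' system enters the SITTING state after `gate_enter` consecutive sitting
#' decisions and leaves it after `gate_hangover` consecutive non-sitting
#' decisions with no detection. Stage 2 is invoked only in the SITTING state;
#' its first positive emits a detection and exits SITTING until re-entry
#' (one detection per sitting bout).
#'
#' @param model A `cascade_model`.
#' @param trial A `sensor_trial`, or a base feature matrix (epochs x 154)
#'   for pre-featurized input.
#' @param truth Optional tibble of ground-truth transitions (`onset`,
#'   `offset` samples, `direction`); taken from the trial when available.
#' @param n_epochs Optionally process only the first `n_epochs` epochs.
#' @return A `detection_outcome`: per-epoch decisions, detections (epoch and
#'   seconds), and the per-trial detected / failed-to-detect flag.
#' @export
detect_stream <- function(model, trial, truth = NULL, n_epochs = NULL) {
  if (inherits(trial, "sensor_trial")) {
    if (!identical(colnames(trial$signal), sist_channels()))
      abort("trial channels do not match the training layout.")
    sig <- denoise(trial$signal)
    base <- .epoch_features_cpp(sig, model$epoch_length, trial$sample_rate)
    colnames(base) <- feature_names(colnames(sig))
    if (is.null(truth)) truth <- trial$transitions
    meta <- trial[c("subject_id", "activity_id", "position_id")]
  } else {
    base <- as_numeric_matrix(trial, "trial")
    meta <- list(subject_id = NA_integer_, activity_id = NA_integer_,
                 position_id = NA_integer_)
  }
  if (!is.null(n_epochs)) base <- base[seq_len(n_epochs), , drop = FALSE]
  n <- nrow(base)

  x1 <- stage_matrix(model$stage1, base)
  x2 <- stage_matrix(model$stage2, base)
  s1_scores <- stage_scores(model$stage1$classifier, x1)
  sit_dec <- s1_scores >= 0

  C <- model$control$gate_enter
  H <- model$control$gate_hangover
  state <- "idle"
  sit_streak <- 0L
  nonsit_streak <- 0L
  s2_dec <- rep(NA, n)
  s2_score <- rep(NA_real_, n)
  in_state <- character(n)
  det_epochs <- integer()

  for (e in seq_len(n)) {
    if (state == "idle") {
      sit_streak <- if (sit_dec[e]) sit_streak + 1L else 0L
      if (sit_streak >= C) {
        state <- "sitting"
        nonsit_streak <- 0L
      }
    }
    in_state[e] <- state
    if (state == "sitting") {
      sc <- stage_scores(model$stage2$classifier, x2[e, , drop = FALSE])
      s2_score[e] <- sc
      s2_dec[e] <- sc >= 0
      if (s2_dec[e]) {
        det_epochs <- c(det_epochs, e - 1L)  # 0-based epoch index
        state <- "idle"
        sit_streak <- 0L
      } else {
        nonsit_streak <- if (sit_dec[e]) 0L else nonsit_streak + 1L
        if (nonsit_streak >= H) {
          state <- "idle"
          sit_streak <- 0L
        }
      }
    }
  }

  el <- model$epoch_length
  rate <- model$sample_rate
  sist_truth <- if (!is.null(truth) && nrow(truth))
    truth[truth$direction == "SiSt", , drop = FALSE]
  else tibble::tibble(onset = integer(), offset = integer(),
                      direction = character())
  in_region <- vapply(det_epochs, function(e)
    any(e * el < sist_truth$offset & (e + 1L) * el > sist_truth$onset),
    logical(1))

  structure(list(
    epochs = tibble::tibble(
      epoch = seq_len(n) - 1L, time_s = (seq_len(n) - 1L) * el / rate,
      stage1_score = s1_scores, stage1_sit = sit_dec, state = in_state,
      stage2_score = s2_score, stage2_pos = s2_dec),
    detections = tibble::tibble(
      epoch = det_epochs, time_s = det_epochs * el / rate,
      in_region = in_region),
    detected = any(in_region),
    is_transition_trial = nrow(sist_truth) > 0,
    truth = truth,
    subject_id = meta$subject_id, activity_id = meta$activity_id,
    position_id = meta$position_id,
    epoch_length = el, sample_rate = rate
  ), class = "detection_outcome")
}

#' @export
print.detection_outcome <- function(x, ...) {
  cat(sprintf("<detection_outcome> activity %s: %d detection(s)%s\n",
              x$activity_id, nrow(x$detections),
              if (x$is_transition_trial)
                sprintf(", transition %sdetected", if (x$detected) "" else "NOT ")
              else ""))
  invisible(x)
}
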