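# Scoring: epoch-level confusion metrics with the outside-region false-
# positive rule, transition-level trial counts, detection times, the
# leave-one-subject-out experiment, and the paired t-test.

#' Epoch-level detection metrics
#'
#' True positives and false negatives are counted on transition-labelled
#' epochs; epochs that merely overlap a transition region are granted grace
#' (a positive there counts as a true positive, never a false positive);
#' false positives are counted only on epochs wholly outside every region.
#'
#' @param pred_labels,true_labels Equal-length 0/1 vectors per epoch.
#' @param transition_regions Tibble with `onset`, `offset` (0-based half-open
#'   samples); may be empty.
#' @param epoch_length Samples per epoch.
#' @return One-row tibble: `tp`, `tn`, `fp`, `fn`, `tpr`, `tnr`, `accuracy`,
#'   `f1` (rates as fractions in \[0, 1\]).
#' @export
epoch_metrics <- function(pred_labels, true_labels, transition_regions = NULL,
                          epoch_length = 100L) {
  if (length(pred_labels) != length(true_labels))
    abort("`pred_labels` and `true_labels` must have equal length.")
  n <- length(pred_labels)
  pred <- as.integer(pred_labels > 0)
  truth <- as.integer(true_labels > 0)
  overlap <- rep(FALSE, n)
  if (!is.null(transition_regions) && nrow(transition_regions)) {
    starts <- (seq_len(n) - 1L) * epoch_length
    for (r in seq_len(nrow(transition_regions)))
      overlap <- overlap |
        (starts < transition_regions$offset[r] &
           starts + epoch_length > transition_regions$onset[r])
  }
  overlap <- overlap | truth == 1  # labelled epochs are in-region by definition
  tp <- sum(pred == 1 & overlap)
  fn <- sum(pred == 0 & truth == 1)
  fp <- sum(pred == 1 & !overlap)
  tn <- sum(pred == 0 & truth == 0)
  denom <- function(a, b) if (a + b == 0) NA_real_ else a / (a + b)
  tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    tpr = denom(tp, fn), tnr = denom(tn, fp),
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    f1 = if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn))
}

#' Transition-level trial counts
#'
#' A transition trial with at least one in-region detection is a true
#' positive; with none it is Failed to Detect (FTD). A non-transition trial
#' is a true negative iff it has no detection at all.
#'
#' @param outcomes List of `detection_outcome`s, or a tibble with logical
#'   columns `is_transition_trial`, `detected` (in-region) and
#'   `any_detection`.
#' @return One-row tibble: `tp_t`, `tn_t`, `fp_t`, `ftd`.
#' @export
transition_metrics <- function(outcomes) {
  if (inherits(outcomes, "detection_outcome")) outcomes <- list(outcomes)
  if (is.list(outcomes) && !is.data.frame(outcomes)) {
    ok <- vapply(outcomes, inherits, logical(1), "detection_outcome")
    if (!all(ok)) abort("`outcomes` must be detection_outcome objects.")
    outcomes <- dplyr::bind_rows(lapply(outcomes, function(o) {
      if (is.null(o$truth)) abort("trial without truth metadata.")
      tibble::tibble(is_transition_trial = o$is_transition_trial,
                     detected = o$detected,
                     any_detection = nrow(o$detections) > 0)
    }))
  }
  tibble::tibble(
    tp_t = sum(outcomes$is_transition_trial & outcomes$detected),
    ftd = sum(outcomes$is_transition_trial & !outcomes$detected),
    tn_t = sum(!outcomes$is_transition_trial & !outcomes$any_detection),
    fp_t = sum(!outcomes$is_transition_trial & outcomes$any_detection))
}

#' Detection time of one trial
#'
#' Time from the annotated transition onset to the start of the first
#' positively classified in-region epoch, floored at zero (a detection inside
#' the onset epoch counts as immediate), plus the same as a percentage of the
#' region duration. Trials with no in-region detection yield no detection
#' time (they are Failed to Detect).
#'
#' @param outcome A `detection_outcome`.
#' @param region One-row tibble/list with `onset`, `offset` (samples) of the
#'   annotated transition; defaults to the first SiSt truth interval.
#' @return One-row tibble `dt_s`, `dt_pct`, or an empty tibble for FTD
#'   trials.
#' @export
detection_time <- function(outcome, region = NULL) {
  stopifnot(inherits(outcome, "detection_outcome"))
  if (is.null(region)) {
    sist <- outcome$truth[outcome$truth$direction == "SiSt", , drop = FALSE]
    if (!nrow(sist)) abort("trial has no transition region.")
    region <- sist[1, ]
  }
  rate <- outcome$sample_rate
  det <- outcome$detections
  el <- outcome$epoch_length
  inreg <- det$epoch * el < region$offset & (det$epoch + 1L) * el > region$onset
  if (!any(inreg))
    return(tibble::tibble(dt_s = numeric(), dt_pct = numeric()))
  first <- min(det$epoch[inreg])
  dt <- max(0, (first * el - region$onset) / rate)
  dur <- (region$offset - region$onset) / rate
  tibble::tibble(dt_s = dt, dt_pct = 100 * dt / dur)
}

# Re-index a prepared dataset down to a subset of trials.
subset_prepared <- function(prepared, trial_ids) {
  keep <- prepared$trials$trial_id %in% trial_ids
  tr <- prepared$trials[keep, , drop = FALSE]
  rows <- unlist(purrr::map2(tr$row_start, tr$row_end, seq))
  tr2 <- tr
  tr2$row_end <- cumsum(tr$n_epochs)
  tr2$row_start <- tr2$row_end - tr$n_epochs + 1L
  structure(list(
    features = prepared$features[rows, , drop = FALSE],
    epochs = prepared$epochs[rows, , drop = FALSE],
    trials = tr2,
    regions = prepared$regions[tr$trial_id],
    truth = prepared$truth[tr$trial_id],
    epoch_length = prepared$epoch_length,
    sample_rate = prepared$sample_rate
  ), class = "sist_prepared")
}

# Detect on one trial of a prepared dataset (features already computed).
detect_prepared <- function(model, prepared, trial_id) {
  i <- match(trial_id, prepared$trials$trial_id)
  rows <- prepared$trials$row_start[i]:prepared$trials$row_end[i]
  out <- detect_stream(model, prepared$features[rows, , drop = FALSE],
                       truth = prepared$truth[[i]])
  out$subject_id <- prepared$trials$subject_id[i]
  out$activity_id <- prepared$trials$activity_id[i]
  out$regions <- prepared$regions[[i]]
  out
}

# Score one fold: per-trial streams -> epoch metrics (summed counts),
# transition counts, detection times.
score_fold <- function(model, prepared, test_trials) {
  outs <- lapply(test_trials, function(tid) detect_prepared(model, prepared, tid))
  em <- dplyr::bind_rows(lapply(seq_along(outs), function(j) {
    o <- outs[[j]]
    i <- match(test_trials[j], prepared$trials$trial_id)
    rows <- prepared$trials$row_start[i]:prepared$trials$row_end[i]
    pred <- as.integer(!is.na(o$epochs$stage2_pos) & o$epochs$stage2_pos)
    epoch_metrics(pred, prepared$epochs$trans[rows], prepared$regions[[i]],
                  prepared$epoch_length)
  }))
  counts <- dplyr::summarise(em, dplyr::across(c("tp", "tn", "fp", "fn"), sum))
  tm <- transition_metrics(outs)
  dts <- dplyr::bind_rows(lapply(outs, function(o) {
    if (!o$is_transition_trial || !o$detected) return(NULL)
    reg <- if (!is.null(o$regions) && nrow(o$regions)) o$regions[1, ]
    else o$truth[o$truth$direction == "SiSt", ][1, ]
    detection_time(o, reg)
  }))
  rate <- function(a, b) if (a + b == 0) NA_real_ else a / (a + b)
  tibble::tibble(
    tp = counts$tp, tn = counts$tn, fp = counts$fp, fn = counts$fn,
    tpr = rate(counts$tp, counts$fn), tnr = rate(counts$tn, counts$fp),
    accuracy = (counts$tp + counts$tn) / sum(counts),
    f1 = 2 * counts$tp / (2 * counts$tp + counts$fp + counts$fn),
    tp_t = tm$tp_t, tn_t = tm$tn_t, fp_t = tm$fp_t, ftd = tm$ftd,
    dt_mean = if (nrow(dts)) mean(dts$dt_s) else NA_real_,
    dt_sd = if (nrow(dts) > 1) sd(dts$dt_s) else NA_real_,
    dt_pct = if (nrow(dts)) mean(dts$dt_pct) else NA_real_)
}

#' Leave-one-subject-out evaluation across lag counts
#'
#' For every lag and every held-out subject, fits normalization, feature
#' selection and both cascade stages on the remaining subjects' trials,
#' scores all trials of the held-out subject, and aggregates: rates are
#' averaged across folds, transition-level counts are summed over folds, and
#' detection times are pooled over detected trials.
#'
#' @param x A `sist_dataset` or `sist_prepared` with >= 2 subjects.
#' @param lags Lag counts to sweep (subset of 1..10).
#' @param classifier `"elm"` or `"mlp"`.
#' @param seed Integer seed.
#' @param control A [cascade_control()]; its `classifier` field is overridden
#'   by the `classifier` argument.
#' @return A `loso_result`: list with `summary` (tibble, one row per lag)
#'   and `folds` (per fold x lag detail).
#' @export
loso_evaluate <- function(x, lags = 1:10, classifier = c("elm", "mlp"),
                          seed = 1L, control = cascade_control()) {
  classifier <- match.arg(classifier)
  control$classifier <- classifier
  if (!all(lags %in% 1:10)) abort("`lags` must lie in 1..10.")
  if (inherits(x, "sist_dataset")) x <- prepare_trials(x)
  stopifnot(inherits(x, "sist_prepared"))
  subjects <- sort(unique(x$trials$subject_id))
  if (length(subjects) < 2) abort("leave-one-subject-out needs >= 2 subjects.")

  fold_seeds <- child_seeds(seed, length(subjects))
  folds <- list()
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    train_ids <- x$trials$trial_id[x$trials$subject_id != s]
    test_ids <- x$trials$trial_id[x$trials$subject_id == s]
    train_prep <- subset_prepared(x, train_ids)
    for (k in lags) {
      model <- train_cascade(train_prep, k = k, control = control,
                             seed = fold_seeds[si])
      row <- score_fold(model, x, test_ids)
      row$lag <- k
      row$held_out_subject <- s
      folds[[length(folds) + 1L]] <- row
    }
  }
  folds <- dplyr::bind_rows(folds)

  summary <- folds %>%
    group_by(.data$lag) %>%
    summarise(
      tpr = mean(.data$tpr, na.rm = TRUE),
      tnr = mean(.data$tnr, na.rm = TRUE),
      accuracy = mean(.data$accuracy, na.rm = TRUE),
      f1 = mean(.data$f1, na.rm = TRUE),
      fp_e = sum(.data$fp),
      tp_t = sum(.data$tp_t), tn_t = sum(.data$tn_t),
      fp_t = sum(.data$fp_t), ftd = sum(.data$ftd),
      dt_mean = mean(.data$dt_mean, na.rm = TRUE),
      dt_pct = mean(.data$dt_pct, na.rm = TRUE),
      detection_rate = 100 * sum(.data$tp_t) /
        pmax(sum(.data$tp_t) + sum(.data$ftd), 1L),
      .groups = "drop") %>%
    mutate(classifier = classifier, .before = 1)

  structure(list(summary = summary, folds = folds, classifier = classifier,
                 lags = lags, seed = as.integer(seed)),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat(sprintf("<loso_result> %s, %d fold(s) x lags {%s}\n", x$classifier,
              length(unique(x$folds$held_out_subject)),
              paste(x$lags, collapse = ",")))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.loso_result <- function(x, ...) x$summary

#' @export
glance.loso_result <- function(x, ...) {
  best <- x$summary[which.max(x$summary$f1), ]
  tibble::tibble(classifier = x$classifier, n_lags = length(x$lags),
                 best_lag = best$lag, best_f1 = best$f1,
                 total_fp_t = sum(x$summary$fp_t))
}

#' Paired-samples t-test
#'
#' Classic two-tailed paired t-test on the differences. Degenerate cases are
#' defined explicitly: all-zero differences report t = 0, p = 1
#' (`"no difference"`); constant non-zero differences (zero variance) report
#' p = 0 (`"constant difference"`).
#'
#' @param a,b Equal-length paired numeric vectors, n >= 2.
#' @return One-row tibble: `t`, `df`, `p`, `mean_diff`, `note`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  n <- length(a)
  if (n < 2) abort("need at least 2 pairs.")
  d <- a - b
  md <- mean(d)
  sdd <- sd(d)
  if (sdd == 0) {
    if (md == 0)
      return(tibble::tibble(t = 0, df = n - 1, p = 1, mean_diff = 0,
                            note = "no difference"))
    return(tibble::tibble(t = sign(md) * Inf, df = n - 1, p = 0,
                          mean_diff = md, note = "constant difference"))
  }
  t <- md / (sdd / sqrt(n))
  tibble::tibble(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1),
                 mean_diff = md, note = NA_character_)
}
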