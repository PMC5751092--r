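test_that("epoch metrics evaluate the confusion rates as defined", {
  # 5 TP, 5 FN inside a region; 90 TN outside; no FP
  truth <- c(rep(1, 10), rep(0, 90))
  pred <- c(rep(1, 5), rep(0, 95))
  reg <- tibble::tibble(onset = 0L, offset = 1000L)
  m <- epoch_metrics(pred, truth, reg, epoch_length = 100L)
  expect_equal(m$accuracy, 0.95)
  expect_equal(m$tpr, 0.5)
  expect_equal(m$tnr, 1)
  expect_equal(m$f1, 2 * 5 / (2 * 5 + 0 + 5))

  perfect <- epoch_metrics(truth, truth, reg, 100L)
  expect_equal(c(perfect$tpr, perfect$tnr, perfect$accuracy, perfect$f1),
               rep(1, 4))
  expect_error(epoch_metrics(1:3, 1:4), "equal length")
})

test_that("positives in region-overlapping epochs are granted grace", {
  # region covers samples 120..230: epochs 1 and 2 overlap, epoch 2 is
  # majority-labelled 1, epoch 1 is not. A positive in epoch 1 counts TP.
  truth <- c(0, 0, 1, 0, 0)   # majority labels per epoch
  reg <- tibble::tibble(onset = 120L, offset = 230L)
  pred <- c(0, 1, 1, 0, 0)
  m <- epoch_metrics(pred, truth, reg, epoch_length = 100L)
  expect_equal(m$fp, 0L)
  expect_equal(m$tp, 2L)
  # the same positive wholly outside the region is an FP
  pred2 <- c(1, 0, 1, 0, 0)
  expect_equal(epoch_metrics(pred2, truth, reg, 100L)$fp, 1L)
})

test_that("F1 equals its precision/recall harmonic form on random tables", {
  set.seed(50)
  for (i in 1:20) {
    truth <- sample(0:1, 200, replace = TRUE, prob = c(0.9, 0.1))
    pred <- ifelse(runif(200) < 0.2, 1 - truth, truth)
    m <- epoch_metrics(pred, truth, NULL, 100L)
    prec <- m$tp / (m$tp + m$fp)
    rec <- m$tp / (m$tp + m$fn)
    if (m$tp + m$fp > 0 && is.finite(prec + rec) && prec + rec > 0)
      expect_equal(m$f1, 2 * prec * rec / (prec + rec))
  }
})

test_that("F1 can exceed TPR when false positives are absent", {
  # TP 40, FN 60, FP 0, TN 900: TPR = 0.4, F1 = 80/140 = 0.571
  truth <- c(rep(1, 100), rep(0, 900))
  pred <- c(rep(1, 40), rep(0, 960))
  reg <- tibble::tibble(onset = 0L, offset = 100L * 100L)
  m <- epoch_metrics(pred, truth, reg, 100L)
  expect_equal(m$fp, 0L)
  expect_gt(m$f1, m$tpr)
})

test_that("transition-level counting follows the one-epoch-suffices rule", {
  tab <- tibble::tibble(
    is_transition_trial = c(rep(TRUE, 30), rep(FALSE, 4)),
    detected = c(rep(TRUE, 30), rep(FALSE, 4)),
    any_detection = c(rep(TRUE, 30), rep(FALSE, 4)))
  m <- transition_metrics(tab)
  expect_equal(unlist(m), c(tp_t = 30, ftd = 0, tn_t = 4, fp_t = 0))

  tab$detected[1] <- FALSE; tab$any_detection[1] <- FALSE
  expect_equal(transition_metrics(tab)$ftd, 1L)
  tab$any_detection[31] <- TRUE  # detection in a walking-only trial
  expect_equal(transition_metrics(tab)$fp_t, 1L)
})

test_that("detection time measures onset-to-first-in-region-epoch", {
  mk_outcome <- function(det_epochs) {
    structure(list(
      detections = tibble::tibble(epoch = det_epochs,
                                  time_s = det_epochs * 0.2,
                                  in_region = TRUE),
      truth = tibble::tibble(onset = 10000L, offset = 10650L,
                             direction = "SiSt"),
      is_transition_trial = TRUE, detected = TRUE,
      epoch_length = 100L, sample_rate = 500
    ), class = "detection_outcome")
  }
  # onset 20.00 s, detection epoch starts 20.20 s, duration 1.30 s
  dt <- detection_time(mk_outcome(101L))
  expect_equal(dt$dt_s, 0.2)
  expect_equal(dt$dt_pct, 100 * 0.2 / 1.3, tolerance = 1e-6)
  # detection inside the onset epoch clamps to zero
  expect_equal(detection_time(mk_outcome(100L))$dt_s, 0)
  # no in-region detection: excluded
  out <- mk_outcome(300L)
  expect_equal(nrow(detection_time(out)), 0L)
})

test_that("paired t-test matches the reference implementation and edge rules", {
  set.seed(60)
  a <- rnorm(10); b <- rnorm(10)
  mine <- paired_t_test(a, b)
  ref <- t.test(a, b, paired = TRUE)
  expect_lt(abs(mine$p - ref$p.value), 1e-8)
  expect_lt(abs(mine$t - unname(ref$statistic)), 1e-8)

  same <- paired_t_test(a, a)
  expect_equal(same$p, 1)
  expect_equal(same$note, "no difference")
  const <- paired_t_test(c(0.5, 0.6, 0.7), c(0.4, 0.5, 0.6))
  expect_equal(const$p, 0)
  expect_equal(const$note, "constant difference")
  expect_error(paired_t_test(1, 2), "2 pairs")
  expect_error(paired_t_test(1:3, 1:4), "equal length")
})

test_that("LOSO builds one fold per subject and never leaks the test subject", {
  prep <- fake_prepared(n_subj = 3, n_trials = 3, seed = 7)
  res <- loso_evaluate(prep, lags = 2, classifier = "elm", seed = 2,
                       control = fake_control())
  expect_equal(sort(unique(res$folds$held_out_subject)), 1:3)
  expect_equal(nrow(res$folds), 3L)
  expect_equal(nrow(res$summary), 1L)

  # leakage audit: corrupting the held-out subject's features must not change
  # the model trained in its fold
  train_ids <- prep$trials$trial_id[prep$trials$subject_id != 3]
  corrupted <- prep
  rows3 <- which(prep$epochs$subject_id == 3)
  corrupted$features[rows3, ] <- corrupted$features[rows3, ] * 1000 + 5
  m1 <- train_cascade(sistand:::subset_prepared(prep, train_ids),
                      k = 2, control = fake_control(), seed = 11)
  m2 <- train_cascade(sistand:::subset_prepared(corrupted, train_ids),
                      k = 2, control = fake_control(), seed = 11)
  expect_identical(m1$stage1$classifier$beta, m2$stage1$classifier$beta)
  expect_identical(m1$stage1$bounds, m2$stage1$bounds)
  expect_identical(m1$stage2$selected, m2$stage2$selected)

  expect_error(loso_evaluate(fake_prepared(n_subj = 1), lags = 1), "2 subjects")
  expect_error(loso_evaluate(prep, lags = 11), "1..10")
})

test_that("a lag sweep returns one summary row per lag", {
  prep <- fake_prepared(n_subj = 2, n_trials = 3, seed = 13)
  res <- loso_evaluate(prep, lags = c(1, 2, 3), classifier = "elm", seed = 4,
                       control = fake_control())
  expect_equal(res$summary$lag, c(1, 2, 3))
  expect_equal(nrow(res$folds), 6L)
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(nrow(glance(res)), 1L)
})
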