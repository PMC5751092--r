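prep <- fake_prepared(n_subj = 2, n_trials = 4, seed = 42)

test_that("cascade training yields two independently fitted stages", {
  m <- train_cascade(prep, k = 2, control = fake_control(), seed = 1)
  expect_s3_class(m, "cascade_model")
  expect_s3_class(m$stage1$classifier, "elm")
  expect_s3_class(m$stage2$classifier, "elm")
  expect_gte(nrow(m$stage1$selected), 1L)
  expect_gte(nrow(m$stage2$selected), 1L)
  # per-stage normalization bounds are fitted on different row sets
  expect_false(identical(m$stage1$bounds$min, m$stage2$bounds$min))
  expect_error(train_cascade(prep, k = 11), "1..10")
})

test_that("training without a class is rejected with the class named", {
  no_trans <- prep
  no_trans$epochs$trans <- 0L
  expect_error(train_cascade(no_trans, k = 2, control = fake_control()),
               "transition")
  no_sit <- prep
  no_sit$epochs$sit <- 1L
  expect_error(train_cascade(no_sit, k = 2, control = fake_control()),
               "non-sitting")
})

test_that("cascade training is deterministic under a seed", {
  a <- train_cascade(prep, k = 2, control = fake_control(), seed = 9)
  b <- train_cascade(prep, k = 2, control = fake_control(), seed = 9)
  expect_identical(a$stage1$classifier$beta, b$stage1$classifier$beta)
  expect_identical(a$stage2$selected, b$stage2$selected)
})

# stub cascade whose stages are plain functions of the feature matrix;
# feature 1 high = sitting, feature 2 high = transition
stub_model <- function(s1 = function(x) ifelse(x[, 1] > 1, 1, -1),
                       s2 = function(x) ifelse(x[, 2] > 1.5, 1, -1),
                       gate_enter = 3L, gate_hangover = 15L) {
  structure(list(
    stage1 = list(classifier = s1, bounds = NULL, selected = NULL),
    stage2 = list(classifier = s2, bounds = NULL, selected = NULL),
    k = 1L,
    control = cascade_control(gate_enter = gate_enter,
                              gate_hangover = gate_hangover),
    epoch_length = 100L, sample_rate = 500
  ), class = "cascade_model")
}

trial_feats <- function(prep, i) {
  rows <- prep$trials$row_start[i]:prep$trials$row_end[i]
  prep$features[rows, , drop = FALSE]
}

test_that("stage 2 is structurally silent when stage 1 never detects sitting", {
  poison <- function(x) stop("stage 2 must not be called")
  m <- stub_model(s1 = function(x) rep(-1, nrow(x)), s2 = poison)
  out <- detect_stream(m, trial_feats(prep, 1), truth = prep$truth[[1]])
  expect_equal(nrow(out$detections), 0L)
  expect_true(all(is.na(out$epochs$stage2_pos)))
  expect_false(out$detected)
})

test_that("the gate bounds stage-2 invocations and detections stop the bout", {
  m <- stub_model()
  x <- trial_feats(prep, 1)
  out <- detect_stream(m, x, truth = prep$truth[[1]])
  invoked <- !is.na(out$epochs$stage2_pos)
  expect_true(all(out$epochs$state[invoked] == "sitting"))
  expect_lte(sum(invoked), sum(out$epochs$state == "sitting"))
  # the scripted trial has one transition and the stub fires inside it
  expect_equal(nrow(out$detections), 1L)
  expect_true(out$detected)
  # entry needs gate_enter consecutive sitting decisions
  expect_true(all(out$epochs$state[1:2] == "idle"))
})

test_that("decisions are causal: truncated runs equal truncated decisions", {
  m <- stub_model()
  x <- trial_feats(prep, 2)
  full <- detect_stream(m, x, truth = prep$truth[[2]])
  for (E in c(10, 35, 50)) {
    part <- detect_stream(m, x, truth = prep$truth[[2]], n_epochs = E)
    expect_equal(part$epochs, full$epochs[1:E, ])
  }
})

test_that("with oracle stage 1, stage 2 never runs outside sitting context", {
  i <- 3L
  rows <- prep$trials$row_start[i]:prep$trials$row_end[i]
  sit_truth <- prep$epochs$sit[rows]
  k <- 0L
  oracle <- function(x) {
    k <<- k + nrow(x)
    ifelse(sit_truth[k - nrow(x) + seq_len(nrow(x))] == 1, 1, -1)
  }
  m <- stub_model(s1 = oracle, s2 = function(x) rep(1, nrow(x)))
  out <- detect_stream(m, trial_feats(prep, i), truth = prep$truth[[i]])
  invoked <- which(!is.na(out$epochs$stage2_pos))
  # sitting context = truth-sitting epochs plus the hangover after them
  in_ctx <- sit_truth == 1
  for (h in seq_len(m$control$gate_hangover))
    in_ctx <- in_ctx | c(rep(FALSE, h), head(sit_truth == 1, -h))
  expect_true(all(in_ctx[invoked]))
})

test_that("trained cascades detect the scripted transition on held-in data", {
  m <- train_cascade(prep, k = 2, control = fake_control(), seed = 1)
  out <- detect_stream(m, trial_feats(prep, 1), truth = prep$truth[[1]])
  expect_true(out$detected)
})

test_that("an MLP cascade trains and detects too", {
  ctl <- fake_control(classifier = "mlp",
                      mlp = mlp_control(learn_rate = 0.3, max_epochs = 300))
  m <- train_cascade(prep, k = 2, control = ctl, seed = 3)
  expect_s3_class(m$stage1$classifier, "mlp")
  out <- detect_stream(m, trial_feats(prep, 1), truth = prep$truth[[1]])
  expect_s3_class(out, "detection_outcome")
})

test_that("cascade models survive a JSON round trip", {
  m <- train_cascade(prep, k = 2, control = fake_control(), seed = 1)
  path <- tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  x <- trial_feats(prep, 1)
  o1 <- detect_stream(m, x, truth = prep$truth[[1]])
  o2 <- detect_stream(m2, x, truth = prep$truth[[1]])
  expect_equal(o1$epochs$stage1_score, o2$epochs$stage1_score, tolerance = 1e-12)
  expect_equal(o1$detections, o2$detections)
  unlink(path)
})
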