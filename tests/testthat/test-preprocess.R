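test_that("denoising preserves constants and rejects bad input", {
  x <- matrix(3.5, 512, 2)
  expect_equal(denoise(x), x, tolerance = 1e-9)
  x[1, 1] <- NA
  expect_error(denoise(x), "finite")
  expect_error(denoise(matrix(1, 16, 1)), "samples")
})

test_that("denoising reduces noise on a noisy logistic", {
  set.seed(31)
  clean <- knee_trajectory(4, 90, 5, 500)
  noisy <- clean + rnorm(length(clean), 0, 0.5)
  den <- denoise(matrix(noisy, ncol = 1))[, 1]
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(den, clean), rmse(noisy, clean))
})

test_that("cycle-spinning denoising commutes with circular shifts", {
  set.seed(7)
  x <- sin(seq(0, 6 * pi, length.out = 1024)) + rnorm(1024, 0, 0.2)
  d0 <- denoise(matrix(x, ncol = 1), boundary = "periodic")[, 1]
  xs <- c(x[-(1:25)], x[1:25])  # circular shift by 25
  d1 <- denoise(matrix(xs, ncol = 1), boundary = "periodic")[, 1]
  expect_lt(max(abs(d1 - c(d0[-(1:25)], d0[1:25]))), 1e-6)
  # reflection padding agrees with the periodic transform away from the ends
  dr <- denoise(matrix(x, ncol = 1))[, 1]
  expect_lt(max(abs(dr[200:800] - d0[200:800])), 0.05)
})

test_that("epoching follows the floor rule", {
  x <- matrix(rnorm(30000 * 3), 30000, 3)
  blocks <- epoch_signal(x, 100)
  expect_length(blocks, 300L)
  expect_equal(dim(blocks[[1]]), c(3L, 100L))
  expect_length(epoch_signal(matrix(1, 250, 2), 100), 2L)
  expect_error(epoch_signal(matrix(1, 99, 2), 100), "shorter")
  expect_error(epoch_signal(matrix(1, 200, 2), 1), "epoch_length")
})

test_that("annotation recovers the knee midpoint and truth boundaries", {
  subj <- sample_subjects(2, seed = 5)
  for (i in 1:2) for (act in c(2, 6)) {
    tr <- simulate_trial(subj[[i]], act, 2, seed = i * 10 + act)
    den <- denoise(tr$signal)
    ann <- annotate_transitions(den[, "knee_deg"], tr$sample_rate)
    truth <- tr$transitions[tr$transitions$direction == "SiSt", ]
    expect_equal(nrow(ann), nrow(truth))
    expect_lt(max(abs(den[ann$midpoint + 1, "knee_deg"] - 45)), 1)
    expect_lt(max(abs(ann$onset - truth$onset)) / tr$sample_rate, 0.1)
    expect_lt(max(abs(ann$offset - truth$offset)) / tr$sample_rate, 0.1)
  }
})

test_that("a standing-only knee trace yields no transition regions", {
  knee <- rep(5, 5000) + rnorm(5000, 0, 0.3)
  expect_equal(nrow(annotate_transitions(knee, 500)), 0L)
})

test_that("epoch labelling uses the majority rule with ties labelled 1", {
  reg <- tibble::tibble(onset = 0L, offset = 150L)
  expect_equal(label_epochs(reg, 3, 100), c(1L, 1L, 0L))  # 100%, 50% tie
  reg2 <- tibble::tibble(onset = 0L, offset = 30L)
  expect_equal(label_epochs(reg2, 3, 100), c(0L, 0L, 0L))
  expect_equal(label_epochs(NULL, 4, 100), rep(0L, 4))
  expect_error(label_epochs(tibble::tibble(onset = 0L, offset = 500L), 3, 100),
               "exceeds")
})

test_that("sitting labels follow the same majority rule", {
  posture <- c(rep("sit", 150), rep("stand", 150))
  expect_equal(label_sitting(posture, 3, 100), c(1L, 1L, 0L))
})

test_that("labelling every simulated SiSt yields at least one positive epoch", {
  subj <- sample_subjects(1, seed = 8)[[1]]
  for (pos in c(0, 1, 4)) {
    tr <- simulate_trial(subj, 6, pos, seed = 20 + pos)
    et <- epoch_trial(tr)
    expect_gte(sum(et$transition_labels), 1L)
    # labels are reproducible and noise-independent given the same regions
    expect_identical(
      label_epochs(et$regions, et$n_epochs, et$epoch_length),
      et$transition_labels)
  }
})
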