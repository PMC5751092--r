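test_that("the per-epoch feature vector has the documented closed forms", {
  blk <- matrix(3, 14, 100, dimnames = list(sist_channels(), NULL))
  f <- extract_features(blk)
  expect_length(f, 154L)
  expect_equal(unname(f["knee_deg__sd"]), 0)
  expect_equal(unname(f["knee_deg__mean"]), 3)
  expect_equal(unname(f["knee_deg__max"]), 3)
  expect_equal(unname(f["knee_deg__min"]), 3)
  expect_equal(unname(f["knee_deg__median"]), 3)
  expect_equal(unname(f["knee_deg__slope"]), 0)
  expect_equal(unname(f["knee_deg__entropy"]), 0)

  blk[1, ] <- 0:99  # index ramp on the first channel
  f <- extract_features(blk, sample_rate = 500)
  expect_equal(unname(f["thigh_acc_x__slope"]), 500)  # 1/sample * 500 Hz
  expect_equal(unname(f["thigh_acc_x__mean"]), 49.5)
  expect_equal(unname(f["thigh_acc_x__median"]), 49.5)

  blk[1, 1] <- Inf
  expect_error(extract_features(blk), "finite")
})

test_that("features agree with independent base-R computations", {
  set.seed(12)
  x <- rnorm(100, 3, 2)
  blk <- matrix(x, 1, 100)
  f <- extract_features(blk, sample_rate = 500)
  expect_equal(unname(f[1]), sd(x))
  expect_equal(unname(f[4]), mean(x))
  expect_equal(unname(f[5]), max(x))
  expect_equal(unname(f[6]), min(x))
  expect_equal(unname(f[7]), median(x))
  expect_equal(unname(f[8]), unname(coef(lm(x ~ seq_along(x)))[2]) * 500)
  expect_equal(unname(f[3]), sd(x) / mean(x))
  rms <- sqrt(mean(x^2))
  expect_equal(unname(f[9]), max(x) / rms)
  expect_equal(unname(f[10]), rms / mean(x))
  # entropy: 10 equal-width bins over the epoch's own range
  h <- table(cut(x, seq(min(x), max(x), length.out = 11),
                 include.lowest = TRUE))
  p <- h / sum(h)
  expect_equal(unname(f[2]), -sum(p[p > 0] * log2(p[p > 0])))
})

test_that("amplitude shifts move location features and leave shape features", {
  set.seed(4)
  for (i in 1:5) {
    x <- rnorm(100)
    a <- extract_features(matrix(x, 1, 100))
    b <- extract_features(matrix(x + 7, 1, 100))
    expect_equal(unname(b[c(4, 5, 6, 7)]), unname(a[c(4, 5, 6, 7)]) + 7)
    expect_equal(unname(b[1]), unname(a[1]))  # sd
    expect_equal(unname(b[8]), unname(a[8]))  # slope
  }
})

test_that("min-max normalization attains both endpoints and extrapolates", {
  b <- fit_normalization(matrix(c(0, 5, 10), 3, 1))
  expect_equal(apply_normalization(matrix(c(0, 5, 10, 15), 4, 1), b)[, 1],
               c(-1, 0, 1, 2))
  deg <- fit_normalization(matrix(2, 3, 1))
  expect_equal(apply_normalization(matrix(c(2, 9), 2, 1), deg)[, 1], c(0, 0))
  # round trip on random data: every non-degenerate column spans [-1, 1]
  set.seed(2)
  x <- matrix(rnorm(200), 20, 10)
  n <- apply_normalization(x, fit_normalization(x))
  expect_equal(unname(apply(n, 2, min)), rep(-1, 10))
  expect_equal(unname(apply(n, 2, max)), rep(1, 10))
})

test_that("lagged concatenation is causal with frozen-start padding", {
  m <- matrix(seq_len(20), 5, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  expect_identical(lag_concat(m, 1), m)
  l <- lag_concat(m, 3)
  expect_equal(ncol(l), 12L)
  expect_equal(unname(l[3, ]), unname(c(m[1, ], m[2, ], m[3, ])))
  expect_equal(unname(l[1, ]), unname(c(m[1, ], m[1, ], m[1, ])))
  expect_error(lag_concat(m, 11), "1..10")
  expect_error(lag_concat(m, 0), "1..10")

  # causality: changing a later row never changes earlier output rows
  m2 <- m
  m2[5, ] <- 999
  expect_equal(lag_concat(m2, 3)[1:4, ], l[1:4, ])

  # 154 columns at lag 8 expand to 1232
  wide <- matrix(rnorm(154 * 6), 6, 154)
  expect_equal(ncol(lag_concat(wide, 8)), 1232L)
})
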