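test_that("mutual information matches hand-derived values", {
  x <- rep(c(0, 1), 500)
  expect_equal(mutual_information(x, x), 1)  # identical uniform binary
  x2 <- rep(c(0, 0, 1, 1), each = 25)
  y2 <- rep(c(0, 1, 0, 1), each = 25)
  expect_equal(mutual_information(x2, y2), 0)  # exact product table
  # joint counts [[40,10],[10,40]]: evaluate the 4-cell sum directly
  p <- matrix(c(40, 10, 10, 40), 2) / 100
  hand <- sum(p * log2(p / outer(rowSums(p), colSums(p))))
  xx <- rep(c(0, 0, 1, 1), c(40, 10, 10, 40))
  yy <- rep(c(0, 1, 0, 1), c(40, 10, 10, 40))
  expect_equal(mutual_information(xx, yy), hand)
  expect_error(mutual_information(1:3, 1:4), "equal length")
})

test_that("mutual information is symmetric, non-negative, and I(x,x) = H(x)", {
  set.seed(21)
  for (i in 1:10) {
    x <- sample(0:3, 200, replace = TRUE)
    y <- sample(0:2, 200, replace = TRUE)
    expect_equal(mutual_information(x, y), mutual_information(y, x))
    expect_gte(mutual_information(x, y), 0)
    p <- table(x) / length(x)
    expect_equal(mutual_information(x, x), -sum(p * log2(p)))
  }
})

test_that("mRMR penalizes redundancy: a copy ranks below independent noise", {
  set.seed(3)
  cls <- sample(0:1, 400, replace = TRUE)
  f <- cbind(f1 = cls, f2 = cls, f3 = sample(0:1, 400, replace = TRUE))
  rk <- mrmr_rank(f, cls, m = 3, bins = 2)
  expect_equal(rk$index[1], 1L)            # the class itself first
  expect_equal(rk$index[2], 3L)            # noise beats the exact copy
  expect_equal(rk$index[3], 2L)
})

test_that("a duplicated column never ranks directly above its original", {
  set.seed(17)
  for (rep in 1:5) {
    x <- matrix(sample(0:4, 600, replace = TRUE), 100, 6)
    y <- as.integer(x[, 1] + rnorm(100) > 2)
    xx <- cbind(x, dup = x[, 2])
    rk <- mrmr_rank(xx, y, m = 7, bins = 5)
    pos_dup <- which(rk$index == 7L)
    pos_orig <- which(rk$index == 2L)
    expect_false(pos_dup == pos_orig - 1L)
  }
})

test_that("m = 1 mRMR equals the exhaustive relevance argmax", {
  set.seed(9)
  x <- matrix(sample(0:9, 500, replace = TRUE), 50, 10)
  y <- as.integer(x[, 4] > 4)
  rel <- vapply(seq_len(ncol(x)),
                function(j) mutual_information(x[, j], y), numeric(1))
  expect_equal(mrmr_rank(x, y, m = 1, bins = 10)$index, which.max(rel))
})

test_that("greedy mRMR usually agrees with exhaustive subset search", {
  # oracle: maximize Relv(S) - Redn(S) over all C(8,4) subsets, with
  # Relv = mean I(x_i; c) and Redn = (1/|S|^2) sum over ordered pairs
  oracle_best <- function(x, y) {
    combs <- utils::combn(ncol(x), 4)
    mi_c <- vapply(seq_len(ncol(x)),
                   function(j) mutual_information(x[, j], y), numeric(1))
    mi_ff <- outer(seq_len(ncol(x)), seq_len(ncol(x)),
                   Vectorize(function(i, j) mutual_information(x[, i], x[, j])))
    scores <- apply(combs, 2, function(s)
      mean(mi_c[s]) - sum(mi_ff[s, s]) / length(s)^2)
    sort(combs[, which.max(scores)])
  }
  # instances: 8 independently class-correlated binary features with
  # well-separated strengths (flip probabilities), shuffled per instance
  agree <- 0L
  probs <- c(0.05, 0.15, 0.25, 0.35, 0.42, 0.45, 0.47, 0.49)
  for (i in 1:50) {
    set.seed(1000 + i)
    n <- 1000
    cls <- sample(0:1, n, replace = TRUE)
    x <- sapply(probs, function(p) {
      flip <- runif(n) < p
      ifelse(flip, 1L - cls, cls)
    })
    got <- sort(mrmr_rank(x, cls, m = 4, bins = 2)$index)
    if (identical(got, oracle_best(x, cls))) agree <- agree + 1L
  }
  expect_gte(agree, 45L)  # >= 90% of instances (greedy is not assumed perfect)
})

test_that("mRMR ranking is invariant to column order up to its tie-break", {
  set.seed(33)
  x <- matrix(sample(0:4, 800, replace = TRUE), 100, 8)
  y <- as.integer(x[, 2] + x[, 5] > 4)
  rk <- mrmr_rank(x, y, m = 8, bins = 5)
  perm <- c(3, 1, 8, 5, 2, 7, 4, 6)
  rk2 <- mrmr_rank(x[, perm], y, m = 8, bins = 5)
  expect_equal(perm[rk2$index], rk$index)
  expect_error(mrmr_rank(x, y, m = 9), "exceeds")
})

test_that("forward selection keeps improvements and stops on stagnation", {
  # scripted scorer: candidates 1..3 strictly improve, everything after is flat
  f1_of <- function(cols) min(length(cols), 3) / 3
  res <- forward_select(1:10, score_fun = f1_of, patience = 5)
  expect_equal(res$selected, 1:3)

  # useless candidates: the top-ranked feature alone survives
  res2 <- forward_select(1:10, score_fun = function(cols) 0.5, patience = 3)
  expect_equal(res2$selected, 1L)
  expect_error(forward_select(integer(), score_fun = function(cols) 1),
               "non-empty")
})
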