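test_that("an ELM with as many neurons as samples interpolates its targets", {
  set.seed(5)
  X <- matrix(rnorm(400), 40, 10)
  y <- ifelse(rowSums(X[, 1:3]) > 0, 1, -1)
  m <- train_elm(X, y, n_hidden = 40, seed = 2)
  expect_lt(sum(abs(predict(m, X)$.score - y)), 1e-6)
  expect_equal(predict(m, X)$.pred, y)  # 100% training agreement
  expect_error(train_elm(X, y, n_hidden = 41, seed = 1), "exceed")
})

test_that("ELM training is deterministic and prefix-nested in L", {
  set.seed(11)
  X <- matrix(rnorm(600), 60, 10)
  y <- ifelse(rnorm(60) > 0, 1, -1)
  a <- train_elm(X, y, 20, seed = 3)
  b <- train_elm(X, y, 20, seed = 3)
  expect_identical(a$beta, b$beta)
  # shared seed => nested hidden layers => non-increasing LS residual
  res <- vapply(c(5, 10, 20, 40, 60), function(L) {
    m <- train_elm(X, y, L, seed = 3)
    sqrt(sum((predict(m, X)$.score - y)^2))
  }, numeric(1))
  expect_true(all(diff(res) <= 1e-8))
  big <- train_elm(X, y, 20, seed = 3)
  expect_equal(a$a, big$a[1:20, , drop = FALSE])
})

test_that("ELM predictions follow the documented conventions", {
  set.seed(2)
  X <- matrix(rnorm(200), 20, 10)
  y <- ifelse(rnorm(20) > 0, 1, -1)
  m <- train_elm(X, y, 10, seed = 1)
  m0 <- m
  m0$beta <- m$beta * 0
  p0 <- predict(m0, X)
  expect_true(all(p0$.score == 0))
  expect_true(all(p0$.pred == 1L))  # score >= 0 maps to +1
  # row-wise independence: permuted inputs give permuted scores
  perm <- sample(20)
  expect_equal(predict(m, X[perm, ])$.score, predict(m, X)$.score[perm])
  expect_error(predict(m, X[, 1:3]), "columns")
})

test_that("the pseudoinverse solution matches an independent implementation", {
  skip_if_not_installed("MASS")
  set.seed(8)
  for (dims in list(c(12, 5), c(8, 8), c(6, 9))) {
    H <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    y <- rnorm(dims[1])
    expect_equal(sistand:::pinv_solve(H, y),
                 MASS::ginv(H) %*% matrix(y), tolerance = 1e-8)
  }
  # rank-deficient: duplicate column
  H <- cbind(1, 1, rnorm(10))
  y <- rnorm(10)
  expect_equal(sistand:::pinv_solve(H, y), MASS::ginv(H) %*% matrix(y),
               tolerance = 1e-8)
})

test_that("the MLP learns XOR and linearly separable blobs", {
  X <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2)
  y <- c(0, 1, 1, 0)
  ctl <- mlp_control(learn_rate = 0.5, momentum = 0.9, max_epochs = 2000,
                     patience = Inf)
  solved <- sum(vapply(1:5, function(s) {
    m <- train_mlp(X, y, n_hidden = 4, control = ctl, seed = s)
    all(predict(m, X)$.pred == y)
  }, logical(1)))
  expect_gte(solved, 4L)

  set.seed(14)
  Xb <- rbind(matrix(rnorm(60, -2), 30, 2), matrix(rnorm(60, 2), 30, 2))
  yb <- rep(c(0, 1), each = 30)
  # the blobs are linearly separable (perfect separation makes glm warn,
  # which is itself the evidence)
  lin <- suppressWarnings(glm(yb ~ Xb, family = binomial))
  expect_true(all((fitted(lin) >= 0.5) == (yb == 1)))
  m <- train_mlp(Xb, yb, n_hidden = 2,
                 control = mlp_control(learn_rate = 0.5, max_epochs = 1000,
                                       patience = Inf), seed = 2)
  expect_equal(mean(predict(m, Xb)$.pred == yb), 1)
})

test_that("MLP training is deterministic under a seed and rejects q < 1", {
  set.seed(6)
  X <- matrix(rnorm(100), 50, 2)
  y <- as.integer(X[, 1] > 0)
  a <- train_mlp(X, y, 3, seed = 7)
  b <- train_mlp(X, y, 3, seed = 7)
  expect_identical(a$W1, b$W1)
  expect_identical(a$W2, b$W2)
  expect_error(train_mlp(X, y, 0, seed = 1), "n_hidden")
})

test_that("both classifiers are invariant to training-row permutation", {
  set.seed(19)
  X <- matrix(rnorm(200), 50, 4)
  y01 <- as.integer(X[, 1] + X[, 2] > 0)
  perm <- sample(50)
  e1 <- train_elm(X, ifelse(y01 > 0, 1, -1), 15, seed = 4)
  e2 <- train_elm(X[perm, ], ifelse(y01[perm] > 0, 1, -1), 15, seed = 4)
  expect_equal(e1$beta, e2$beta, tolerance = 1e-8)
  ctl <- mlp_control(max_epochs = 200, patience = Inf)  # full batch, no split
  m1 <- train_mlp(X, y01, 3, control = ctl, seed = 4)
  m2 <- train_mlp(X[perm, ], y01[perm], 3, control = ctl, seed = 4)
  expect_equal(m1$W1, m2$W1, tolerance = 1e-6)
})

test_that("hidden-neuron selection minimizes CV error with ties to smaller", {
  set.seed(25)
  X <- rbind(matrix(rnorm(100, -2), 50, 2), matrix(rnorm(100, 2), 50, 2))
  y <- rep(c(0, 1), each = 50)
  expect_equal(select_hidden_neurons(X, y, grid = 7, "elm", seed = 1)$best, 7)
  # trivially separable: every grid value reaches zero error, smallest wins
  sel <- select_hidden_neurons(X, y, grid = c(20, 5, 10), "elm", seed = 1)
  expect_equal(sel$errors$cv_error, rep(0, 3))
  expect_equal(sel$best, 5)
  expect_error(select_hidden_neurons(X, y, grid = numeric(), "elm"), "grid")
})
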