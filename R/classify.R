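# The two neural classifiers: an extreme learning machine (random fixed
# hidden layer, output weights solved in closed form via the Moore-Penrose
# pseudoinverse) and a single-hidden-layer perceptron trained by full-batch
# backpropagation with momentum.

# Minimum-norm least-squares solution beta = pinv(H) %*% y, Moore-Penrose
# pseudoinverse with a relative singular-value cutoff. Small problems use the
# SVD of H directly; tall problems use the spectral decomposition of H'H,
# which never forms more than an L x L matrix and is equivalent up to the
# (squared) cutoff.
pinv_solve <- function(H, y, tol = 1e-10) {
  y <- as.matrix(y)
  if (nrow(H) <= 10000) {
    s <- svd(H)
    keep <- s$d > tol * max(s$d)
    if (!any(keep)) return(matrix(0, ncol(H), ncol(y)))
    return(s$v[, keep, drop = FALSE] %*%
             (crossprod(s$u[, keep, drop = FALSE], y) / s$d[keep]))
  }
  HtH <- crossprod(H)
  Hty <- crossprod(H, y)
  e <- eigen(HtH, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  keep <- sqrt(ev) > tol * sqrt(max(ev, 0))
  if (!any(keep)) return(matrix(0, ncol(H), ncol(y)))
  V <- e$vectors[, keep, drop = FALSE]
  V %*% ((crossprod(V, Hty)) / ev[keep])
}

#' Train an extreme learning machine
#'
#' Single-hidden-layer feedforward network with logistic-sigmoid activation.
#' Input weights and biases are drawn uniform(-1, 1) under the seed (one
#' weight+bias block per neuron, so networks with shared seeds are nested by
#' hidden-layer prefix); output weights solve beta = pinv(H) T in closed form.
#' Training is non-iterative. Requires `n_hidden <= nrow(x)`.
#'
#' @param x Numeric matrix/data frame, N x n.
#' @param y Targets in \{-1, +1\} (a 0/1 vector is recoded to -1/+1).
#' @param n_hidden Hidden-neuron count L.
#' @param seed Seed for the random hidden layer.
#' @param ridge Optional per-sample ridge penalty lambda >= 0 on the output
#'   weights (beta solves (H'H + lambda N I) beta = H'T). The default 0 is
#'   the plain pseudoinverse solution beta = pinv(H) T.
#' @return An `elm` model object.
#' @export
train_elm <- function(x, y, n_hidden, seed = 1L, ridge = 0) {
  x <- as_numeric_matrix(x)
  if (!all(is.finite(x))) abort("`x` must be finite.")
  N <- nrow(x)
  n <- ncol(x)
  L <- as.integer(n_hidden)
  if (L > N)
    abort(sprintf("`n_hidden` (%d) must not exceed the training count (%d).",
                  L, N))
  if (L < 1) abort("`n_hidden` must be >= 1.")
  y <- as.numeric(y)
  if (all(y %in% c(0, 1))) y <- ifelse(y > 0, 1, -1)
  if (!all(y %in% c(-1, 1))) abort("`y` must be coded {-1, +1} (or 0/1).")
  draws <- with_seed(seed, runif(L * (n + 1L), -1, 1))
  W <- matrix(draws, nrow = L, byrow = TRUE)
  a <- W[, seq_len(n), drop = FALSE]
  b <- W[, n + 1L]
  H <- sigmoid(tcrossprod(x, a) + matrix(b, N, L, byrow = TRUE))
  beta <- if (ridge > 0) {
    solve(crossprod(H) + diag(ridge * N, L), crossprod(H, matrix(y, ncol = 1)))
  } else {
    pinv_solve(H, matrix(y, ncol = 1))
  }
  structure(list(a = a, b = b, beta = beta, n_hidden = L, input_dim = n,
                 n_train = N, seed = as.integer(seed), ridge = ridge,
                 feature_names = colnames(x)),
            class = "elm")
}

# raw decision scores g(x a' + b) beta
elm_decide <- function(model, x) {
  H <- sigmoid(tcrossprod(x, model$a) +
                 matrix(model$b, nrow(x), model$n_hidden, byrow = TRUE))
  as.numeric(H %*% model$beta)
}

#' Predict from an ELM
#'
#' @param object An `elm` model.
#' @param newdata Numeric matrix/data frame with `input_dim` columns.
#' @param ... Unused.
#' @return Tibble with `.score` and `.pred` in \{-1, +1\}; the label is +1
#'   iff the score is >= 0.
#' @export
predict.elm <- function(object, newdata, ...) {
  newdata <- as_numeric_matrix(newdata, "newdata")
  if (ncol(newdata) != object$input_dim)
    abort(sprintf("`newdata` has %d columns; model expects %d.",
                  ncol(newdata), object$input_dim))
  s <- elm_decide(object, newdata)
  tibble::tibble(.score = s, .pred = ifelse(s >= 0, 1L, -1L))
}

#' @export
print.elm <- function(x, ...) {
  cat(sprintf("<elm> %d inputs -> %d hidden -> 1, trained on %d samples (seed %d)\n",
              x$input_dim, x$n_hidden, x$n_train, x$seed))
  invisible(x)
}

#' @export
glance.elm <- function(x, ...) {
  tibble::tibble(input_dim = x$input_dim, n_hidden = x$n_hidden,
                 n_train = x$n_train, seed = x$seed,
                 beta_norm = sqrt(sum(x$beta^2)))
}

#' @export
tidy.elm <- function(x, ...) {
  tibble::tibble(neuron = seq_len(x$n_hidden), bias = x$b,
                 beta = as.numeric(x$beta))
}

#' Training configuration for the MLP
#'
#' @param learn_rate Gradient-descent step size.
#' @param momentum Momentum coefficient.
#' @param max_epochs Maximum training epochs (full-batch updates).
#' @param patience Early-stopping patience on the validation loss; `Inf`
#'   disables early stopping (and the validation split).
#' @param val_fraction Fraction of rows held out for early stopping.
#' @return List of class `mlp_control`.
#' @export
mlp_control <- function(learn_rate = 0.01, momentum = 0.9, max_epochs = 500L,
                        patience = 20L, val_fraction = 0.1) {
  structure(list(learn_rate = learn_rate, momentum = momentum,
                 max_epochs = as.integer(max_epochs), patience = patience,
                 val_fraction = val_fraction), class = "mlp_control")
}

#' Train a multilayer perceptron
#'
#' Three layers (input, one sigmoid hidden layer of `n_hidden` units, sigmoid
#' output): Z_j = f(sum_i w_ij x_i - theta_j), Y = f(sum_j w_kj Z_j -
#' theta_k). Trained by full-batch backpropagation (squared-error loss) with
#' momentum; optional early stopping monitors a held-out validation split and
#' restores the best weights.
#'
#' @param x Numeric matrix/data frame, N x n.
#' @param y Targets in \{0, 1\}.
#' @param n_hidden Hidden-unit count q (>= 1).
#' @param control An [mlp_control()] object.
#' @param seed Seed for weight initialization and the validation split.
#' @return An `mlp` model object.
#' @export
train_mlp <- function(x, y, n_hidden, control = mlp_control(), seed = 1L) {
  x <- as_numeric_matrix(x)
  q <- as.integer(n_hidden)
  if (q < 1) abort("`n_hidden` must be >= 1.")
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) abort("`y` must be coded {0, 1}.")
  N <- nrow(x)
  n <- ncol(x)

  with_seed(seed, {
    use_val <- is.finite(control$patience) && control$val_fraction > 0 &&
      floor(N * control$val_fraction) >= 1
    if (use_val) {
      vidx <- sample.int(N, floor(N * control$val_fraction))
      xv <- x[vidx, , drop = FALSE]; yv <- y[vidx]
      xt <- x[-vidx, , drop = FALSE]; yt <- y[-vidx]
    } else {
      xt <- x; yt <- y
    }
    W1 <- matrix(runif(n * q, -0.5, 0.5), n, q)   # input -> hidden
    th1 <- runif(q, -0.5, 0.5)                    # hidden onsets
    W2 <- matrix(runif(q, -0.5, 0.5), q, 1)       # hidden -> output
    th2 <- runif(1, -0.5, 0.5)
    vW1 <- W1 * 0; vth1 <- th1 * 0; vW2 <- W2 * 0; vth2 <- 0
    Nt <- nrow(xt)

    best <- list(loss = Inf, W1 = W1, th1 = th1, W2 = W2, th2 = th2)
    wait <- 0L
    for (ep in seq_len(control$max_epochs)) {
      Z <- sigmoid(xt %*% W1 - matrix(th1, Nt, q, byrow = TRUE))
      Y <- sigmoid(as.numeric(Z %*% W2) - th2)
      err <- Y - yt
      dY <- err * Y * (1 - Y)                         # N
      gW2 <- crossprod(Z, dY) / Nt
      gth2 <- -mean(dY)
      dZ <- (dY %*% t(W2)) * Z * (1 - Z)              # N x q
      gW1 <- crossprod(xt, dZ) / Nt
      gth1 <- -colMeans(dZ)

      vW1 <- control$momentum * vW1 - control$learn_rate * gW1
      vth1 <- control$momentum * vth1 - control$learn_rate * gth1
      vW2 <- control$momentum * vW2 - control$learn_rate * gW2
      vth2 <- control$momentum * vth2 - control$learn_rate * gth2
      W1 <- W1 + vW1; th1 <- th1 + vth1; W2 <- W2 + vW2; th2 <- th2 + vth2

      if (use_val) {
        Zv <- sigmoid(xv %*% W1 - matrix(th1, nrow(xv), q, byrow = TRUE))
        Yv <- sigmoid(as.numeric(Zv %*% W2) - th2)
        loss <- mean((Yv - yv)^2)
        if (loss < best$loss - 1e-12) {
          best <- list(loss = loss, W1 = W1, th1 = th1, W2 = W2, th2 = th2)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= control$patience) break
        }
      }
    }
    if (use_val && is.finite(best$loss)) {
      W1 <- best$W1; th1 <- best$th1; W2 <- best$W2; th2 <- best$th2
    }
    structure(list(W1 = W1, th1 = th1, W2 = W2, th2 = th2,
                   n_hidden = q, input_dim = n, n_train = N,
                   control = control, seed = as.integer(seed),
                   epochs_run = ep, feature_names = colnames(x)),
              class = "mlp")
  })
}

mlp_prob <- function(model, x) {
  Z <- sigmoid(x %*% model$W1 -
                 matrix(model$th1, nrow(x), model$n_hidden, byrow = TRUE))
  sigmoid(as.numeric(Z %*% model$W2) - model$th2)
}

#' Predict from an MLP
#'
#' @param object An `mlp` model.
#' @param newdata Numeric matrix/data frame.
#' @param ... Unused.
#' @return Tibble with `.prob` and `.pred` in \{0, 1\} (threshold 0.5).
#' @export
predict.mlp <- function(object, newdata, ...) {
  newdata <- as_numeric_matrix(newdata, "newdata")
  if (ncol(newdata) != object$input_dim)
    abort(sprintf("`newdata` has %d columns; model expects %d.",
                  ncol(newdata), object$input_dim))
  p <- mlp_prob(object, newdata)
  tibble::tibble(.prob = p, .pred = as.integer(p >= 0.5))
}

#' @export
print.mlp <- function(x, ...) {
  cat(sprintf("<mlp> %d inputs -> %d hidden -> 1, %d epochs (seed %d)\n",
              x$input_dim, x$n_hidden, x$epochs_run, x$seed))
  invisible(x)
}

#' @export
glance.mlp <- function(x, ...) {
  tibble::tibble(input_dim = x$input_dim, n_hidden = x$n_hidden,
                 n_train = x$n_train, epochs_run = x$epochs_run,
                 seed = x$seed)
}

#' Choose the hidden-neuron count by cross-validation
#'
#' Stratified 5-fold cross-validation over a grid of hidden-layer sizes;
#' returns the grid value with the lowest mean validation misclassification
#' error (ties break toward the smaller count).
#'
#' @param x,y Training matrix and binary labels.
#' @param grid Candidate hidden-neuron counts.
#' @param classifier `"elm"` or `"mlp"`.
#' @param seed Seed for fold assignment and classifier initialization.
#' @param folds Number of CV folds.
#' @param control [mlp_control()] for the MLP.
#' @return List with `best` (chosen count) and `errors` (tibble per grid
#'   value).
#' @export
select_hidden_neurons <- function(x, y, grid, classifier = c("elm", "mlp"),
                                  seed = 1L, folds = 5L,
                                  control = mlp_control()) {
  if (!length(grid)) abort("`grid` must be non-empty.")
  classifier <- match.arg(classifier)
  x <- as_numeric_matrix(x)
  y01 <- as.integer(as.numeric(y) > 0)
  fold_of <- with_seed(seed, {
    f <- integer(length(y01))
    for (cls in unique(y01)) {
      idx <- which(y01 == cls)
      f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    f
  })
  errs <- vapply(grid, function(L) {
    fold_err <- vapply(seq_len(folds), function(k) {
      tr <- fold_of != k
      if (classifier == "elm") {
        Luse <- min(L, sum(tr))
        fit <- train_elm(x[tr, , drop = FALSE], ifelse(y01[tr] > 0, 1, -1),
                         n_hidden = Luse, seed = seed)
        pred <- as.integer(elm_decide(fit, x[!tr, , drop = FALSE]) >= 0)
      } else {
        fit <- train_mlp(x[tr, , drop = FALSE], y01[tr], n_hidden = L,
                         control = control, seed = seed)
        pred <- as.integer(mlp_prob(fit, x[!tr, , drop = FALSE]) >= 0.5)
      }
      mean(pred != y01[!tr])
    }, numeric(1))
    mean(fold_err)
  }, numeric(1))
  best <- min(grid[errs == min(errs)])  # ties break to the smaller count
  list(best = best,
       errors = tibble::tibble(n_hidden = grid, cv_error = errs))
}
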