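# Feature selection: mutual-information-based mRMR ranking followed by a
# wrapper forward feature selection (FFS).

#' Mutual information between two discrete variables
#'
#' Plug-in estimate in bits, I = sum p(x,y) log2\[p(x,y) / (p(x) p(y))\],
#' with 0 log 0 = 0. Inputs are treated as categorical.
#'
#' @param x,y Equal-length vectors (integer, factor or character).
#' @return Mutual information in bits (non-negative).
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  tab <- table(x, y)
  n <- sum(tab)
  pj <- tab / n
  px <- rowSums(pj)
  py <- colSums(pj)
  terms <- pj * log2(pj / outer(px, py))
  max(sum(terms[pj > 0]), 0)
}

#' Discretize feature columns into equal-width bins
#'
#' Bins each column into `bins` equal-width intervals over a reference range
#' (by default the column's own range); values outside the range clamp to the
#' end bins. Used to estimate mutual information on continuous features.
#'
#' @param features Numeric matrix or data frame.
#' @param bins Number of bins.
#' @param bounds Optional `norm_bounds` giving the reference range per column
#'   (e.g. from training data).
#' @return Integer matrix of codes 0..bins-1.
#' @export
discretize_features <- function(features, bins = 10L, bounds = NULL) {
  x <- as_numeric_matrix(features, "features")
  bins <- as.integer(bins)
  lo <- if (is.null(bounds)) apply(x, 2, min) else bounds$min
  hi <- if (is.null(bounds)) apply(x, 2, max) else bounds$max
  w <- (hi - lo) / bins
  w[w <= 0] <- 1
  codes <- floor(sweep(sweep(x, 2, lo, "-"), 2, w, "/"))
  codes[codes < 0] <- 0
  codes[codes >= bins] <- bins - 1L
  storage.mode(codes) <- "integer"
  dimnames(codes) <- dimnames(x)
  codes
}

#' mRMR feature ranking
#'
#' Greedy first-order incremental minimum-redundancy-maximum-relevance
#' ranking. The first feature maximizes the relevance I(x_i; c); each later
#' step maximizes I(x_j; c) - (1/|S|) sum over selected x_i of I(x_j; x_i)
#' (the difference-form criterion). Continuous features are discretized into
#' equal-width bins for the mutual-information estimates; ties break toward
#' the lowest column index.
#'
#' @param features Numeric matrix or data frame (epochs x features), or an
#'   integer matrix of pre-discretized codes.
#' @param labels Class labels (0/1 or factor), one per row.
#' @param m Number of features to rank (<= number of columns).
#' @param bins Discretization bins.
#' @return Tibble with `rank`, `index` (column index), `name`, `criterion`
#'   (Relv - Redn at selection) and `relevance` (I(x_i; c)).
#' @export
mrmr_rank <- function(features, labels, m, bins = 10L) {
  x <- as_numeric_matrix(features, "features")
  if (m > ncol(x)) abort("`m` exceeds the number of feature columns.")
  if (length(labels) != nrow(x)) abort("`labels` must match rows of `features`.")
  y <- as.integer(factor(labels)) - 1L
  ny <- max(y) + 1L
  codes <- if (is.integer(features) && is.matrix(features)) features
  else discretize_features(x, bins = bins)
  res <- .mrmr_rank_cpp(codes, y, as.integer(m), as.integer(bins), ny)
  tibble::tibble(
    rank = seq_len(m),
    index = as.integer(res$order),
    name = (colnames(x) %||% paste0("V", seq_len(ncol(x))))[res$order],
    criterion = as.numeric(res$criterion),
    relevance = as.numeric(res$relevance)[res$order]
  )
}

#' Wrapper forward feature selection
#'
#' Scans candidate columns in ranking order; a candidate is kept iff it
#' strictly improves the validation F1 score of a small seeded classifier
#' trained on the kept set plus the candidate. Stops after `patience`
#' consecutive non-improvements or at `max_features`. At least one feature
#' (the top-ranked) is always returned.
#'
#' @param ranked Integer vector of candidate column indices, best first
#'   (e.g. `mrmr_rank(...)$index`).
#' @param x_train,y_train Training matrix and 0/1 labels.
#' @param x_val,y_val Validation matrix and 0/1 labels (disjoint rows).
#' @param n_hidden Hidden-layer size of the wrapper ELM.
#' @param seed Seed for the wrapper classifier.
#' @param patience Consecutive non-improvements tolerated.
#' @param max_features Cap on the selected-set size.
#' @param ridge Ridge penalty of the wrapper ELM.
#' @param score_fun Optional replacement validation scorer,
#'   `function(cols) -> F1`; mostly for testing the acceptance rule.
#' @return List with `selected` (column indices, in acceptance order) and
#'   `trace` (tibble of candidate, f1, kept).
#' @export
forward_select <- function(ranked, x_train, y_train, x_val, y_val,
                           n_hidden = 100L, seed = 1L, patience = 5L,
                           max_features = 25L, ridge = 0, score_fun = NULL) {
  if (!length(ranked)) abort("`ranked` must be non-empty.")
  score <- if (is.null(score_fun)) {
    x_train <- as_numeric_matrix(x_train, "x_train")
    x_val <- as_numeric_matrix(x_val, "x_val")
    function(cols) {
      fit <- train_elm(x_train[, cols, drop = FALSE],
                       ifelse(y_train > 0, 1, -1),
                       n_hidden = min(n_hidden, nrow(x_train)), seed = seed,
                       ridge = ridge)
      pred <- elm_decide(fit, x_val[, cols, drop = FALSE])
      binary_f1(as.integer(pred > 0), as.integer(y_val > 0))
    }
  } else score_fun
  selected <- ranked[1]
  best <- score(selected)
  trace <- list(tibble::tibble(candidate = ranked[1], f1 = best, kept = TRUE))
  fails <- 0L
  for (cand in ranked[-1]) {
    if (length(selected) >= max_features || fails >= patience) break
    f1 <- score(c(selected, cand))
    kept <- f1 > best
    if (kept) {
      selected <- c(selected, cand)
      best <- f1
      fails <- 0L
    } else fails <- fails + 1L
    trace[[length(trace) + 1L]] <- tibble::tibble(candidate = cand, f1 = f1,
                                                  kept = kept)
  }
  list(selected = selected, trace = dplyr::bind_rows(trace), f1 = best)
}

# plain binary F1 = 2TP / (2TP + FP + FN); 0 when no positives anywhere
binary_f1 <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}
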