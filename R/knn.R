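#' k-nearest-neighbour GEBV prediction
#'
#' For each test individual, Euclidean distances to every training
#' individual are computed on the (imputed) genotype codes and the GEBV is
#' the mean trait value of the `k` nearest.  Distance ties at the k-th rank
#' are broken by ascending training index.
#'
#' @param g_train,g_test genotype matrices (rows = individuals) on the same
#'   markers.
#' @param y_train numeric training values.
#' @param k neighbour count, `1 <= k <= nrow(g_train)`.
#' @return Numeric vector of predictions, one per test row.
#' @export
predict_knn <- function(g_train, y_train, g_test, k) {
  A <- unclass(as.matrix(g_train)); B <- unclass(as.matrix(g_test))
  if (nrow(A) == 0L) stop("empty training set")
  if (ncol(A) != ncol(B)) stop("training and test marker counts differ")
  y_train <- as.numeric(y_train)
  if (length(y_train) != nrow(A)) stop("length(y_train) must equal nrow(g_train)")
  k <- as.integer(k)
  if (k < 1L || k > nrow(A)) stop("k must lie in 1..n_train")
  # squared cross-distances via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2ab'
  d2 <- outer(rowSums(B^2), rowSums(A^2), "+") - 2 * tcrossprod(B, A)
  apply(d2, 1L, function(d) mean(y_train[order(d)[seq_len(k)]]))
}

#' Choose k by cross-validated mean squared error
#'
#' Folds are assigned by a seeded shuffle; for each candidate `k` the
#' held-out squared errors are pooled over folds and the `k` with the
#' smallest mean squared error wins, ties going to the smaller `k`
#' (parsimony).
#'
#' @param g_train genotype matrix of the training population.
#' @param y_train training values.
#' @param k_grid candidate neighbour counts (clipped to valid values).
#' @param cv_folds number of folds (default 5).
#' @param seed optional seed for the fold shuffle.
#' @return The selected `k` (integer).
#' @export
select_k_cv <- function(g_train, y_train, k_grid = 1:10, cv_folds = 5L,
                        seed = NULL) {
  A <- unclass(as.matrix(g_train))
  n <- nrow(A)
  if (cv_folds < 2L || cv_folds > n) stop("cv_folds must lie in 2..n_train")
  k_grid <- sort(unique(as.integer(k_grid)))
  k_grid <- k_grid[k_grid >= 1L]
  if (!length(k_grid)) stop("empty k grid")
  if (!is.null(seed)) set.seed(seed)
  fold <- sample(rep(seq_len(cv_folds), length.out = n))
  max_train <- n - max(table(fold))
  k_grid <- k_grid[k_grid <= max_train]
  if (!length(k_grid)) stop("every candidate k exceeds the fold training size")
  sse <- stats::setNames(numeric(length(k_grid)), k_grid)
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    if (!any(tr)) stop("fold ", f, " has no training neighbours")
    for (i in seq_along(k_grid)) {
      pred <- predict_knn(A[tr, , drop = FALSE], y_train[tr],
                          A[!tr, , drop = FALSE], k_grid[i])
      sse[i] <- sse[i] + sum((y_train[!tr] - pred)^2)
    }
  }
  k_grid[which.min(sse)]  # first minimum = smallest k on the sorted grid
}
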