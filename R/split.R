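#' Kennard-Stone sample selection
#'
#' Classic deterministic max-min procedure on Euclidean distances: start
#' from the two mutually farthest points, then repeatedly add the point
#' whose minimum distance to the already-selected set is largest.
#' Distance ties break toward the lowest row index, so the selection is
#' fully deterministic across platforms.
#'
#' @param X Numeric matrix or data frame (samples x features).
#' @param k Number of points to select, `2 <= k <= nrow(X)`.
#' @return Integer vector of selected row indices, in selection order.
#' @export
kennard_stone <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop("k = ", k, " exceeds the ", n, " samples", call. = FALSE)
  D <- as.matrix(stats::dist(X))
  # farthest pair; on ties take the lexicographically smallest (i, j)
  far <- which(D == max(D), arr.ind = TRUE)
  far <- far[far[, 1L] < far[, 2L], , drop = FALSE]
  far <- far[order(far[, 1L], far[, 2L]), , drop = FALSE]
  sel <- c(far[1L, 1L], far[1L, 2L])
  mind <- pmin(D[, sel[1L]], D[, sel[2L]])
  while (length(sel) < k) {
    mind[sel] <- -Inf
    nxt <- which.max(mind)  # which.max takes the lowest index on ties
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
  }
  as.integer(sel)
}

#' Species-stratified Kennard-Stone split
#'
#' Runs [kennard_stone()] independently within each class and assigns the
#' selected, spread-out points to the prediction (test) set; the rest
#' form the training set. With the reference design of 30 samples per
#' species and a one-third fraction, each species contributes 10 test
#' samples (50 of 150 overall). Note the convention: the Kennard-Stone
#' picks become the *test* set.
#'
#' @param X Numeric matrix of the feature space in which distances are
#'   measured (typically the reduced model-input scores).
#' @param y Class labels aligned with the rows of `X`.
#' @param test_fraction Fraction of each class selected for the test set
#'   (default 1/3); per class `k = round(n_class * test_fraction)`,
#'   which must be at least 2.
#' @return A `split_indices` list: integer `train` and `test` row
#'   indices, `per_class_test` counts and the fraction used.
#' @export
stratified_split <- function(X, y, test_fraction = 1 / 3) {
  X <- as.matrix(X)
  y <- factor(y)
  test <- integer(0)
  for (lv in levels(y)) {
    idx <- which(y == lv)
    k <- round(length(idx) * test_fraction)
    if (k < 2L) {
      stop("class ", lv, ": test fraction selects fewer than 2 samples",
           call. = FALSE)
    }
    picked <- kennard_stone(X[idx, , drop = FALSE], k)
    test <- c(test, idx[picked])
  }
  test <- sort(test)
  structure(list(train = setdiff(seq_len(nrow(X)), test), test = test,
                 per_class_test = table(y[test]),
                 test_fraction = test_fraction),
            class = "split_indices")
}
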