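# Shared fixtures and independent oracles used across the suite.

# Small multi-class Gaussian fixture in full profile-table shape: every
# panel element is noise except the ones listed in `signal`, which get
# class-specific means.
make_profile_fixture <- function(n_per_class = 10, classes = c("duck", "pig"),
                                 signal = list(), noise_sd = 1, seed = 1,
                                 base = 10) {
  set.seed(seed)
  panel <- element_panel()
  rows <- lapply(seq_along(classes), function(ci) {
    m <- matrix(abs(stats::rnorm(n_per_class * length(panel),
                                 mean = base, sd = noise_sd)),
                nrow = n_per_class, dimnames = list(NULL, panel))
    for (el in names(signal)) {
      m[, el] <- abs(stats::rnorm(n_per_class, mean = signal[[el]][ci],
                                  sd = noise_sd))
    }
    data.frame(sample_id = sprintf("%s_%02d", classes[ci], seq_len(n_per_class)),
               species = classes[ci], m,
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  element_profile(do.call(rbind, rows), kind = "absolute")
}

# Independent Wilks' lambda oracle: scatter matrices assembled with
# explicit elementwise loops, then a plain determinant ratio.
wilks_oracle <- function(X, y) {
  X <- as.matrix(X)
  y <- as.character(y)
  n <- nrow(X); p <- ncol(X)
  grand <- colSums(X) / n
  Tm <- matrix(0, p, p)
  for (i in seq_len(n)) {
    d <- X[i, ] - grand
    Tm <- Tm + outer(d, d)
  }
  Wm <- matrix(0, p, p)
  for (lv in unique(y)) {
    idx <- which(y == lv)
    mu <- colSums(X[idx, , drop = FALSE]) / length(idx)
    for (i in idx) {
      d <- X[i, ] - mu
      Wm <- Wm + outer(d, d)
    }
  }
  det(Wm) / det(Tm)
}

# Exhaustive O(n^2) oracle for the Kennard-Stone starting pair.
farthest_pair_oracle <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  best <- c(NA, NA); bestd <- -Inf
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d <- sqrt(sum((X[i, ] - X[j, ])^2))
    if (d > bestd) { bestd <- d; best <- c(i, j) }
  }
  best
}

# Ridge-stabilized normal-equations least squares, an independent
# alternative to the SVD minimum-norm solve.
ridge_lsq_oracle <- function(H, T, ridge = 1e-12) {
  solve(crossprod(H) + diag(ridge, ncol(H)), crossprod(H, T))
}
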