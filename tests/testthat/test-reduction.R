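test_that("PCA recovers covariance structure with ordered contributions", {
  set.seed(1)
  # isotropic 2-D data: two roughly equal contributions
  Xi <- matrix(rnorm(4000), 2000, 2)
  m <- fit_pca(Xi)
  expect_equal(m$contributions[1], 0.5, tolerance = 0.05)
  expect_true(all(diff(m$eigenvalues) <= 0))
  # eigenvalue sum equals the covariance trace
  expect_equal(sum(m$eigenvalues), sum(diag(stats::cov(Xi))),
               tolerance = 1e-8)
  # orthonormal basis
  expect_equal(crossprod(m$basis), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)

  # data on a line: first contribution ~ 1
  t <- rnorm(200)
  Xl <- cbind(t, 2 * t + rnorm(200, sd = 1e-6), -t)
  ml <- fit_pca(Xl)
  expect_gt(ml$contributions[1], 0.999)

  # full reconstruction reproduces centered data
  set.seed(2)
  X <- matrix(rnorm(50 * 4), 50, 4)
  mf <- fit_pca(X)
  sc <- project(mf, X)
  rec <- sc %*% t(mf$basis)
  expect_equal(rec, sweep(X, 2, colMeans(X)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # cumulative contribution is monotone and ends at 1
  expect_true(all(diff(mf$cumulative) >= -1e-12))
  expect_equal(mf$cumulative[4], 1, tolerance = 1e-12)

  # agreement with the standard PCA implementation (independent route)
  pr <- stats::prcomp(X)
  expect_equal(mf$eigenvalues, unname(pr$sdev^2), tolerance = 1e-8)
})

test_that("Fisher LDA maximizes the Rayleigh quotient and respects the rank bound", {
  set.seed(3)
  n <- 20
  X <- rbind(matrix(rnorm(n * 3), n, 3),
             matrix(rnorm(n * 3, mean = 1.5), n, 3),
             matrix(rnorm(n * 3, mean = c(3, 0, -2)), n, 3))
  y <- rep(c("a", "b", "c"), each = n)
  m <- fit_lda(X, y)
  expect_lte(ncol(m$basis), 2L)  # C - 1 components
  expect_true(all(diff(m$eigenvalues) <= 1e-10))

  # random-search oracle: no direction beats the top generalized
  # eigenvalue by more than 1%
  s <- eabgauth:::scatter_matrices(X, y)
  B <- s$T - s$W
  rq <- function(w) as.numeric(t(w) %*% B %*% w / (t(w) %*% s$W %*% w))
  best_random <- max(apply(matrix(rnorm(3 * 10000), 3), 2, rq))
  expect_gte(m$eigenvalues[1] * 1.01, best_random)
  expect_equal(rq(m$basis[, 1]), m$eigenvalues[1], tolerance = 1e-8)

  # five classes yield at most 4 discriminant functions
  p <- generate_profiles(config = generator_config(n_per_class = 10, seed = 2))
  z <- zscore_apply(p, zscore_fit(p))
  ml <- fit_lda(as.matrix(z[, element_panel()]), z$species)
  expect_lte(ncol(ml$basis), 4L)

  expect_error(fit_lda(X, rep("a", nrow(X))), "2 classes")
})

test_that("two separated 1-D classes give one dominant discriminant", {
  set.seed(4)
  x <- cbind(c(rnorm(30, -5, 0.1), rnorm(30, 5, 0.1)))
  y <- rep(c("lo", "hi"), each = 30)
  m <- fit_lda(x, y)
  expect_equal(ncol(m$basis), 1L)
  sc <- project(m, x, 1)
  mu <- tapply(sc[, 1], y, mean)
  sdw <- mean(tapply(sc[, 1], y, stats::sd))
  expect_gt(abs(diff(mu)) / sdw, 50)
})

test_that("LDA separation is invariant to diagonal rescaling of inputs", {
  set.seed(6)
  X <- rbind(matrix(rnorm(60), 20, 3), matrix(rnorm(60, 2), 20, 3))
  y <- rep(c("a", "b"), each = 20)
  sep <- function(M, Z) {
    sc <- project(M, Z, 1)
    mu <- tapply(sc[, 1], y, mean)
    abs(diff(mu)) / sqrt(mean(tapply(sc[, 1], y, stats::var)))
  }
  m1 <- fit_lda(X, y)
  D <- diag(c(10, 0.2, 3))
  m2 <- fit_lda(X %*% D, y)
  expect_equal(sep(m1, X), sep(m2, X %*% D), tolerance = 1e-6)
  expect_equal(m1$eigenvalues, m2$eigenvalues, tolerance = 1e-8)
})

test_that("projection preserves geometry and handles k edge cases", {
  set.seed(7)
  X <- matrix(rnorm(30 * 5), 30, 5)
  m <- fit_pca(X)
  sc <- project(m, X)  # all components: a rotation
  expect_equal(as.matrix(stats::dist(sc)), as.matrix(stats::dist(X)),
               tolerance = 1e-8)
  expect_equal(ncol(project(m, X, 0)), 0L)
  expect_error(project(m, X, 6), "exceeds")
})

test_that("branch component defaults follow the reference pipeline", {
  expect_identical(retained_components("pca", "absolute", "anova"), 8L)
  expect_identical(retained_components("pca", "absolute", "swda"), 5L)
  expect_identical(retained_components("pca", "relative", "anova"), 9L)
  expect_identical(retained_components("pca", "relative", "swda"), 5L)
  for (k in c("absolute", "relative")) for (s in c("anova", "swda")) {
    expect_identical(retained_components("fisher_lda", k, s), 3L)
  }
  expect_identical(retained_components("pca", "absolute", "anova",
                                       override = 4), 4L)
})
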