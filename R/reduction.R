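# Sign convention shared by both reducers: flip each component so its
# entry of largest magnitude is positive; makes scores reproducible
# across linear-algebra backends.
fix_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

new_projection_model <- function(method, basis, eigenvalues, center,
                                 extra = list()) {
  ev <- pmax(eigenvalues, 0)
  contrib <- if (sum(ev) > 0) ev / sum(ev) else rep(0, length(ev))
  structure(c(list(method = method, basis = basis, eigenvalues = ev,
                   contributions = contrib, cumulative = cumsum(contrib),
                   center = center), extra),
            class = "projection_model")
}

#' Principal component analysis of a numeric table
#'
#' Eigendecomposition of the sample covariance matrix; components are
#' ordered by decreasing eigenvalue, and each component's contribution is
#' its eigenvalue's share of the covariance trace (the accumulative
#' contribution rate is the running sum of those shares).
#'
#' @param X Numeric matrix or data frame of samples x variables
#'   (typically Z-scored element values).
#' @return A `projection_model` with fields `basis` (columns =
#'   components), `eigenvalues`, `contributions`, `cumulative`, `center`.
#' @export
fit_pca <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 samples", call. = FALSE)
  C <- stats::cov(X)
  e <- eigen(C, symmetric = TRUE)
  V <- fix_signs(e$vectors)
  colnames(V) <- paste0("PC", seq_len(ncol(V)))
  rownames(V) <- colnames(X)
  new_projection_model("pca", V, e$values, colMeans(X))
}

#' Fisher linear discriminant analysis
#'
#' Solves the generalized eigenproblem "between-class scatter vs
#' within-class scatter": directions maximizing the ratio of inter-class
#' to intra-class deviation. Solved by Cholesky whitening of the
#' within-class scatter followed by a symmetric eigendecomposition, which
#' equals the direct generalized solve on nonsingular problems but is
#' numerically robust. At most `C - 1` discriminant functions exist for
#' `C` classes; contributions are eigenvalue shares over those functions.
#' A near-singular within-class scatter is ridged
#' (`1e-8 * trace/dim`, with a warning).
#'
#' @param X Numeric matrix or data frame (samples x variables).
#' @param y Class labels (>= 2 classes).
#' @return A `projection_model` with additional fields `class_means` and
#'   `within_scatter`.
#' @export
fit_lda <- function(X, y) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2L) stop("need at least 2 classes", call. = FALSE)
  s <- scatter_matrices(X, y)
  B <- s$T - s$W
  W <- s$W
  ok <- tryCatch({ R <- chol(W); rcond(W) > .Machine$double.eps * 100 },
                 error = function(e) FALSE)
  if (!ok) {
    warning("near-singular within-class scatter; applying ridge",
            call. = FALSE)
    W <- ridge_scatter(W)
    R <- chol(W)
  }
  # whiten: M = R^{-T} B R^{-1} is symmetric with the same eigenvalues
  # as W^{-1} B; basis maps back through R^{-1}
  Rinv <- backsolve(R, diag(ncol(W)))
  M <- t(Rinv) %*% B %*% Rinv
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  k <- min(nlevels(y) - 1L, ncol(X))
  V <- fix_signs(Rinv %*% e$vectors[, seq_len(k), drop = FALSE])
  colnames(V) <- paste0("DF", seq_len(k))
  rownames(V) <- colnames(X)
  cm <- do.call(rbind, lapply(levels(y), function(lv) {
    colMeans(X[y == lv, , drop = FALSE])
  }))
  rownames(cm) <- levels(y)
  new_projection_model("fisher_lda", V, e$values[seq_len(k)], colMeans(X),
                       extra = list(class_means = cm, within_scatter = W))
}

#' Project samples onto the leading components
#'
#' @param model A `projection_model`.
#' @param X Numeric matrix/data frame with the variables the model was
#'   fitted on.
#' @param k Number of leading components (default: all available).
#' @return Score matrix (samples x k).
#' @export
project <- function(model, X, k = NULL) {
  stopifnot(inherits(model, "projection_model"))
  X <- as.matrix(X)
  avail <- ncol(model$basis)
  if (is.null(k)) k <- avail
  if (k > avail) stop("k = ", k, " exceeds the ", avail,
                      " available components", call. = FALSE)
  if (k == 0L) {
    return(matrix(numeric(0), nrow = nrow(X), ncol = 0L))
  }
  sweep(X, 2L, model$center, "-") %*% model$basis[, seq_len(k), drop = FALSE]
}

#' Default number of retained components per pipeline branch
#'
#' The pipeline's reference defaults, keyed by reducer, dataset kind and
#' selector: PCA keeps 8 (absolute/ANOVA), 5 (absolute/SWDA), 9
#' (relative/ANOVA) or 5 (relative/SWDA) principal components; Fisher LDA
#' keeps the top 3 discriminant functions in every branch. These counts
#' reproduce the reference pipeline's accumulative-contribution choices
#' and can be overridden.
#'
#' @param method `"pca"` or `"fisher_lda"`.
#' @param dataset_kind `"absolute"` or `"relative"`.
#' @param selector `"anova"` or `"swda"`.
#' @param override Optional explicit count.
#' @return Integer component count.
#' @export
retained_components <- function(method = c("pca", "fisher_lda"),
                                dataset_kind = c("absolute", "relative"),
                                selector = c("anova", "swda"),
                                override = NULL) {
  method <- match.arg(method)
  dataset_kind <- match.arg(dataset_kind)
  selector <- match.arg(selector)
  if (!is.null(override)) return(as.integer(override))
  if (method == "fisher_lda") return(3L)
  defaults <- c(absolute.anova = 8L, absolute.swda = 5L,
                relative.anova = 9L, relative.swda = 5L)
  defaults[[paste(dataset_kind, selector, sep = ".")]]
}

#' @export
print.projection_model <- function(x, ...) {
  cat(sprintf("<projection_model> %s, %d component(s); cumulative contribution: %s\n",
              x$method, ncol(x$basis),
              paste(sprintf("%.3f", x$cumulative), collapse = " ")))
  invisible(x)
}
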