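#' One-way ANOVA screening of elements
#'
#' Tests each panel element with a fixed-effects one-way ANOVA across the
#' species groups and retains elements with P below `alpha`. No
#' multiple-testing correction is applied (elements are screened
#' individually). The F statistic is invariant to per-element affine
#' rescaling, so it does not matter whether the table is standardized.
#'
#' @param table Profile table (or standardized data frame with `species`).
#' @param alpha Significance level (default 0.05).
#' @return A `selection_result` list: `method`, `selected` (ordered by
#'   panel position), `stats` (per-element F and P), `alpha`.
#' @export
anova_screen <- function(table, alpha = 0.05) {
  g <- factor(table$species)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2L)) stop("every group needs >= 2 samples", call. = FALSE)
  m <- profile_matrix(table)
  res <- lapply(colnames(m), function(el) {
    tab <- stats::anova(stats::lm(m[, el] ~ g))
    data.frame(element = el, F = tab$`F value`[1L], P = tab$`Pr(>F)`[1L],
               stringsAsFactors = FALSE)
  })
  stats_df <- do.call(rbind, res)
  selected <- stats_df$element[!is.na(stats_df$P) & stats_df$P < alpha]
  structure(list(method = "anova", selected = selected,
                 stats = stats_df, alpha = alpha),
            class = "selection_result")
}

# Within-class (W) and total (T) scatter matrices on a numeric matrix.
scatter_matrices <- function(X, y) {
  X <- as.matrix(X)
  y <- factor(y)
  Tc <- sweep(X, 2L, colMeans(X), "-")
  Tm <- crossprod(Tc)
  Wm <- matrix(0, ncol(X), ncol(X))
  for (lv in levels(y)) {
    Xi <- X[y == lv, , drop = FALSE]
    Wc <- sweep(Xi, 2L, colMeans(Xi), "-")
    Wm <- Wm + crossprod(Wc)
  }
  list(W = Wm, T = Tm)
}

# Ridge used when a scatter matrix is (near-)singular on tiny fixtures.
ridge_scatter <- function(M) {
  eps <- 1e-8 * sum(diag(M)) / ncol(M)
  if (eps <= 0) eps <- 1e-12
  M + diag(eps, ncol(M))
}

#' Wilks' lambda of an element subset
#'
#' `det(W) / det(T)` for the within-class scatter `W` and total scatter
#' `T` computed on the given columns: 1 means no class separation, values
#' near 0 mean classes are far apart relative to their internal scatter.
#' Near-singular scatter is stabilized with a ridge of
#' `1e-8 * trace/dim` (with a warning).
#'
#' @param X Numeric matrix or data frame (samples x elements).
#' @param y Class labels.
#' @return Wilks' lambda in (0, 1].
#' @export
wilks_lambda <- function(X, y) {
  s <- scatter_matrices(X, y)
  dT <- det(s$T)
  if (!is.finite(dT) || dT <= 0 ||
      rcond(s$T) < .Machine$double.eps * 100) {
    warning("near-singular total scatter; applying ridge", call. = FALSE)
    s$W <- ridge_scatter(s$W)
    s$T <- ridge_scatter(s$T)
    dT <- det(s$T)
  }
  det(s$W) / dT
}

# Partial F for adding a variable: subset size p before the addition.
partial_f_enter <- function(lambda_with, lambda_without, n, g, p) {
  ((n - g - p) / (g - 1)) * (lambda_without / lambda_with - 1)
}

#' Stepwise discriminant analysis (Wilks' lambda)
#'
#' Classic forward-stepwise variable selection: at each step the element
#' whose inclusion gives the largest partial F (from the ratio of Wilks'
#' lambdas with and without it) enters if that F reaches `f_enter`; after
#' each entry, any included element whose partial F for removal drops
#' below `f_remove` is removed. Stops when no entry or removal occurs. The
#' default thresholds (3.84 enter / 2.71 remove) are the classic
#' stepwise-discriminant defaults. Partial-F ties break toward the lower
#' panel index, making the procedure deterministic.
#'
#' @param table Profile table or standardized data frame with `species`.
#' @param f_enter,f_remove F thresholds to enter/remove a variable.
#' @param max_steps Safety cap on entry steps (default: panel size).
#' @return A `selection_result` list: `method = "swda"`, `selected` (in
#'   entry order), `trace` (one row per entry/removal with the Wilks'
#'   lambda and partial F), thresholds.
#' @export
swda <- function(table, f_enter = 3.84, f_remove = 2.71, max_steps = NULL) {
  y <- factor(table$species)
  if (nlevels(y) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(y) < 2L)) stop("every group needs >= 2 samples", call. = FALSE)
  m <- profile_matrix(table)
  panel <- colnames(m)
  if (is.null(max_steps)) max_steps <- length(panel)
  n <- nrow(m); g <- nlevels(y)
  included <- character(0)
  lambda_cur <- 1
  trace <- list()
  note <- function(action, el, lambda, f) {
    trace[[length(trace) + 1L]] <<- data.frame(
      step = length(trace) + 1L, action = action, element = el,
      lambda = lambda, partial_F = f, stringsAsFactors = FALSE)
  }
  for (step in seq_len(max_steps)) {
    p <- length(included)
    candidates <- setdiff(panel, included)
    if (length(candidates) == 0L || n - g - p <= 0L) break
    lam <- vapply(candidates, function(el) {
      wilks_lambda(m[, c(included, el), drop = FALSE], y)
    }, numeric(1))
    f <- partial_f_enter(lam, lambda_cur, n, g, p)
    best <- which.max(f)  # first max = lowest panel index on ties
    if (!is.finite(f[best]) || f[best] < f_enter) break
    included <- c(included, candidates[best])
    lambda_cur <- lam[best]
    note("enter", candidates[best], lambda_cur, f[best])
    # backward pass: drop anything whose removal F fell below f_remove
    repeat {
      p <- length(included)
      if (p < 2L) break
      lam_wo <- vapply(included, function(el) {
        wilks_lambda(m[, setdiff(included, el), drop = FALSE], y)
      }, numeric(1))
      f_rm <- partial_f_enter(lambda_cur, lam_wo, n, g, p - 1L)
      worst <- which.min(f_rm)
      if (f_rm[worst] >= f_remove) break
      el <- included[worst]
      lambda_cur <- lam_wo[worst]
      included <- setdiff(included, el)
      note("remove", el, lambda_cur, f_rm[worst])
    }
  }
  structure(list(method = "swda", selected = included,
                 trace = if (length(trace)) do.call(rbind, trace)
                         else data.frame(),
                 f_enter = f_enter, f_remove = f_remove),
            class = "selection_result")
}

#' Select elements with the configured method
#'
#' @param table Profile table.
#' @param method `"anova"` or `"swda"`.
#' @param ... Passed to [anova_screen()] or [swda()].
#' @return A `selection_result`.
#' @export
select_elements <- function(table, method = c("anova", "swda"), ...) {
  method <- match.arg(method)
  switch(method, anova = anova_screen(table, ...), swda = swda(table, ...))
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> method = %s, %d element(s): %s\n",
              x$method, length(x$selected),
              paste(x$selected, collapse = ", ")))
  invisible(x)
}
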