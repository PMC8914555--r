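#' Compact letter display from values and group labels
#'
#' Runs a one-way ANOVA followed by Tukey's HSD all-pairs comparison and
#' converts the pairwise decisions into a compact letter display: groups
#' sharing a letter are not significantly different at `alpha`. Letters
#' are assigned with the insert-and-absorb algorithm, with the group of
#' highest mean receiving letter "a". When the residual variance is
#' numerically zero (degenerate fixtures), groups are compared by exact
#' equality of means instead.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (coerced to factor).
#' @param alpha Significance level (default 0.05).
#' @return Named character vector of letter strings, one per group, named
#'   by group and ordered by descending group mean. Attribute `method`
#'   records the post-hoc test used.
#' @export
compact_letter_display <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  means <- tapply(values, g, mean)
  lv <- names(sort(means, decreasing = TRUE))
  k <- length(lv)
  fit <- stats::aov(values ~ g)
  mse <- stats::deviance(fit) / stats::df.residual(fit)
  # significance matrix in descending-mean order
  sig <- matrix(FALSE, k, k, dimnames = list(lv, lv))
  if (!is.finite(mse) || mse < 1e-12 * max(1, mean(values)^2)) {
    for (i in seq_len(k)) for (j in seq_len(k)) {
      sig[i, j] <- abs(means[lv[i]] - means[lv[j]]) > 1e-12
    }
  } else {
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    for (r in seq_along(pairs)) {
      a <- pairs[[r]][1L]; b <- pairs[[r]][2L]
      p <- tk[r, "p adj"]
      if (is.finite(p) && p < alpha) {
        sig[a, b] <- TRUE; sig[b, a] <- TRUE
      }
    }
  }
  cols <- list(lv)  # start with all groups in one letter column
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    if (!sig[lv[i], lv[j]]) next
    for (ci in rev(seq_along(cols))) {
      col <- cols[[ci]]
      if (lv[i] %in% col && lv[j] %in% col) {
        cols[[ci]] <- setdiff(col, lv[i])
        cols[[length(cols) + 1L]] <- setdiff(col, lv[j])
      }
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(cols))
    for (ci in seq_along(cols)) for (cj in seq_along(cols)) {
      if (ci != cj && keep[ci] && keep[cj] &&
          all(cols[[ci]] %in% cols[[cj]]) &&
          !(all(cols[[cj]] %in% cols[[ci]]) && ci < cj)) {
        keep[ci] <- FALSE
      }
    }
    cols <- cols[keep]
  }
  # order columns by their best-ranked member, letter them a, b, c, ...
  best <- vapply(cols, function(col) min(match(col, lv)), numeric(1))
  cols <- cols[order(best)]
  letters_out <- stats::setNames(rep("", k), lv)
  for (ci in seq_along(cols)) {
    letters_out[cols[[ci]]] <- paste0(letters_out[cols[[ci]]],
                                      letters[ci])
  }
  structure(letters_out, method = "tukey_hsd")
}

#' Compact letter display for one element across species
#'
#' Convenience wrapper around [compact_letter_display()] for a profile
#' table: the response is one element's values, the groups are the
#' species labels.
#'
#' @param table Profile table.
#' @param element Panel element symbol.
#' @param alpha Significance level.
#' @return As [compact_letter_display()].
#' @export
compact_letters <- function(table, element, alpha = 0.05) {
  if (!element %in% names(table)) {
    stop("no such element column: ", element, call. = FALSE)
  }
  compact_letter_display(table[[element]], table$species, alpha = alpha)
}
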