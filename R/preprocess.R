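#' Convert absolute concentrations to relative content
#'
#' Per sample, each element value is divided by that sample's 25-element
#' total, so every row of the result sums to 1. This is computed on the
#' raw concentrations (the definition of relative content), before any
#' standardization.
#'
#' @param table An absolute-content [element_profile()] table.
#' @return An [element_profile()] table of kind `"relative"`.
#' @export
to_relative <- function(table) {
  if (profile_kind(table) != "absolute") {
    stop("to_relative expects an absolute-content table", call. = FALSE)
  }
  panel <- element_panel()
  m <- profile_matrix(table)
  tot <- rowSums(m)
  bad <- which(tot <= 0)
  if (length(bad) > 0L) {
    stop("sample ", table$sample_id[bad[1L]], " has zero total content",
         call. = FALSE)
  }
  out <- as.data.frame(m / tot, check.names = FALSE)
  out <- cbind(table[, c("sample_id", "species"), drop = FALSE], out)
  # guard against accumulated floating error before revalidation
  out[, panel] <- out[, panel] / rowSums(out[, panel])
  element_profile(out, kind = "relative")
}

#' Fit per-element Z-score parameters
#'
#' Computes per-element center (mean) and scale (sample SD, n-1
#' denominator) on the fitting set. The default scope is the whole
#' dataset, matching a workflow that standardizes the full table before
#' splitting; `"training_only"` restricts fitting to `split$train` to
#' avoid train/test leakage.
#'
#' @param table Profile table (any kind).
#' @param scope `"whole_dataset"` or `"training_only"`.
#' @param split A list with integer `train` indices, required for
#'   `"training_only"`.
#' @return A `scaler_params` list with `center`, `scale`, `scope`.
#' @export
zscore_fit <- function(table, scope = c("whole_dataset", "training_only"),
                       split = NULL) {
  scope <- match.arg(scope)
  m <- profile_matrix(table)
  if (scope == "training_only") {
    if (is.null(split$train)) {
      stop("training_only scope needs split$train indices", call. = FALSE)
    }
    m <- m[split$train, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("need at least 2 samples to fit", call. = FALSE)
  center <- colMeans(m)
  scale <- apply(m, 2L, stats::sd)
  flat <- which(scale <= 0 | !is.finite(scale))
  if (length(flat) > 0L) {
    stop("constant column(s): ", paste(colnames(m)[flat], collapse = ", "),
         call. = FALSE)
  }
  structure(list(center = center, scale = scale, scope = scope),
            class = "scaler_params")
}

#' Apply (or invert) a fitted Z-score transform
#'
#' @param table Profile table whose element columns are to be transformed.
#' @param params A `scaler_params` from [zscore_fit()].
#' @param invert If `TRUE`, undo the transform (`x * scale + center`).
#' @return A plain data frame with `sample_id`, `species` and the
#'   standardized element columns (no longer a valid `element_profile`,
#'   since standardized values are signed).
#' @export
zscore_apply <- function(table, params, invert = FALSE) {
  stopifnot(inherits(params, "scaler_params"))
  m <- profile_matrix(table)
  missing_el <- setdiff(colnames(m), names(params$center))
  if (length(missing_el) > 0L) {
    stop("scaler has no parameters for: ",
         paste(missing_el, collapse = ", "), call. = FALSE)
  }
  ctr <- params$center[colnames(m)]
  scl <- params$scale[colnames(m)]
  z <- if (invert) {
    sweep(sweep(m, 2L, scl, "*"), 2L, ctr, "+")
  } else {
    sweep(sweep(m, 2L, ctr, "-"), 2L, scl, "/")
  }
  cbind(table[, c("sample_id", "species"), drop = FALSE],
        as.data.frame(z, check.names = FALSE))
}
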