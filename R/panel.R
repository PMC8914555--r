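#' The 25-element measurement panel
#'
#' The fixed, ordered panel of element symbols measured on every blood-gel
#' sample: 21 trace elements determined by ICP-MS plus the four
#' macro-elements (Na, Mg, Ca, K) determined by AAS. All absolute
#' concentrations are in mg/kg; relative content is the dimensionless
#' fraction of a sample's total measured element content.
#'
#' @return Character vector of 25 element symbols in panel order.
#' @export
#' @examples
#' element_panel()
element_panel <- function() {
  c("Li", "Be", "B", "Al", "Ti", "V", "Cr", "Mn", "Fe", "Co",
    "Ni", "Cu", "Zn", "As", "Se", "Rb", "Sr", "Cd", "Ba", "Tl",
    "Pb", "Na", "Mg", "Ca", "K")
}

#' The five blood-gel species labels
#'
#' @return Character vector of the five species, in reference-table order.
#' @export
species_levels <- function() {
  c("duck", "chicken", "bovine", "pig", "sheep")
}

#' Construct and validate an element profile table
#'
#' An element profile table is the pipeline's universal currency: one row per
#' sample, with a `sample_id`, a `species` label and the 25 panel element
#' columns. `kind` records whether values are absolute concentrations
#' (mg/kg) or relative fractions (each row summing to 1).
#'
#' @param df Data frame with columns `sample_id`, `species` and the 25
#'   panel elements.
#' @param kind `"absolute"` or `"relative"`.
#' @return The validated data frame with class `element_profile` and a
#'   `kind` attribute.
#' @export
element_profile <- function(df, kind = c("absolute", "relative")) {
  kind <- match.arg(kind)
  panel <- element_panel()
  needed <- c("sample_id", "species", panel)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop("profile table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, needed, drop = FALSE]
  bad_sp <- setdiff(unique(as.character(df$species)), species_levels())
  if (length(bad_sp) > 0L) {
    stop("unknown species label(s): ", paste(bad_sp, collapse = ", "),
         call. = FALSE)
  }
  for (el in panel) {
    v <- df[[el]]
    if (!is.numeric(v)) {
      stop("column ", el, " is not numeric", call. = FALSE)
    }
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad) > 0L) {
      stop("negative or non-finite value for element ", el,
           " in sample ", df$sample_id[bad[1L]], call. = FALSE)
    }
  }
  if (kind == "relative" && nrow(df) > 0L) {
    rs <- rowSums(df[, panel, drop = FALSE])
    off <- which(abs(rs - 1) > 1e-9)
    if (length(off) > 0L) {
      stop("relative profile rows must sum to 1; sample ",
           df$sample_id[off[1L]], " sums to ", rs[off[1L]], call. = FALSE)
    }
  }
  structure(df, kind = kind, class = c("element_profile", "data.frame"))
}

#' Extract the numeric 25-column matrix from a profile table
#'
#' @param table An `element_profile` (or any data frame carrying the panel
#'   columns).
#' @return Numeric matrix, samples in rows, elements in columns.
#' @export
profile_matrix <- function(table) {
  m <- as.matrix(table[, element_panel()[element_panel() %in% names(table)],
                       drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- table$sample_id
  m
}

#' @export
print.element_profile <- function(x, ...) {
  cat(sprintf("<element_profile> %d samples, kind = %s\n",
              nrow(x), attr(x, "kind")))
  NextMethod()
}

profile_kind <- function(table) {
  k <- attr(table, "kind")
  if (is.null(k)) stop("table has no 'kind' attribute", call. = FALSE)
  k
}
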