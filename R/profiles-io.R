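#' Read an element profile table from CSV
#'
#' Canonical dialect: comma-separated, UTF-8, "." decimal point, one header
#' line `sample_id,species,Li,...,K` with the 25 panel elements in fixed
#' order, one row per sample, lower-case species labels. The content kind
#' is taken from the `kind` argument unless the file carries a
#' `#kind: <absolute|relative>` comment line above the header (written by
#' [write_profiles()]).
#'
#' @param path CSV file path.
#' @param kind `"absolute"`, `"relative"`, or `NULL` to require the
#'   embedded metadata line.
#' @return An [element_profile()] table.
#' @export
read_profiles <- function(path, kind = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  skip <- 0L
  if (startsWith(first, "#kind:")) {
    file_kind <- trimws(sub("^#kind:", "", first))
    skip <- 1L
    if (is.null(kind)) kind <- file_kind
  }
  if (is.null(kind)) {
    stop("content kind not given and not recorded in the file header",
         call. = FALSE)
  }
  df <- utils::read.csv(path, skip = skip, stringsAsFactors = FALSE,
                        check.names = FALSE)
  element_profile(df, kind = kind)
}

#' Write an element profile table to CSV
#'
#' Writes the dialect [read_profiles()] accepts, with a `#kind:` metadata
#' line and numeric values formatted at full round-trip precision (17
#' significant digits), so write-then-read reproduces the table exactly.
#'
#' @param table An [element_profile()] table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(table, path) {
  kind <- profile_kind(table)
  panel <- element_panel()
  out <- data.frame(sample_id = as.character(table$sample_id),
                    species = as.character(table$species),
                    stringsAsFactors = FALSE)
  for (el in panel) out[[el]] <- sprintf("%.17g", table[[el]])
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#kind: ", kind), con)
  utils::write.table(out, con, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
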