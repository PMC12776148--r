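#' @include consistency.R
NULL

#' Convert a tabular section to a character matrix and back
#'
#' `tableToMatrix` lays a harmonized table out as a rectangular character
#' matrix: header row first, then one row per data row, duplicated column
#' names retained as duplicated header cells. `matrixToTable` inverts it
#' losslessly. Units and the Factors preamble live on the table object, not
#' in the matrix; carry the source table through the `template` argument to
#' restore them.
#'
#' @param table A [MWTabTable-class] whose rows are harmonized (every row
#'   carries exactly the header's columns).
#' @return For `tableToMatrix`, a character matrix with `length(rows) + 1`
#'   rows.
#' @export
tableToMatrix <- function(table) {
  stopifnot(is(table, "MWTabTable"))
  ncol <- length(table@columns)
  for (r in table@rows) {
    if (!identical(r@keys, table@columns))
      stop("table rows are not harmonized against the header; ",
           "matrix layout requires rectangular data")
  }
  m <- matrix("", nrow = length(table@rows) + 1, ncol = ncol)
  m[1, ] <- table@columns
  for (i in seq_along(table@rows))
    m[i + 1, ] <- vapply(table@rows[[i]]@values, cellText, character(1))
  m
}

#' @rdname tableToMatrix
#' @param m Character matrix as produced by `tableToMatrix`.
#' @param template Optional [MWTabTable-class] supplying role, units and
#'   factors row.
#' @return For `matrixToTable`, a [MWTabTable-class].
#' @export
matrixToTable <- function(m, template = NULL) {
  stopifnot(is.matrix(m), nrow(m) >= 1)
  columns <- as.character(m[1, ])
  rows <- lapply(seq_len(nrow(m) - 1L), function(i)
    DuplicatesMap(columns, as.list(as.character(m[i + 1, ]))))
  MWTabTable(
    role = if (is.null(template)) "METABOLITES" else template@role,
    units = if (is.null(template)) character(0) else template@units,
    columns = columns,
    factorsRow = if (is.null(template)) character(0) else template@factorsRow,
    rows = rows)
}
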