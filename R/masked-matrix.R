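#' Numeric feature table with an explicit missingness mask
#'
#' The container exchanged by every stage of the package: an `N x M` numeric
#' matrix of feature values together with a logical mask marking missing
#' cells.  Masked cells carry `NA` in `values` and are never read as data.
#'
#' @param values Numeric matrix (or data frame coercible to one); rows are
#'   instances (e.g. patients), columns are features.  Cells that are `NA`
#'   are treated as missing.
#' @param mask Optional logical matrix of the same shape, `TRUE` = missing.
#'   Defaults to `is.na(values)`.  Cells flagged missing are set to `NA`
#'   regardless of the value supplied.
#' @return An object of class `masked_matrix` with components `values`,
#'   `mask` and `column_names`.
#' @examples
#' x <- matrix(rnorm(20), 5, 4)
#' x[2, 3] <- NA
#' mm <- masked_matrix(x)
#' n_missing(mm)
#' @export
masked_matrix <- function(values, mask = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  stopifnot(is.matrix(values), is.numeric(values))
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("'values' must have at least one row and one column", call. = FALSE)
  if (is.null(mask)) mask <- is.na(values)
  stopifnot(is.logical(mask), identical(dim(mask), dim(values)))
  values[mask] <- NA_real_
  if (any(is.na(values) & !mask))
    stop("'values' contains NA cells not flagged in 'mask'", call. = FALSE)
  cn <- colnames(values)
  if (is.null(cn)) cn <- paste0("V", seq_len(ncol(values)))
  colnames(values) <- colnames(mask) <- cn
  structure(list(values = values, mask = mask, column_names = cn),
            class = "masked_matrix")
}

#' @export
print.masked_matrix <- function(x, ...) {
  cat(sprintf("masked_matrix: %d x %d, %d missing cells (%.1f%%), %d complete rows\n",
              nrow(x$values), ncol(x$values), n_missing(x),
              100 * n_missing(x) / length(x$values),
              sum(complete_rows(x))))
  invisible(x)
}

#' @export
dim.masked_matrix <- function(x) dim(x$values)

#' Count of missing cells in a masked matrix
#' @param x A `masked_matrix`.
#' @return Integer count of masked cells.
#' @export
n_missing <- function(x) {
  stopifnot(inherits(x, "masked_matrix"))
  sum(x$mask)
}

#' Logical index of fully observed rows
#' @param x A `masked_matrix`.
#' @return Logical vector, `TRUE` for rows with no missing cell.
#' @export
complete_rows <- function(x) {
  stopifnot(inherits(x, "masked_matrix"))
  rowSums(x$mask) == 0L
}

## Subset rows, preserving the class.
mm_rows <- function(x, i) masked_matrix(x$values[i, , drop = FALSE],
                                        x$mask[i, , drop = FALSE])

#' Read a delimited feature table into a masked matrix
#'
#' Reads a CSV/TSV file with a header row; cells equal to any of the
#' `na_strings` (or empty) become missing.
#'
#' @param file Path to a delimited text file.
#' @param sep Field separator; `","` (default) or `"\t"`.
#' @param na_strings Character vector of markers treated as missing.
#' @return A [masked_matrix()].
#' @export
read_masked_csv <- function(file, sep = ",", na_strings = c("", "NA", "NaN")) {
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          na.strings = na_strings, check.names = FALSE)
  masked_matrix(as.matrix(df))
}

#' Write a masked matrix (or plain matrix) as CSV
#'
#' Missing cells are written as the string `"NA"`.
#'
#' @param x A `masked_matrix` or numeric matrix.
#' @param file Output path.
#' @export
write_masked_csv <- function(x, file) {
  m <- if (inherits(x, "masked_matrix")) x$values else x
  utils::write.csv(as.data.frame(m), file, row.names = FALSE)
  invisible(file)
}
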