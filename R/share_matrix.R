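#' Row-stochastic share matrix
#'
#' A `share_matrix` is a numeric matrix of dimensionless fractions in which
#' every row sums to one: market shares of product categories per year
#' (years x categories), splits of a product category across material forms
#' (categories x forms), or their composition (years x forms).
#'
#' @param values numeric matrix with all entries in `[0, 1]`.
#' @param row_labels,col_labels character vectors of identifiers (years or
#'   category/form names).  Taken from `dimnames(values)` when omitted.
#' @param tol tolerance on the row sums (default `1e-9`).
#'
#' @return a matrix of class `"share_matrix"` with row and column names set.
#' @examples
#' share_matrix(rbind(c(0.5, 0.5), c(0.2, 0.8)),
#'              row_labels = c("2029", "2030"),
#'              col_labels = c("composites", "energy"))
#' @export
share_matrix <- function(values, row_labels = rownames(values),
                         col_labels = colnames(values), tol = 1e-9) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("share matrix values must be numeric", call. = FALSE)
  }
  if (is.null(row_labels)) row_labels <- as.character(seq_len(nrow(values)))
  if (is.null(col_labels)) col_labels <- as.character(seq_len(ncol(values)))
  if (length(row_labels) != nrow(values) || length(col_labels) != ncol(values)) {
    stop("label length does not match matrix dimensions", call. = FALSE)
  }
  dimnames(values) <- list(as.character(row_labels), as.character(col_labels))
  class(values) <- c("share_matrix", "matrix")
  validate_share_matrix(values, tol = tol)
  values
}

#' Validate a share matrix
#'
#' Checks that all entries lie in `[0, 1]` and that every row sums to one
#' within `tol`.  Errors name the offending rows.
#'
#' @param x matrix to check.
#' @param tol tolerance on the row sums.
#' @return `x`, invisibly.
#' @export
validate_share_matrix <- function(x, tol = 1e-9) {
  if (any(!is.finite(x))) {
    stop("share matrix contains non-finite entries", call. = FALSE)
  }
  if (any(x < -tol) || any(x > 1 + tol)) {
    stop("share matrix entries must lie in [0, 1]", call. = FALSE)
  }
  rs <- rowSums(x)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad) > 0L) {
    stop(sprintf(
      "share matrix rows do not sum to 1 (tol %.1e): %s",
      tol,
      paste(sprintf("'%s' (sum %.6f)", rownames(x)[bad], rs[bad]),
            collapse = ", ")
    ), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.share_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("share matrix: %d rows x %d columns (rows sum to 1)\n",
              nrow(x), ncol(x)))
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Read / write a share matrix as CSV
#'
#' The CSV dialect has the row label in the first column, column labels in
#' the header, and decimal fractions as values.  Row sums are validated on
#' read with a configurable tolerance.
#'
#' @param path file path.
#' @param tol row-sum tolerance passed to [validate_share_matrix()].
#' @return [read_share_matrix()] returns a `share_matrix`;
#'   [write_share_matrix()] returns `path` invisibly.
#' @export
read_share_matrix <- function(path, tol = 1e-9) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("share matrix CSV needs a label column and at least one value column",
                          call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  share_matrix(m, row_labels = as.character(df[[1L]]),
               col_labels = colnames(df)[-1L], tol = tol)
}

#' @rdname read_share_matrix
#' @param x a `share_matrix`.
#' @export
write_share_matrix <- function(x, path) {
  df <- data.frame(label = rownames(x), unclass(x), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
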