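#' Labeled time-series matrix
#'
#' Container for m time series (rows) observed at n common, equally
#' spaced time points (columns). Missing observations are `NA`; they are
#' never silently treated as zero. Most users construct one by reading a
#' delimited file with [read_ts_matrix()] or simulating with
#' [null_matrix()].
#'
#' @param values numeric m x n matrix, `NA` for missing observations.
#' @param row_labels character vector of m unique series identifiers;
#'   defaults to existing rownames or `s1..sm`.
#' @param col_labels character vector of n unique time-point labels;
#'   defaults to existing colnames or `t1..tn`.
#'
#' @return A numeric matrix of class `ts_matrix` with the labels as
#'   dimnames.
#' @examples
#' ts_matrix(rbind(a = c(1, 2, NA, 4), b = c(0, 1, 0, 2)))
#' @export
ts_matrix <- function(values, row_labels = NULL, col_labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  m <- nrow(values)
  n <- ncol(values)
  if (m < 1L || n < 2L) {
    stop("a ts_matrix needs m >= 1 series and n >= 2 time points",
         call. = FALSE)
  }
  if (is.null(row_labels)) {
    row_labels <- rownames(values)
    if (is.null(row_labels)) row_labels <- paste0("s", seq_len(m))
  }
  if (is.null(col_labels)) {
    col_labels <- colnames(values)
    if (is.null(col_labels)) col_labels <- paste0("t", seq_len(n))
  }
  row_labels <- as.character(row_labels)
  col_labels <- as.character(col_labels)
  if (length(row_labels) != m || anyDuplicated(row_labels)) {
    stop("`row_labels` must be ", m, " unique identifiers", call. = FALSE)
  }
  if (length(col_labels) != n || anyDuplicated(col_labels)) {
    stop("`col_labels` must be ", n, " unique identifiers", call. = FALSE)
  }
  if (any(!is.finite(values) & !is.na(values))) {
    stop("`values` must be finite numbers or NA", call. = FALSE)
  }
  dimnames(values) <- list(row_labels, col_labels)
  class(values) <- c("ts_matrix", "matrix", "array")
  values
}

as_ts_matrix <- function(x) {
  if (inherits(x, "ts_matrix")) x else ts_matrix(as.matrix(x))
}

#' @export
print.ts_matrix <- function(x, ...) {
  v <- unclass(x)
  cat(sprintf("ts_matrix: %d series x %d time points (%d missing)\n",
              nrow(v), ncol(v), sum(is.na(v))))
  utils::str(v, give.attr = FALSE)
  invisible(x)
}

#' Read / write a delimited time-series matrix
#'
#' Plain-text matrix layout: one header row of time-point labels, then
#' one row per series whose first field is the series label. Fields are
#' separated by `delimiter`; empty fields, `NA` and `NaN` are read as
#' missing.
#'
#' @param path file path.
#' @param delimiter single field-separator character (default tab).
#' @param missing character vector of markers to read as missing.
#'
#' @return `read_ts_matrix()` returns a [ts_matrix()];
#'   `write_ts_matrix()` writes `x` and returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_ts_matrix(ts_matrix(rbind(a = 1:3, b = c(2, NA, 0))), f)
#' read_ts_matrix(f)
#' @export
read_ts_matrix <- function(path, delimiter = "\t",
                           missing = c("", "NA", "NaN")) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  if (file.size(path) == 0) {
    stop("input file is empty: ", path, call. = FALSE)
  }
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          row.names = 1L, na.strings = missing,
                          check.names = FALSE, comment.char = "",
                          quote = "\"", stringsAsFactors = FALSE)
  vals <- as.matrix(df)
  if (!is.numeric(vals)) {
    stop("non-numeric values in ", path, call. = FALSE)
  }
  ts_matrix(vals, rownames(df), colnames(df))
}

#' @param x a [ts_matrix()] (or coercible matrix) to write.
#' @rdname read_ts_matrix
#' @export
write_ts_matrix <- function(x, path, delimiter = "\t") {
  x <- as_ts_matrix(x)
  v <- unclass(x)
  df <- data.frame(label = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- ""
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}
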