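#' Interpolate missing observations
#'
#' Fills each missing entry from its nearest observed temporal
#' neighbours: interior gaps are interpolated linearly between the
#' closest observed point on each side (which for a single-point gap is
#' exactly the average of the two nearest observations), and a missing
#' run at either boundary is filled with the single nearest observed
#' value. Idempotent: a complete matrix passes through unchanged.
#'
#' @param x a [ts_matrix()] (or coercible matrix), `NA` marking missing
#'   observations.
#' @return A [ts_matrix()] with no missing entries.
#' @examples
#' m <- ts_matrix(rbind(a = c(1, NA, 3), b = c(NA, 5, 7)))
#' interpolate_missing(m)
#' @export
interpolate_missing <- function(x) {
  x <- as_ts_matrix(x)
  v <- unclass(x)
  n <- ncol(v)
  for (r in seq_len(nrow(v))) {
    row <- v[r, ]
    obs <- which(!is.na(row))
    if (length(obs) < 2L) {
      stop(sprintf("series '%s' has %d observed value(s); at least 2 are needed to interpolate",
                   rownames(v)[r], length(obs)), call. = FALSE)
    }
    if (length(obs) < n) {
      v[r, ] <- stats::approx(obs, row[obs], xout = seq_len(n),
                              method = "linear", rule = 2)$y
    }
  }
  ts_matrix(v, rownames(v), colnames(v))
}

#' Remove series dominated by zeros
#'
#' Drops every series in which the fraction of exactly-zero time steps
#' exceeds `max_zero_fraction` (strict inequality: a series with exactly
#' that fraction is retained). Zeros are counted in the raw
#' (interpolated) values, before any standardization; the rule targets
#' sparse count data such as taxon abundances, where a mostly-zero row
#' carries little local-similarity signal but many spurious ties.
#'
#' @param x a complete (interpolated) [ts_matrix()].
#' @param max_zero_fraction maximum tolerated fraction of zero entries
#'   per series, in `[0, 1)`; default 0.25.
#' @return A list with components `matrix` (the retained series, a
#'   [ts_matrix()]) and `removed` (character vector of dropped labels).
#' @examples
#' m <- ts_matrix(rbind(a = c(0, 0, 1, 2), b = c(0, 1, 2, 3)))
#' filter_zero_rows(m)
#' @export
filter_zero_rows <- function(x, max_zero_fraction = 0.25) {
  x <- as_ts_matrix(x)
  v <- unclass(x)
  if (anyNA(v)) {
    stop("matrix still has missing values; run interpolate_missing() first",
         call. = FALSE)
  }
  if (!is.numeric(max_zero_fraction) || length(max_zero_fraction) != 1L ||
      max_zero_fraction < 0 || max_zero_fraction >= 1) {
    stop("`max_zero_fraction` must be a single number in [0, 1)",
         call. = FALSE)
  }
  zero_frac <- rowMeans(v == 0)
  keep <- zero_frac <= max_zero_fraction
  removed <- rownames(v)[!keep]
  if (!any(keep)) {
    stop("all series removed by the zero-fraction filter", call. = FALSE)
  }
  list(matrix = ts_matrix(v[keep, , drop = FALSE]), removed = removed)
}

#' Standardize series to mean 0, population variance 1
#'
#' Each series is centred by its mean and scaled by its population
#' standard deviation (divisor n, not n - 1), the normalization under
#' which a series' squared values sum to n. This makes the LSA
#' self-comparison exactly 1, bounds every |LSA| by 1
#' (Cauchy-Schwarz), and sets Var(XY) = 1 in the analytic p-value
#' bound. Idempotent to numerical tolerance.
#'
#' @param x a complete [ts_matrix()] (or coercible matrix), or a single
#'   numeric series.
#' @return An object of the same shape with every series standardized.
#' @examples
#' standardize(c(0, 2))           # -1, 1
#' standardize(ts_matrix(rbind(a = c(1, 2, 3), b = c(5, 5, 8))))
#' @export
standardize <- function(x) {
  if (is.numeric(x) && is.null(dim(x))) {
    return(standardize_row(x, "x"))
  }
  x <- as_ts_matrix(x)
  v <- unclass(x)
  if (anyNA(v)) {
    stop("matrix still has missing values; run interpolate_missing() first",
         call. = FALSE)
  }
  for (r in seq_len(nrow(v))) {
    v[r, ] <- standardize_row(v[r, ], rownames(v)[r])
  }
  ts_matrix(v, rownames(v), colnames(v))
}

standardize_row <- function(row, label) {
  check_series(row, label)
  mu <- mean(row)
  s <- sqrt(mean((row - mu)^2))
  if (s == 0) {
    stop(sprintf("series '%s' is constant: zero variance, cannot standardize",
                 label), call. = FALSE)
  }
  (row - mu) / s
}

# TRUE when every row is standardized to within `tol`.
is_standardized <- function(v, tol = 1e-8) {
  mu <- rowMeans(v)
  s2 <- rowMeans((v - mu)^2)
  all(abs(mu) <= tol) && all(abs(s2 - 1) <= tol)
}
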