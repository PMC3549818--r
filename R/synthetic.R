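#' Simulate a null time-series matrix
#'
#' Generates m independent series of n iid draws — the no-association
#' null under which the p-value bound is calibrated. `uniform01` (draws
#' on `[0, 1)`) matches large simulated null studies of this kind;
#' standardization removes location and scale, so the support choice is
#' immaterial downstream. Optional fractions of entries can be forced to
#' exact zero (to exercise the zero-fraction filter) or flagged missing
#' (to exercise interpolation). Bitwise reproducible for a fixed seed;
#' the caller's RNG state is untouched.
#'
#' @param m number of series (rows), >= 1.
#' @param n series length, >= 2.
#' @param distribution `"uniform01"` or `"standard_normal"`.
#' @param zero_fraction fraction of entries set to exact 0, in `[0, 1)`.
#' @param missing_fraction fraction of entries flagged missing (`NA`),
#'   in `[0, 1)`; applied after zeroing, on distinct entries.
#' @param seed integer seed.
#' @return A [ts_matrix()] with zero-padded labels (`s001`, ...).
#' @examples
#' null_matrix(m = 3, n = 8, seed = 7)
#' @export
null_matrix <- function(m, n, distribution = c("uniform01", "standard_normal"),
                        zero_fraction = 0, missing_fraction = 0, seed = 1L) {
  distribution <- match.arg(distribution)
  m <- check_count(m, "m", min = 1L)
  n <- check_count(n, "n", min = 2L)
  for (f in c(zero_fraction, missing_fraction)) {
    if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f < 0 || f >= 1) {
      stop("fractions must be single numbers in [0, 1)", call. = FALSE)
    }
  }
  with_seed(seed, {
    vals <- switch(distribution,
                   uniform01 = stats::runif(m * n),
                   standard_normal = stats::rnorm(m * n))
    vals <- matrix(vals, nrow = m, ncol = n)
    total <- m * n
    n_zero <- round(zero_fraction * total)
    n_miss <- round(missing_fraction * total)
    marked <- sample.int(total, n_zero + n_miss)
    if (n_zero > 0) vals[marked[seq_len(n_zero)]] <- 0
    if (n_miss > 0) vals[marked[n_zero + seq_len(n_miss)]] <- NA_real_
    ts_matrix(vals,
              row_labels = sprintf("s%0*d", nchar(m), seq_len(m)),
              col_labels = sprintf("t%0*d", nchar(n), seq_len(n)))
  })
}

#' Simulate a lead-lag coupled pair of series
#'
#' Series `a` is iid standard normal; on the overlap, series `b` at time
#' t is `coupling * a[t - lag] + noise_sd * e[t]` with iid standard
#' normal noise `e`, and iid standard normal where `t - lag` falls
#' outside the series. With `coupling = 1`, `noise_sd = 0` the pair is a
#' perfect copy shifted by `lag`, the textbook lead-lag signal the LSA
#' scan is designed to recover. Raw (unstandardized) series are
#' returned.
#'
#' @param n series length, >= 2.
#' @param lag shift in time steps, `|lag| <= n - 2`; positive lag means
#'   `b` trails `a`.
#' @param coupling coupling strength in `[0, 1]`; 0 gives independent
#'   pairs.
#' @param noise_sd standard deviation of the additive noise, >= 0.
#' @param seed integer seed.
#' @return `list(a = , b = )` of numeric series of length n.
#' @examples
#' p <- lagged_pair(n = 50, lag = 2, coupling = 1, noise_sd = 0.05, seed = 1)
#' lsa_pair(standardize(p$a), standardize(p$b), D = 3)
#' @export
lagged_pair <- function(n, lag, coupling, noise_sd, seed = 1L) {
  n <- check_count(n, "n", min = 2L)
  if (!is.numeric(lag) || length(lag) != 1L || lag != round(lag) ||
      abs(lag) > n - 2L) {
    stop("`lag` must be an integer with |lag| <= n - 2", call. = FALSE)
  }
  if (!is.numeric(coupling) || length(coupling) != 1L ||
      coupling < 0 || coupling > 1) {
    stop("`coupling` must be in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop("`noise_sd` must be >= 0", call. = FALSE)
  }
  lag <- as.integer(lag)
  with_seed(seed, {
    a <- stats::rnorm(n)
    eps <- stats::rnorm(n)
    fill <- stats::rnorm(n)
    b <- numeric(n)
    for (t in seq_len(n)) {
      s <- t - lag
      b[t] <- if (s >= 1L && s <= n) {
        coupling * a[s] + noise_sd * eps[t]
      } else {
        fill[t]
      }
    }
    list(a = a, b = b)
  })
}

#' Empirical null tail of |LSA|
#'
#' Simulates independent standard-normal pairs, standardizes each
#' series, computes |LSA| with lag bound D, and returns the empirical
#' exceedance fraction P(|LSA| > x) at each grid point. This is the
#' Monte-Carlo yardstick against which the analytic bound's
#' conservativeness is checked: at every x where the bound is below 1,
#' the empirical tail should not exceed it (up to binomial noise).
#'
#' @param n series length, >= 2.
#' @param D maximum lag, `0 <= D <= n - 2`.
#' @param num_pairs number of simulated pairs, >= 100.
#' @param grid numeric vector of non-negative thresholds x.
#' @param seed integer seed.
#' @return Numeric vector of tail probabilities, one per grid point,
#'   monotone non-increasing in x.
#' @examples
#' empirical_null_tail(n = 50, D = 0, num_pairs = 200,
#'                     grid = c(0, 0.2, 0.4), seed = 1)
#' @export
empirical_null_tail <- function(n, D, num_pairs, grid, seed = 1L) {
  n <- check_count(n, "n", min = 2L)
  D <- check_lag(D, n)
  num_pairs <- check_count(num_pairs, "num_pairs", min = 100L)
  if (!is.numeric(grid) || length(grid) == 0L || anyNA(grid) ||
      any(!is.finite(grid)) || any(grid < 0)) {
    stop("`grid` must be finite, non-negative numeric", call. = FALSE)
  }
  stats_abs <- with_seed(seed, {
    X <- matrix(stats::rnorm(num_pairs * n), nrow = num_pairs)
    Y <- matrix(stats::rnorm(num_pairs * n), nrow = num_pairs)
    X <- t(apply(X, 1L, standardize_row, label = "x"))
    Y <- t(apply(Y, 1L, standardize_row, label = "y"))
    abs(lsa_stat_rows_cpp(X, Y, D))
  })
  vapply(grid, function(g) mean(stats_abs > g), numeric(1))
}
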