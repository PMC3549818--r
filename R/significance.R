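#' One-sided normal distribution function
#'
#' G(t) = sqrt(2/pi) * integral of exp(-s^2/2) from 0 to t
#'      = 2 * pnorm(t) - 1 for t >= 0, and 0 for t < 0:
#' the CDF of the absolute value of a standard normal. This is the
#' limiting distribution of the maximum of scaled partial sums that
#' underlies the analytic LSA p-value bound.
#'
#' @param t numeric vector, finite.
#' @return Values in `[0, 1]`.
#' @examples
#' one_sided_normal_G(c(0, 1, -2))
#' @export
one_sided_normal_G <- function(t) {
  if (!is.numeric(t) || length(t) == 0L || anyNA(t) || any(!is.finite(t))) {
    stop("`t` must be finite numeric", call. = FALSE)
  }
  ifelse(t < 0, 0, 2 * stats::pnorm(t) - 1)
}

#' Asymptotic upper bound on the LSA p-value
#'
#' Closed-form conservative bound on P(|LSA| > x) under the null of
#' independent series, replacing the permutation test. Two variants are
#' provided:
#'
#' * `"table"` (default): `min(1, 2n * (1 - pnorm(x * sqrt(n / variance))))`.
#'   This is the bound evaluated with the lag terms collapsed (D = 0)
#'   and a single one-sided tail factor; it is the form whose values
#'   match published reference tables of the bound, and is the tighter
#'   of the two.
#' * `"theorem"`: the literal union-bound expression
#'   `min(1, 2 * (n^2 - (n-D-1)*(n-D)) * (1 - G(x * sqrt(n / variance))))`
#'   with G the one-sided normal CDF; at least as conservative as
#'   `"table"` for every D >= 0.
#'
#' Both are monotone non-increasing in `x` and capped at 1. The bound is
#' asymptotic in n; below roughly 30 time points it is loose (a warning
#' is emitted) but remains conservative, so short series do not produce
#' easy false positives.
#'
#' @param x statistic magnitude threshold(s), non-negative.
#' @param n series length, >= 2.
#' @param D maximum lag used in the scan (enters the `"theorem"`
#'   variant only), `0 <= D <= n - 2`.
#' @param variance variance of the elementwise product of one pair of
#'   observations; 1 after [standardize()]. For unstandardized input
#'   supply the sample variance of `x * y`.
#' @param variant `"table"` or `"theorem"`.
#' @return P-value bound(s) in `[0, 1]`, same length as `x`.
#' @examples
#' pvalue_bound(0.41, n = 30)                      # 0.742
#' pvalue_bound(0.35, n = 50)                      # 0.666
#' pvalue_bound(0.35, n = 50, D = 3, variant = "theorem")
#' @export
pvalue_bound <- function(x, n, D = 0L, variance = 1,
                         variant = c("table", "theorem")) {
  variant <- match.arg(variant)
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) ||
      any(!is.finite(x)) || any(x < 0)) {
    stop("`x` must be finite and non-negative", call. = FALSE)
  }
  n <- check_count(n, "n", min = 2L)
  D <- check_lag(D, n)
  if (!is.numeric(variance) || length(variance) != 1L ||
      !is.finite(variance) || variance <= 0) {
    stop("`variance` must be a single positive number", call. = FALSE)
  }
  if (n < 30L) {
    warning("n < 30: the asymptotic p-value bound is loose for short series",
            call. = FALSE)
  }
  t <- x * sqrt(n / variance)
  # 1 - G(t) = 2 * (1 - pnorm(t)) for t >= 0; evaluated via the upper
  # tail directly so the deep tail does not cancel to zero
  upper <- 2 * stats::pnorm(t, lower.tail = FALSE)
  if (variant == "table") {
    pmin(1, n * upper)
  } else {
    pmin(1, 2 * (n^2 - (n - D - 1) * (n - D)) * upper)
  }
}

#' Permutation-test p-value for an LSA statistic
#'
#' Monte-Carlo comparator for [pvalue_bound()]: shuffles the time
#' indices of one series (`"shuffle_one"`, the default; shuffling both
#' adds cost without changing the null) or of both independently
#' (`"shuffle_both"`), recomputes |LSA| for each permutation, and
#' returns the add-one estimator `(1 + k) / (1 + num_perms)` where k
#' counts permuted statistics at least as large as the observed one.
#' The add-one form avoids zero p-values. Reproducible for a fixed
#' `seed`; the caller's RNG state is left untouched.
#'
#' @inheritParams lsa_pair
#' @param num_perms number of permutations, >= 1.
#' @param seed integer seed for the permutation stream.
#' @param scheme `"shuffle_one"` or `"shuffle_both"`.
#' @return A p-value in `(0, 1]`.
#' @examples
#' x <- standardize(sin(1:30))
#' permutation_pvalue(x, x, D = 0, num_perms = 199, seed = 1)
#' @export
permutation_pvalue <- function(x, y, D = 0L, num_perms = 999L, seed = 1L,
                               scheme = c("shuffle_one", "shuffle_both")) {
  scheme <- match.arg(scheme)
  num_perms <- check_count(num_perms, "num_perms", min = 1L)
  obs <- abs(lsa_pair(x, y, D)$statistic)
  n <- length(x)
  x <- as.numeric(x)
  y <- as.numeric(y)
  perm_stats <- with_seed(seed, {
    X <- matrix(x, nrow = num_perms, ncol = n, byrow = TRUE)
    Y <- matrix(0, nrow = num_perms, ncol = n)
    for (k in seq_len(num_perms)) {
      Y[k, ] <- y[sample.int(n)]
      if (scheme == "shuffle_both") X[k, ] <- x[sample.int(n)]
    }
    lsa_stat_rows_cpp(X, Y, as.integer(D))
  })
  (1 + sum(abs(perm_stats) >= obs)) / (1 + num_perms)
}

#' Bonferroni-corrected significance level
#'
#' Family-wise error control for an all-pairs screen: the per-test level
#' is `alpha / num_tests`. [all_pairs_lsa()] uses
#' `num_tests = choose(m, 2)`, the number of unordered pairs actually
#' tested.
#'
#' @param alpha nominal family-wise level, in `(0, 1]`.
#' @param num_tests number of tests, >= 1.
#' @return The corrected per-test level.
#' @examples
#' bonferroni_alpha(0.05, choose(1000, 2))
#' @export
bonferroni_alpha <- function(alpha, num_tests) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha > 1) {
    stop("`alpha` must be in (0, 1]", call. = FALSE)
  }
  num_tests <- check_count(num_tests, "num_tests", min = 1L)
  alpha / num_tests
}
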