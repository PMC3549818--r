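# Shared fixtures, built in code at test time.

# a random series standardized to mean 0, population variance 1
rand_std <- function(n) standardize(stats::rnorm(n))

# a small matrix with one planted lead-lag pair (rows 1 and 2) among nulls
planted_matrix <- function(m = 5, n = 50, lag = 2, coupling = 1,
                           noise_sd = 0.05, seed = 42) {
  pair <- lagged_pair(n, lag, coupling, noise_sd, seed = seed)
  rest <- with_seed2(seed + 1, matrix(stats::rnorm((m - 2) * n), m - 2, n))
  ts_matrix(rbind(pair$a, pair$b, rest),
            row_labels = sprintf("s%02d", seq_len(m)))
}

# local-seed evaluation without touching the session RNG
with_seed2 <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
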