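# Internal validation and RNG helpers.

# Evaluate `code` under a fixed seed without disturbing the caller's RNG
# stream (the global .Random.seed is saved and restored).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  if (x <= .Machine$integer.max) as.integer(x) else x
}

check_series <- function(x, name = "x") {
  if (!is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric vector", name), call. = FALSE)
  }
  if (length(x) < 2L) {
    stop(sprintf("`%s` is degenerate: series need length n >= 2", name),
         call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` contains missing or non-finite values", name),
         call. = FALSE)
  }
  invisible(as.numeric(x))
}

check_series_pair <- function(x, y) {
  check_series(x, "x")
  check_series(y, "y")
  if (length(x) != length(y)) {
    stop(sprintf("length mismatch: x has %d points, y has %d",
                 length(x), length(y)), call. = FALSE)
  }
  invisible(NULL)
}

# Max lag D: 0 <= D <= n - 2.
check_lag <- function(D, n) {
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D != round(D)) {
    stop("`D` must be a single non-negative integer", call. = FALSE)
  }
  D <- as.integer(D)
  if (D < 0L || D > n - 2L) {
    stop(sprintf("`D` must satisfy 0 <= D <= n - 2 (got D = %d, n = %d)",
                 D, n), call. = FALSE)
  }
  D
}
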