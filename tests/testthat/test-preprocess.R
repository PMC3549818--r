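test_that("missing values are filled from nearest observed neighbours", {
  m <- ts_matrix(rbind(a = c(1, NA, 3),
                       b = c(NA, 5, 7)))
  out <- unclass(interpolate_missing(m))
  expect_equal(out["a", ], c(t1 = 1, t2 = 2, t3 = 3))
  expect_equal(out["b", ], c(t1 = 5, t2 = 5, t3 = 7))

  # an interior multi-point gap is the linear interpolant between the
  # nearest observed points on each side
  g <- interpolate_missing(ts_matrix(rbind(a = c(1, NA, NA, 4))))
  expect_equal(unname(unclass(g)[1, ]), c(1, 2, 3, 4))

  # trailing gap takes the nearest observed value
  tr <- interpolate_missing(ts_matrix(rbind(a = c(2, 6, NA, NA))))
  expect_equal(unname(unclass(tr)[1, ]), c(2, 6, 6, 6))
})

test_that("interpolation is idempotent and rejects unrecoverable rows", {
  m <- ts_matrix(rbind(a = c(1, NA, 3, NA, 8), b = c(2, 2, NA, 1, 5)))
  once <- interpolate_missing(m)
  expect_identical(unclass(interpolate_missing(once)), unclass(once))
  expect_false(anyNA(once))
  expect_error(interpolate_missing(ts_matrix(rbind(bad = c(NA, NA, 7)))),
               "bad")
})

test_that("zero-fraction filter removes rows above the threshold, strictly", {
  m <- ts_matrix(rbind(half = c(0, 0, 1, 2),
                       quarter = c(0, 1, 2, 3),
                       none = c(4, 1, 2, 3)))
  out <- filter_zero_rows(m)
  expect_identical(out$removed, "half")
  expect_identical(rownames(out$matrix), c("quarter", "none"))

  expect_error(filter_zero_rows(ts_matrix(rbind(a = c(0, 0, 1)))),
               "all series removed")
  expect_error(filter_zero_rows(ts_matrix(rbind(a = c(NA, 1, 2)))),
               "missing")
})

test_that("mostly non-zero null matrices survive the filter", {
  m <- null_matrix(m = 50, n = 390, zero_fraction = 0.10, seed = 9)
  out <- filter_zero_rows(interpolate_missing(m))
  expect_identical(out$removed, character(0))
  expect_equal(nrow(out$matrix), 50)
})

test_that("standardization gives population mean 0 / variance 1 and is idempotent", {
  expect_equal(standardize(c(1, -1)), c(1, -1))
  expect_equal(standardize(c(0, 2)), c(-1, 1))
  with_seed2(55, {
    for (k in 1:20) {
      v <- rnorm(sample(5:60, 1), mean = runif(1, -5, 5),
                 sd = runif(1, 0.1, 10))
      s <- standardize(v)
      expect_lt(abs(mean(s)), 1e-12)
      expect_lt(abs(mean(s^2) - 1), 1e-12)
      expect_equal(standardize(s), s, tolerance = 1e-12)
    }
  })
  expect_error(standardize(ts_matrix(rbind(flat = c(2, 2, 2)))), "flat")
})

test_that("LSA is invariant to affine rescaling of the raw series", {
  with_seed2(66, {
    a <- rnorm(40)
    b <- rnorm(40)
    r1 <- lsa_pair(standardize(a), standardize(b), D = 2)
    r2 <- lsa_pair(standardize(3.7 * a + 11), standardize(0.2 * b - 4),
                   D = 2)
    expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
    expect_identical(r1$best_lag, r2$best_lag)
  })
})

test_that("pipeline order: zeros are counted before standardization", {
  # after standardization no entry of this row is zero, so the filter
  # must act on the raw values to remove it
  m <- ts_matrix(rbind(sparse = c(0, 0, 0, 1, 2, 3),
                       dense = c(5, 1, 2, 8, 1, 9)))
  out <- filter_zero_rows(m)
  expect_identical(out$removed, "sparse")
  std <- standardize(out$matrix)
  expect_false(any(unclass(std) == 0))
})

test_that("delimited matrices round-trip through write and read", {
  m <- null_matrix(m = 5, n = 12, missing_fraction = 0.1, seed = 3)
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  write_ts_matrix(m, f)
  back <- read_ts_matrix(f)
  expect_equal(unclass(back), unclass(m), tolerance = 1e-12)
  expect_identical(rownames(back), rownames(m))

  f2 <- tempfile(fileext = ".csv")
  on.exit(unlink(f2), add = TRUE)
  write_ts_matrix(m, f2, delimiter = ",")
  expect_equal(unclass(read_ts_matrix(f2, delimiter = ",")), unclass(m),
               tolerance = 1e-12)

  empty <- tempfile()
  file.create(empty)
  on.exit(unlink(empty), add = TRUE)
  expect_error(read_ts_matrix(empty), "empty")
  expect_error(read_ts_matrix(tempfile()), "not found")
})
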