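test_that("two identical series yield one maximally significant edge", {
  x <- rand_std(100)
  m <- ts_matrix(rbind(a = x, b = x))
  e <- all_pairs_lsa(m, D = 0, alpha = 0.001)
  expect_equal(nrow(e), 1)
  expect_equal(e$statistic, 1, tolerance = 1e-12)
  expect_true(e$significant)
  expect_lt(e$p_bound, 1e-12)
})

test_that("edge table covers each unordered pair once in canonical order", {
  m <- standardize(null_matrix(m = 10, n = 40, seed = 8))
  e <- all_pairs_lsa(m, D = 2, alpha = 0.05)
  expect_equal(nrow(e), choose(10, 2))
  expect_true(all(e$label_a < e$label_b))
  expect_false(any(e$label_a == e$label_b))
  expect_equal(anyDuplicated(paste(e$label_a, e$label_b)), 0L)

  # significance flag is exactly the dual filter
  meta <- attr(e, "meta")
  expect_identical(e$significant,
                   e$p_bound <= meta$corrected_alpha &
                     abs(e$statistic) >= meta$lsa_threshold)
  expect_equal(meta$corrected_alpha, 0.05 / choose(10, 2))
})

test_that("results are identical for any workers setting", {
  m <- standardize(null_matrix(m = 12, n = 30, seed = 4))
  runs <- lapply(c(1, 4, 16), function(w) {
    suppressWarnings(all_pairs_lsa(m, D = 3, workers = w))
  })
  expect_identical(runs[[1]], runs[[2]])
  expect_identical(runs[[1]], runs[[3]])
})

test_that("a planted lead-lag pair is the top edge with the planted lag", {
  m <- standardize(planted_matrix(m = 5, n = 50, lag = 2, seed = 13))
  e <- all_pairs_lsa(m, D = 3, alpha = 0.001)
  top <- e[which.max(abs(e$statistic)), ]
  expect_identical(c(top$label_a, top$label_b), c("s01", "s02"))
  expect_equal(abs(top$best_lag), 2)

  # the winning pair agrees with the brute-force oracle
  o <- lsa_pair_oracle(unclass(m)["s01", ], unclass(m)["s02", ], D = 3)
  expect_equal(top$statistic, o$statistic, tolerance = 1e-12)
  expect_equal(abs(o$best_lag), 2)
})

test_that("unstandardized or inconsistent input is rejected", {
  raw <- null_matrix(m = 4, n = 20, seed = 1)
  expect_error(suppressWarnings(all_pairs_lsa(raw, D = 2)), "standardize")
  expect_error(all_pairs_lsa(standardize(raw)[1, , drop = FALSE], D = 2),
               "at least 2")
})

test_that("SIF export encodes edge signs and empty tables are valid", {
  x <- rand_std(60)
  m <- ts_matrix(rbind(A = x, B = x, C = -x))
  e <- all_pairs_lsa(m, D = 0, alpha = 0.001)
  f <- tempfile(fileext = ".sif")
  on.exit(unlink(f))
  export_network(e, f, format = "sif")
  lines <- readLines(f)
  expect_true("A +ls B" %in% lines)
  expect_true("A -ls C" %in% lines)

  # empty significant set: header-only TSV, empty SIF, parseable GraphML
  e0 <- all_pairs_lsa(standardize(null_matrix(4, 40, seed = 2)),
                      D = 0, alpha = 1e-6)
  expect_equal(sum(e0$significant), 0)
  fs <- tempfile(fileext = ".sif")
  ft <- tempfile(fileext = ".tsv")
  fg <- tempfile(fileext = ".graphml")
  on.exit(unlink(c(fs, ft, fg)), add = TRUE)
  export_network(e0, fs, format = "sif")
  expect_identical(readLines(fs), character(0))
  export_network(e0, ft, format = "edge_attr_tsv")
  expect_equal(length(readLines(ft)), 1L)  # header only
  export_network(e0, fg, format = "graphml")
  g0 <- igraph::read_graph(fg, format = "graphml")
  expect_equal(igraph::ecount(g0), 0)
  expect_equal(igraph::vcount(g0), 4)

  expect_error(export_network(e, f, format = "dot"), "arg")
})

test_that("GraphML export of a wide matrix round-trips through igraph", {
  # emulates a long abundance table (many time points, permissive screen)
  m <- standardize(null_matrix(m = 40, n = 390, seed = 21))
  e <- all_pairs_lsa(m, D = 3, alpha = 0.05, correction = "none")
  f <- tempfile(fileext = ".graphml")
  on.exit(unlink(f))
  export_network(e, f, format = "graphml")
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::ecount(g), sum(e$significant))
  expect_equal(igraph::vcount(g), 40)
  expect_true("statistic" %in% igraph::edge_attr_names(g))
})

test_that("optional permutation column is populated and order-independent", {
  m <- standardize(null_matrix(m = 4, n = 30, seed = 6))
  e <- all_pairs_lsa(m, D = 2, alpha = 0.05, perms = 49, seed = 10)
  expect_true(all(e$p_perm > 0 & e$p_perm <= 1))
  e2 <- all_pairs_lsa(m, D = 2, alpha = 0.05, perms = 49, seed = 10)
  expect_identical(e$p_perm, e2$p_perm)
})
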