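#' All-pairs LSA screen
#'
#' Scores every unordered pair of series with [lsa_pair()], attaches the
#' analytic p-value bound at the observed |statistic|, and flags
#' significance. A pair is significant when its p-value bound is at or
#' below the (optionally Bonferroni-corrected) level AND its |statistic|
#' reaches `lsa_threshold` — the dual filter used when drawing
#' co-occurrence networks. Pairs are enumerated once in a fixed
#' canonical order (labels sorted bytewise), so output is deterministic;
#' `workers` is accepted for interface compatibility but the scan runs
#' in serial compiled code, whose result is identical for any value.
#'
#' The O(m^2 n (2D+1)) scan with the closed-form bound replaces the
#' O(p m^2 n) permutation approach; an optional permutation p-value
#' column (`perms > 0`) is offered for comparison on small m.
#'
#' @param series standardized series: a [ts_matrix()] or numeric matrix
#'   with rows standardized to mean 0, population variance 1 (see
#'   [standardize()]); m >= 2 rows.
#' @param D maximum time lag searched, `0 <= D <= n - 2`.
#' @param alpha nominal significance level.
#' @param correction `"bonferroni"` (divide alpha by `choose(m, 2)`, the
#'   number of tests) or `"none"`.
#' @param lsa_threshold minimum |statistic| for significance (default 0,
#'   no magnitude filter).
#' @param bound_variant p-value bound variant, see [pvalue_bound()].
#' @param perms if > 0, also compute [permutation_pvalue()] with this
#'   many permutations per pair (column `p_perm`); costly for large m.
#' @param seed base seed for the optional permutation column; pair k
#'   uses `seed + k` so results do not depend on evaluation order.
#' @param workers accepted for call-site compatibility; does not change
#'   results.
#' @return A `data.frame` of class `lsa_edges`, one row per unordered
#'   pair with `label_a < label_b`: `label_a`, `label_b`, `statistic`,
#'   `p_bound`, (`p_perm`,) `best_lag`, `win_start`, `win_end`,
#'   `significant`. Screen settings and labels are stored in
#'   `attr(, "meta")`.
#' @examples
#' m <- standardize(null_matrix(m = 6, n = 40, seed = 1))
#' e <- all_pairs_lsa(m, D = 3, alpha = 0.05)
#' head(e)
#' @export
all_pairs_lsa <- function(series, D = 3L, alpha = 0.05,
                          correction = c("bonferroni", "none"),
                          lsa_threshold = 0,
                          bound_variant = c("table", "theorem"),
                          perms = 0L, seed = 1L, workers = 1L) {
  correction <- match.arg(correction)
  bound_variant <- match.arg(bound_variant)
  v <- unclass(as_ts_matrix(series))
  m <- nrow(v)
  n <- ncol(v)
  if (m < 2L) stop("need at least 2 series", call. = FALSE)
  if (anyNA(v) || any(!is.finite(v))) {
    stop("series contain missing or non-finite values; preprocess first",
         call. = FALSE)
  }
  if (!is_standardized(v)) {
    stop("series are not standardized; call standardize() first",
         call. = FALSE)
  }
  D <- check_lag(D, n)
  if (!is.numeric(lsa_threshold) || length(lsa_threshold) != 1L ||
      !is.finite(lsa_threshold) || lsa_threshold < 0) {
    stop("`lsa_threshold` must be a single non-negative number",
         call. = FALSE)
  }
  check_count(workers, "workers", min = 1L)

  # canonical order: labels sorted bytewise (locale-independent)
  ord <- order(rownames(v), method = "radix")
  v <- v[ord, , drop = FALSE]
  labels <- rownames(v)

  raw <- all_pairs_cpp(v, D)
  num_tests <- nrow(raw)
  corrected_alpha <- if (correction == "bonferroni") {
    bonferroni_alpha(alpha, num_tests)
  } else {
    bonferroni_alpha(alpha, 1L)
  }
  p_bound <- pvalue_bound(abs(raw$statistic), n = n, D = D, variance = 1,
                          variant = bound_variant)
  significant <- p_bound <= corrected_alpha &
    abs(raw$statistic) >= lsa_threshold

  edges <- data.frame(
    label_a = labels[raw$i],
    label_b = labels[raw$j],
    statistic = raw$statistic,
    p_bound = p_bound,
    best_lag = raw$best_lag,
    win_start = raw$win_start,
    win_end = raw$win_end,
    significant = significant,
    stringsAsFactors = FALSE)

  if (perms > 0) {
    perms <- check_count(perms, "perms", min = 1L)
    seed <- check_count(seed, "seed", min = 0L)
    edges$p_perm <- vapply(seq_len(num_tests), function(k) {
      permutation_pvalue(v[raw$i[k], ], v[raw$j[k], ], D = D,
                         num_perms = perms, seed = seed + k)
    }, numeric(1))
    edges <- edges[, c("label_a", "label_b", "statistic", "p_bound",
                       "p_perm", "best_lag", "win_start", "win_end",
                       "significant")]
  }

  attr(edges, "meta") <- list(
    m = m, n = n, D = D, alpha = alpha, correction = correction,
    corrected_alpha = corrected_alpha, lsa_threshold = lsa_threshold,
    bound_variant = bound_variant, perms = as.integer(perms),
    num_tests = num_tests, labels = labels)
  class(edges) <- c("lsa_edges", "data.frame")
  edges
}

#' @export
print.lsa_edges <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf(
    "LSA edge table: %d pairs from %d series (n = %d, D = %d)\n",
    nrow(x), meta$m, meta$n, meta$D))
  cat(sprintf(
    "alpha = %g (%s, per-test %.3g), |LSA| >= %g, bound variant '%s': %d significant\n",
    meta$alpha, meta$correction, meta$corrected_alpha, meta$lsa_threshold,
    meta$bound_variant, sum(x$significant)))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

#' Export an LSA edge table as a network file
#'
#' Writes the significant edges (or all edges with `all_edges = TRUE`)
#' in one of three formats:
#'
#' * `"sif"` — Cytoscape simple interaction format, one
#'   `label_a <+ls|-ls> label_b` line per edge, the interaction type
#'   encoding the statistic's sign;
#' * `"edge_attr_tsv"` — tab-separated table of all edge columns, for
#'   Cytoscape attribute import or further analysis;
#' * `"graphml"` — GraphML with every series as a node and
#'   `statistic`, `p_bound` and `best_lag` edge attributes (written via
#'   the igraph library).
#'
#' @param edges an `lsa_edges` table from [all_pairs_lsa()].
#' @param path output file path.
#' @param format one of `"sif"`, `"edge_attr_tsv"`, `"graphml"`.
#' @param all_edges export every scored pair instead of only the
#'   significant ones.
#' @return `path`, invisibly.
#' @examples
#' m <- standardize(null_matrix(m = 4, n = 40, seed = 1))
#' e <- all_pairs_lsa(m, D = 2, alpha = 0.5, correction = "none")
#' f <- tempfile(fileext = ".sif")
#' export_network(e, f, format = "sif")
#' readLines(f)
#' @export
export_network <- function(edges, path,
                           format = c("edge_attr_tsv", "sif", "graphml"),
                           all_edges = FALSE) {
  format <- match.arg(format)
  if (!inherits(edges, "lsa_edges")) {
    stop("`edges` must come from all_pairs_lsa()", call. = FALSE)
  }
  meta <- attr(edges, "meta")
  sel <- as.data.frame(edges)
  if (!all_edges) sel <- sel[sel$significant, , drop = FALSE]

  if (format == "sif") {
    lines <- if (nrow(sel)) {
      sprintf("%s %s %s", sel$label_a,
              ifelse(sel$statistic >= 0, "+ls", "-ls"), sel$label_b)
    } else {
      character(0)
    }
    writeLines(lines, path)
  } else if (format == "edge_attr_tsv") {
    utils::write.table(sel, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      sel[, c("label_a", "label_b", "statistic", "p_bound", "best_lag")],
      directed = FALSE,
      vertices = data.frame(name = meta$labels, stringsAsFactors = FALSE))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
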