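#' Run the full LSA screening pipeline
#'
#' Reads a delimited time-series matrix, interpolates missing values,
#' removes series with more than `max_zero_fraction` zeros, standardizes
#' the survivors, scores all pairs with [all_pairs_lsa()], exports the
#' requested network formats, and writes a run report echoing every
#' parameter (the report alone suffices to reproduce the run). Outputs
#' are deterministic for a fixed configuration and seed; partial output
#' files are removed if any stage fails.
#'
#' Output files share `output_prefix`: `<prefix>.sif`,
#' `<prefix>.edges.tsv`, `<prefix>.graphml` (as requested by `formats`),
#' plus `<prefix>.report.txt` (human-readable) and
#' `<prefix>.report.tsv` (machine-readable key-value pairs).
#'
#' @param input path to the input matrix (see [read_ts_matrix()]).
#' @param output_prefix path prefix for all outputs.
#' @param delimiter input/output field separator.
#' @param D maximum time lag searched (default 3).
#' @param alpha nominal significance level (default 0.001).
#' @param lsa_threshold minimum |statistic| for significance.
#' @param correction `"bonferroni"` or `"none"`.
#' @param bound_variant `"table"` or `"theorem"` (see [pvalue_bound()]).
#' @param perms permutations per pair for an optional `p_perm` column
#'   (0, the default, disables it).
#' @param workers accepted for interface compatibility; results are
#'   identical for any value.
#' @param seed integer seed (used only when `perms > 0`).
#' @param formats character vector among `"sif"`, `"edge_attr_tsv"`,
#'   `"graphml"`.
#' @param all_edges export all scored pairs, not only significant ones.
#' @param max_zero_fraction zero-fraction filter threshold (default
#'   0.25).
#' @param log_level `"info"`, `"debug"` or `"quiet"`.
#' @return Invisibly, `list(edges, report, files)`: the `lsa_edges`
#'   table, the named report list, and the paths written.
#' @examples
#' mat <- null_matrix(m = 6, n = 40, seed = 2)
#' f <- tempfile(fileext = ".tsv")
#' write_ts_matrix(mat, f)
#' out <- tempfile()
#' res <- run_pipeline(f, out, alpha = 0.05, log_level = "quiet")
#' res$report$significant_edges
#' @export
run_pipeline <- function(input, output_prefix, delimiter = "\t",
                         D = 3L, alpha = 0.001, lsa_threshold = 0,
                         correction = c("bonferroni", "none"),
                         bound_variant = c("table", "theorem"),
                         perms = 0L, workers = 1L, seed = 1L,
                         formats = "edge_attr_tsv", all_edges = FALSE,
                         max_zero_fraction = 0.25,
                         log_level = c("info", "debug", "quiet")) {
  correction <- match.arg(correction)
  bound_variant <- match.arg(bound_variant)
  log_level <- match.arg(log_level)
  formats <- match.arg(formats, c("sif", "edge_attr_tsv", "graphml"),
                       several.ok = TRUE)
  say <- function(...) if (log_level != "quiet") message(sprintf(...))

  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)

  say("reading %s", input)
  mat <- read_ts_matrix(input, delimiter = delimiter)
  m_read <- nrow(mat)

  mat <- interpolate_missing(mat)
  filt <- filter_zero_rows(mat, max_zero_fraction = max_zero_fraction)
  if (length(filt$removed) && log_level == "debug") {
    say("removed by zero filter: %s", paste(filt$removed, collapse = ", "))
  }
  std <- standardize(filt$matrix)
  say("%d series read, %d removed by zero filter, %d analyzed (n = %d)",
      m_read, length(filt$removed), nrow(std), ncol(std))

  edges <- all_pairs_lsa(std, D = D, alpha = alpha,
                         correction = correction,
                         lsa_threshold = lsa_threshold,
                         bound_variant = bound_variant,
                         perms = perms, seed = seed, workers = workers)
  meta <- attr(edges, "meta")
  say("%d pairs tested, %d significant", meta$num_tests,
      sum(edges$significant))

  ext <- c(sif = ".sif", edge_attr_tsv = ".edges.tsv",
           graphml = ".graphml")
  for (fmt in formats) {
    p <- paste0(output_prefix, ext[[fmt]])
    export_network(edges, p, format = fmt, all_edges = all_edges)
    written <- c(written, p)
  }

  report <- list(
    input = input,
    series_read = m_read,
    series_removed_zero_filter = length(filt$removed),
    series_analyzed = meta$m,
    n_time_points = meta$n,
    D = meta$D,
    alpha = alpha,
    correction = correction,
    corrected_alpha = meta$corrected_alpha,
    bound_variant = bound_variant,
    lsa_threshold = lsa_threshold,
    perms = meta$perms,
    workers = as.integer(workers),
    seed = as.integer(seed),
    pairs_tested = meta$num_tests,
    significant_edges = sum(edges$significant),
    formats = paste(formats, collapse = ","),
    package_version = as.character(utils::packageVersion("lsanet")))

  rep_txt <- paste0(output_prefix, ".report.txt")
  writeLines(c("lsanet run report",
               sprintf("%-28s %s", names(report),
                       vapply(report, format, character(1)))),
             rep_txt)
  rep_tsv <- paste0(output_prefix, ".report.tsv")
  utils::write.table(
    data.frame(key = names(report),
               value = vapply(report, format, character(1)),
               stringsAsFactors = FALSE),
    rep_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  written <- c(written, rep_txt, rep_tsv)

  ok <- TRUE
  invisible(list(edges = edges, report = report, files = written))
}
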