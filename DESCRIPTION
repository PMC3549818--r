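Package: lsanet
Title: Local Similarity Analysis of Time Series with an Analytic P-Value Bound
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pairwise local similarity analysis (LSA) for collections of
    time series. Computes the lag-bounded LSA statistic by dynamic
    programming over truncated partial sums, assesses significance through
    a closed-form asymptotic upper bound on the p-value (replacing the
    classical permutation test, which is also provided as a comparator),
    screens all pairs with Bonferroni control, and exports co-occurrence
    networks in SIF, tab-separated and GraphML formats for Cytoscape.
    Includes seeded generators for null matrices and lead-lag coupled
    pairs, plus preprocessing (interpolation of missing values,
    zero-fraction filtering, standardization) for raw abundance tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
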