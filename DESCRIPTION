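Package: temporalmotifs
Title: Exact Census of Temporal Network Motifs in a Delta Time Window
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Exact enumeration and counting of temporal motifs in timestamped
    multigraphs. A temporal motif is a small connected graph whose edge
    timestamps are standardized to ranks; a motif occurs in a target network
    whenever a connected subgraph with at most k nodes and l edges matches its
    topology and chronological order, with all timestamps falling within a
    window of width delta. The census is computed by a seed-and-extend
    backtracking search over edge subsets with canonical-form keyed counting,
    implemented in C++. The package also ships an independent brute-force
    reference counter, a seeded synthetic temporal-graph generator, a
    small-motif universe enumerator for verifying the canonical labeling, and
    a command-line front end that reads whitespace-separated edge lists and
    writes per-motif counts and census summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
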