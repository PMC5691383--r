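Package: asmblend
Title: Assembly Reconciliation, Merging and K-Mer Quality Control for Polyploid Genomes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale tools for reconciling two whole-genome assemblies of a
    large, repeat-rich polyploid genome: containment de-duplication by
    self-alignment, two-assembly bridge merging with gap filling,
    ancestor-guided subgenome partitioning, mutual-best-match consensus
    re-polishing, k-mer uniqueness-ratio and missing-k-mer diagnostics,
    synthetic mate-pair extraction and pair-based structural validation.
    Includes an exact-anchor chaining aligner, NG50 and related assembly
    statistics, and a seeded simulator for polyploid, repeat-rich test
    genomes with recorded ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
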