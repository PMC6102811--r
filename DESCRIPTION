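Package: ccscluster
Title: Clustering of Circular Consensus Sequences for Long Amplicon Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A divide-and-conquer pipeline for single-molecule real-time
    (SMRT) sequencing of pooled long-range PCR amplicons. Per-molecule
    circular consensus sequences (CCS) are built from multi-pass subreads,
    clustered by exact barcode/primer matching in their end windows, and the
    whitelisted raw subreads of each cluster are polished into an
    amplicon-specific consensus; overlapping amplicon consensus sequences
    are then assembled per sample with explicit mismatch (N) rules. Includes
    a SMRT amplicon library simulator with a homopolymer-biased error model
    and a bootstrap harness relating subread depth to consensus and assembly
    accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    stringi,
    tibble,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
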