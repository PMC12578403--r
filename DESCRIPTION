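Package: proxratio
Title: Co-Occurrence Probability Ratios for Spatial Transcriptomics Proximity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies spatial enrichment of one cell category near another in
    imaging-based spatial transcriptomics (Xenium-style cell maps): QC filtering
    of cells and genes, marker-positivity cell categorization, the inclusive-interval
    co-occurrence probability ratio P(exp | reference) / P(exp) with an accelerated
    fixed-radius neighbor search and an exhaustive oracle, subsampling min/max
    confidence intervals, and a paired cross-sample comparison. Includes a
    marked-point-process simulator with planted paracrine enrichment so the whole
    analysis is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
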