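Package: esgamap
Title: Quantitative Genetic Interaction Mapping from Bacterial Colony-Array Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantitative synthetic genetic array (eSGA)
    screens of arrayed double mutants scored by colony size under multiple
    growth conditions. Provides spatial plate normalization (median-polish
    row/column correction, edge-ring correction), replicate quality control,
    linkage masking on the circular chromosome, multiplicative-model epistasis
    (E-) scores with empirical permutation p-values, enrichment-calibrated
    score cutoffs with label-shuffled controls, signed interaction networks
    with bioprocess crosstalk and topology statistics, genetic-interaction
    profile correlations against external evidence sets, and differential
    (condition-specific) interaction calls. Includes a synthetic-screen
    generator with planted ground truth so the full pipeline is verifiable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
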