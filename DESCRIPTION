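Package: netmed
Title: Causal Networks, Key Drivers, and Mediation for Dual-Tissue Transcriptomics
Version: 0.1.0
Authors@R:
    person("Dana", "Whitmore", email = "dwhitmore@example.org",
           role = c("aut", "cre"))
Description: An integrated analysis pipeline for paired systemic and local
    tissue RNA-seq cohorts: counts-per-million normalization and abundance
    filtering, discovery/test cohort splitting, covariate-adjusted
    negative-binomial differential expression with cross-set directional
    validation, weighted co-expression module detection with hypergeometric
    enrichment and eigengene-phenotype association, cis-eQTL mapping,
    eQTL-anchored discrete Bayesian network reconstruction by structure
    MCMC with edge-frequency consensus, key driver analysis on directed
    downstream neighborhoods, and causal mediation screening between
    key drivers of two tissues.  Includes a synthetic-cohort generator
    with machine-readable planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    data.table,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr,
    optparse
Config/testthat/edition: 3
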