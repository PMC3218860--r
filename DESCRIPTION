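Package: accessmap
Title: Linking Chromatin Accessibility to Transcription Factor Occupancy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of the relationship between DNase-derived
    chromatin accessibility and transcription-factor occupancy measured by
    ChIP. Provides FDR-controlled accessible-region calling against a local
    background, position weight matrix scanning with exact score-distribution
    p-values, scrambled-motif null models with similarity-based rejection,
    affinity-cohort and rank-cohort occupancy statistics, hypergeometric
    overlap tests, temporal ratio-correlation analysis across developmental
    stages, and a fully seeded synthetic-study generator implementing a
    thermodynamic widespread-binding occupancy model so that every stage of
    the pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Rcpp,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
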