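Package: hrsurvey
Title: Homology Survey Toolkit for the Oxygen-Binding Hemerythrin Domain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale re-implementation of the computational survey used to
    trace the evolution of the oxygen-binding hemerythrin domain across cellular
    genomes. Provides Smith-Waterman local alignment with PRSS-style
    shuffle-based significance (Gumbel fit of the permutation null), curated
    profile hidden Markov model construction and proteome scanning with
    E-value calibration, coverage-based single-domain versus long-sequence
    classification, domain-architecture resolution and tabulation, a simple
    progressive multiple aligner, and maximum-likelihood phylogenetics under
    LG+Gamma with approximate likelihood-ratio test branch supports,
    low-support collapse and midpoint rooting. A seeded synthetic-proteome
    simulator with planted, ground-truthed domain families makes the whole
    pipeline testable without any database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    withr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
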