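Package: gfscan
Title: Growth-Factor Combination Screening Analysis for Glioma Stem Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput growth-factor combination
    screens of patient-derived glioma stem cells in 384-well ATP-luminescence
    format. Enumerates the combinatorial condition catalog (pairs and singles
    of a growth-factor panel, each with and without EGF/bFGF), applies
    signal-based quality control to raw plate readouts, computes cell growth
    indices and growth success rates, clusters samples by their growth
    profiles into EGF/bFGF-dependent and -independent groups, ranks culture
    conditions within genotype-defined subgroups, and screens every
    mutation-condition pair for growth associations. Expression-side tools
    cover tumor-intrinsic gene filtering against paired tissue profiles,
    two-group differential expression, nearest template prediction,
    single-sample gene set enrichment subtype assignment, and two-class gene
    set enrichment analysis. A synthetic-data module simulates cohorts with
    planted genotype-dependent growth-factor effects so the whole pipeline is
    testable without access to raw screen data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
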