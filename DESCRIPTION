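Package: proteoMR
Title: Proteome-Wide Mendelian Randomization Screening of Drug Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for proteome-wide two-sample Mendelian randomization (MR)
    drug-target screens from GWAS summary statistics: cis-pQTL instrument
    selection (genome-wide significance, F-statistic strength, greedy LD
    clumping, cis-window restriction), Wald-ratio and inverse-variance-weighted
    causal estimation with odds-ratio reporting and Bonferroni prioritization,
    reverse-causality testing by MR Steiger filtering and bidirectional MR,
    Bayesian colocalization via Wakefield approximate Bayes factors under the
    single-causal-variant model, pleiotropy scanning against a local trait
    catalog, external replication, and phenome-wide MR side-effect screening
    standardized to a target risk reduction. A synthetic summary-statistics
    generator with known ground truth (LD blocks, shared or distinct causal
    variants, horizontal pleiotropy, reverse causation) makes the whole
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'gwas-io.R'
    'instruments.R'
    'mr-core.R'
    'directionality.R'
    'coloc.R'
    'phewmr.R'
    'simulate.R'
    'pipeline.R'
    'proteoMR-package.R'
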