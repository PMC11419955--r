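Package: TwoStepMR
Title: Two-Sample Mendelian Randomization with Two-Step Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for two-sample Mendelian randomization (MR) from
    GWAS summary statistics: instrument selection (p-value screening,
    greedy LD clumping, minor-allele-frequency and weak-instrument F
    filters), allele harmonization of exposure-outcome pairs, five causal
    estimators (inverse-variance weighted, MR-Egger, weighted median,
    simple and weighted mode), heterogeneity and pleiotropy diagnostics
    (Cochran's Q, Egger intercept, leave-one-out, funnel/scatter tables),
    multi-exposure screening with reverse-MR gating, and two-step MR
    mediation decomposition (indirect/direct effects and proportion
    mediated with delta-method uncertainty). Includes a generator of
    linked synthetic GWAS summary-statistics triplets (exposure,
    mediator, binary outcome) with known causal structure, block LD and
    case-control standard errors, so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'summary-stats.R'
    'harmonize.R'
    'ld-matrix.R'
    'instruments.R'
    'estimators.R'
    'diagnostics.R'
    'mediation.R'
    'screening.R'
    'run-study.R'
    'simulate.R'
    'fixture.R'
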