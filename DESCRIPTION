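Package: cismr
Title: Drug-Target Mendelian Randomization with cis Instruments, Mediation
    and Confounder Adjustment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-sample Mendelian randomization toolkit for drug-target
    studies that proxy pharmacological modulation with cis-eQTL instruments.
    Reads and harmonizes GWAS summary statistics, selects instruments by
    significance, exclusion screening, LD clumping and F-statistic filtering,
    and estimates causal effects with inverse-variance weighting, MR-Egger,
    the weighted median and MR-PRESSO, together with Cochran's Q,
    Egger-intercept and leave-one-out diagnostics. Implements two-step MR
    mediation with delta-method confidence intervals for indirect effects and
    mediated proportions, a difference-in-coefficients sensitivity analysis
    based on multivariable MR, and two-step cis-MR adjustment of instrument
    outcome associations for measured confounder pathways. Ships a fully
    seeded synthetic summary-statistics generator with known ground truth so
    every stage of the pipeline can be exercised and calibrated offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
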