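Package: lipidmr
Title: Two-Sample Mendelian Randomization of Plasma Lipid Species on
    Hemorrhagic Stroke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable two-sample Mendelian randomization (MR)
    pipeline for scanning many quantitative exposures (plasma lipid
    species) against binary outcomes (intracerebral and subarachnoid
    hemorrhage) from GWAS summary statistics. Implements instrument
    selection (genome-wide significance filter, greedy LD clumping,
    instrument-strength R-squared and F statistics, outcome-association
    exclusion), allele harmonization with palindromic-SNP policies, five
    causal estimators (fixed-effect and multiplicative-random-effects
    inverse-variance weighting, MR-Egger, weighted median, weighted
    mode), a full sensitivity battery (Cochran's Q, MR-Egger intercept,
    MR-PRESSO global/outlier/distortion tests, Steiger directionality,
    leave-one-out), Benjamini-Hochberg multiplicity control, a
    candidate-exposure decision rule, and DerSimonian-Laird
    random-effects meta-analysis across discovery and replication
    cohorts. Ships a summary-level synthetic GWAS generator with known
    ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
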