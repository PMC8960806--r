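Package: dietgxe
Title: Genotype-by-Environment Analysis of Macronutrient Tolerance in Inbred Fly Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for large diet screens on inbred Drosophila
    panels. Quantifies genotype-by-environment interaction in larval survival
    with binomial mixed models (random diet slopes per strain), runs a
    multivariate per-variant association screen (MANOVA with a Wolbachia
    covariate, per-diet Wilcoxon rank-sum tests and median-difference effect
    sizes), fits logistic pupation kinetics with closed-form time-to-threshold
    extraction, converts flow-through respirometry into standardized resting
    metabolic rate via the respiratory-quotient energy-equivalent relationship,
    and provides exactly-specified bench-assay calculators. Includes a
    synthetic-data generator that emulates the statistical structure of a
    panel-scale diet screen so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    minpack.lm,
    MASS,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    pracma,
    optparse,
    knitr
Config/testthat/edition: 3
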