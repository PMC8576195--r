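Package: vtegxe
Title: Gene-Environment Interaction and Genetic Risk Score Analysis for
    Venous Thromboembolism Case-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for cross-sectional case-control analysis of venous
    thromboembolism (VTE) risk in two-population cohorts genotyped at a
    small panel of prothrombotic SNPs. Provides cohort ingestion and
    validation, per-population allele-frequency estimation with exact
    Hardy-Weinberg testing and Bonferroni-controlled allelic association,
    genotype-level odds ratios with complete-separation handling,
    unweighted and weighted genetic risk scores with score-stratified
    association, a gene-environment interaction framework on both the
    multiplicative and additive (RERI) scales with rank-based
    inverse-normal covariate transformation, and a calibrated synthetic
    cohort generator for end-to-end testing and parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
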