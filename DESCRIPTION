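Package: duomr
Title: Two-Sample Mendelian Randomization with Maternal and Fetal Effect
    Partitioning
Version: 0.1.0
Authors@R:
    person("duomr", "developers", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Tools for estimating causal effects of maternal exposures on
    offspring birth outcomes from GWAS summary statistics. Partitions
    SNP-birth-weight associations into maternal-specific (intrauterine) and
    fetal-specific components, harmonizes them with SNP-exposure estimates
    from an independent sample, and applies a suite of two-sample Mendelian
    randomization estimators (inverse-variance weighted, MR-Egger, weighted
    median, mode-based, and multivariable variants) together with instrument
    diagnostics. Includes a mother-offspring duo simulator for validating
    every pipeline stage against known generative truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
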