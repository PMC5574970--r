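Package: mrsummary
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) with GWAS
    summary statistics: ingestion and allele harmonization of
    exposure/outcome association tables, per-variant Wald ratio estimates
    with Delta-method standard errors, fixed-effect inverse-variance
    weighted (IVW) pooling with Cochran's Q and I-squared heterogeneity
    diagnostics, MR-Egger regression with the I2_GX dilution diagnostic,
    the weighted median estimator with a parametric bootstrap, unweighted
    allele-score association tests including a negative-control
    comparison, instrument-strength (F statistic) reporting, and a
    calibrated generator of synthetic two-sample GWAS summary data with
    configurable pleiotropy for method validation. Includes a complete
    pipeline for studying the causal effect of age at menarche on time
    spent in education.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
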