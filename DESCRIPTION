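Package: ivmr
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization with GWAS
    summary statistics: allele harmonization between exposure and outcome
    studies (including frequency-based resolution of palindromic variants),
    inverse-variance weighted, MR-Egger, weighted-median and MR-PRESSO
    causal estimators, Cochran's Q and I-squared heterogeneity diagnostics,
    instrument-strength (variance explained) and binary-outcome power
    calculations, and a summary-statistic simulator for operating-
    characteristic studies. Ships the 11-instrument plasma vitamin C /
    Parkinson's disease example dataset as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    graphics,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
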