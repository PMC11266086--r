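Package: mrmediate
Title: Two-Sample Mendelian Randomization with Two-Step Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for bidirectional two-sample Mendelian randomization (MR)
    from GWAS summary statistics: instrument selection with p-value
    thresholding and greedy LD clumping, effect-allele harmonization with
    palindromic-SNP handling, inverse-variance-weighted, MR-Egger and
    weighted-median causal estimators, sensitivity diagnostics (Cochran Q,
    Egger intercept, MR-PRESSO outlier detection, leave-one-out), and
    two-step mediation analysis with delta-method confidence intervals,
    the Sobel test and proportion mediated. Includes a seeded synthetic
    summary-statistics generator with a known causal and mediation
    structure so every stage can be validated against ground truth, and a
    pipeline driver that orchestrates the four-step bidirectional plus
    two-step design with Benjamini-Hochberg FDR correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
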