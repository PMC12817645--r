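Package: mrmediate
Title: Two-Step Mendelian Randomization Mediation Analysis with GWAS
    Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) and two-step
    MR mediation analysis from GWAS summary statistics. Provides reading and
    harmonization of summary-statistic tables onto a shared effect-allele
    frame, instrument selection by p-value thresholding, LD clumping and
    F-statistic screening, a battery of MR estimators (inverse-variance
    weighted, MR-Egger, weighted median, simple and weighted mode, and a
    Bayesian weighted MR), sensitivity diagnostics (Cochran's Q, Egger
    intercept, MR-PRESSO style outlier tests, leave-one-out, scatter and
    funnel plot data), product-of-coefficients mediation with delta-method
    inference, and a summary-statistic simulator with known causal and
    mediation structure for end-to-end validation.
License: MIT + file LICENSE
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
    ggplot2
Config/testthat/edition: 3
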