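Package: cnamcr
Title: Recurrent Copy-Number Alteration Regions from Array CGH Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of tumor/normal array comparative genomic
    hybridization (aCGH) cohorts: within-array lowess and between-array
    quantile normalization, kernel-density centralization, interval-score
    (ADM-2 style) aberration detection with fuzzy-zero correction,
    context-corrected common-aberration statistics under a Poisson-binomial
    null, copy-number alteration region (CNAR) and cross-platform minimal
    common region (MCR) extraction, MLPA three-state validation calling,
    qPCR delta-delta-Ct expression association, and clinicopathological
    statistics (Lauren-type association, age correlation, hierarchical
    clustering, Kaplan-Meier/log-rank survival). Ships a synthetic cohort
    generator with planted ground truth so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    limma,
    survival,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
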