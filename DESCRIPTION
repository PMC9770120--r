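Package: prscohort
Title: Polygenic Risk Score Evaluation and Case-Control Association for
    Sequenced Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for validating published polygenic risk scores (PRSs) in
    a whole-genome-sequenced case-control cohort: scoring-file harmonization
    and per-sample scoring, overall and within-ancestry standardization, an
    ensemble PRS, odds ratio per standard deviation and decile risk
    stratification, DeLong AUC machinery for correlated ROC comparisons,
    post-GWAS clumping, known-locus replication and fixed-effect
    meta-analysis, rare-variant case-control ratio (CCR and pseudo-CCR)
    burden statistics with exact collapsing tests and a variance-component
    score test, EM haplotype frequency estimation from unphased genotypes
    with a case-control haplotype test, analytic case-control power, and a
    Balding-Nichols synthetic cohort generator so every stage is testable
    without access-controlled genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    metafor,
    jsonlite
Config/testthat/edition: 3
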