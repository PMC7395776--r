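Package: prstransfer
Title: Cross-Population Evaluation and Recalibration of Polygenic Risk Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating a polygenic risk score (PRS) developed in
    one population when applied to another. Implements dosage-based scoring
    with allele-orientation handling and imputation-quality filtering,
    standardisation to a reference-control standard deviation, per-SD and
    percentile-bin odds ratios, prospective hazard ratios, study-adjusted
    AUC, fixed-effect meta-analysis, family-history attenuation, closed-form
    predictions of the multiplicative polygenic model (percentile-bin odds
    ratios, familial relative risk explained, theoretical AUC), absolute
    risk projection under competing mortality with iterative calibration of
    group-specific incidences to population rates, risk-stratified
    screening-threshold analytics, and an EM-fitted hierarchical
    measurement-error model for cross-population concordance of per-SNP
    effect sizes. A synthetic-cohort generator with recorded ground truth
    makes the whole pipeline testable without access to individual-level
    consortium data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
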