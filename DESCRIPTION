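Package: t2dprs
Title: Multi-Ancestry Polygenic Risk Score Construction and
    Characterization for Type 2 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Construction and characterization of multi-ancestry polygenic
    risk scores (PRS) for type 2 diabetes: harmonization of variant weight
    tables against imputed dosage panels (allele matching, strand
    complementation, INFO and effective-sample-size filters), weighted-sum
    scoring with control-anchored standardization, cross-validated
    non-negative linear combination of population-specific scores,
    evaluation of risk stratification (odds ratio per standard deviation,
    percentile-category odds ratios, AUC, age at diagnosis), context
    stratified effect heterogeneity (Cochran's Q, interaction likelihood
    ratio tests), trait associations, phecode-based phenome-wide
    association scans, and inverse-variance-weighted fixed-effect
    meta-analysis with heterogeneity statistics. Includes a synthetic
    multi-population cohort generator with known ground truth so the whole
    pipeline is testable without access-controlled biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    vcfR
Config/testthat/edition: 3
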