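Package: fdftools
Title: Fabry Phenotype Scoring and GLA Carrier Association Analysis for Biobank Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for population-scale association analysis of X-linked GLA gene
    variants with Fabry disease phenotypes in biobank-style cohorts. Provides a
    seeded synthetic-cohort generator with sex-stratified X-linked genotypes, an
    ICD-10 code registry mapping diagnoses to Fabry clinical domains and
    cardiovascular risk factors, a FASTEX-derived Fabry (FDF) phenotype score
    with ROC/Youden threshold evaluation, a cardiovascular risk score with
    75th-percentile stratification, and a sex-matched association engine
    (logistic, proportional-odds ordinal and linear models) with variance
    inflation factor checks and Benjamini-Hochberg multiple-testing correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    pROC,
    car,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
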