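Package: solapheno
Title: CYP2D6 Poor-Metabolizer Phenotyping from Solanidine Metabolic Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for solanidine-based CYP2D6 phenotyping from targeted
    LC-HRMS serum metabolomics. Translates CYP2D6 star-allele diplotypes into
    genotype-predicted metabolizer subgroups, extracts and integrates analyte
    peaks from centroided full-scan runs, computes truncated
    metabolite-to-solanidine metabolic ratios, performs stratified test /
    validation cohort splitting, derives ROC-optimal classification thresholds
    for the poor-metabolizer phenotype with full predictive-value evaluation,
    and fits the genotype / age / sex linear models for each ratio. A
    calibrated synthetic-cohort generator reproduces the genotype mix,
    covariate structure, ln-scale regression model, and limit-of-detection
    missingness of a large therapeutic-drug-monitoring population, so the
    entire pipeline can be exercised and validated without patient data.
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
    pROC,
    multcomp,
    mzR,
    optparse
Config/testthat/edition: 3
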