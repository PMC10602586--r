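Package: apol1sepsis
Title: APOL1 Risk Genotypes and Sepsis in Hospitalized Infection Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable reimplementation of a retrospective
    electronic-health-record (EHR) cohort analysis of APOL1 G1/G2 high-risk
    genotypes and sepsis among patients hospitalized with infections. Provides
    a synthetic longitudinal EHR generator with known ground truth, an adapted
    EHR Sepsis-3 phenotyper (septic-shock codes plus five organ-dysfunction
    criteria), recessive APOL1 risk-genotype classification, infection-cohort
    construction with attrition logging, Charlson/Deyo comorbidity and
    severe-renal-disease covariates, logistic-regression association analyses
    under three renal-disease strategies, and a restricted phecode PheWAS with
    a severe-renal-exclusion sensitivity analysis.
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
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
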