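# apol1sepsis

An R package for studying whether *APOL1* high-risk genotypes are associated
with sepsis in patients hospitalized with infections — and whether that
association survives accounting for pre-existing severe renal disease. It is
a desk-scale, fully testable reimplementation of a retrospective EHR cohort
analysis: because the patient-level data behind such studies are
access-restricted, the package ships a synthetic longitudinal EHR generator
with known latent ground truth, so every downstream stage (phenotyping,
cohort construction, covariates, modelling, PheWAS) is verifiable end to
end.

It is aimed at epidemiologists and biostatisticians who want a reproducible
reference implementation of:

- **Recessive APOL1 risk classification.** G1 is tracked by rs73885319 and
  G2 by the proxy rs12106505. A patient is *high risk* with any two risk
  alleles — G1/G1, G2/G2, or the G1/G2 compound heterozygote; carriers of
  one or zero risk alleles are *low risk*. Exposure is coded high = 1.
- **An adapted EHR Sepsis-3 phenotype.** Sepsis = septic-shock/severe-sepsis
  billing codes (ICD-9-CM 995.92, 785.52; ICD-10-CM R65.20, R65.21) on days
  −1/0/+1, OR any of five organ-dysfunction criteria: circulatory
  (vasopressors, with a stress-echo guard on dobutamine/dopamine),
  respiratory (ventilation ∧ ICU), renal (creatinine ≥ 2 × baseline),
  hepatic (bilirubin ≥ 2 mg/dL ∧ ≥ 2 × baseline), hematologic (platelets
  < 100,000/µL ∧ ≤ ½ of a baseline ≥ 100,000). Baselines are the window
  extremum over [admission − 1 year, discharge].
- **Infection-cohort construction.** Adults with an infection billing code
  *and* an antibiotic within 1 day of admission (days −1, 0, +1); first
  qualifying admission only; exclusions for cardiac surgery, cardiogenic
  shock, transplantation, absent labs, and COVID-19 — with a complete
  attrition log.
- **Association analyses.** Logistic regression of each outcome on the risk
  group adjusted for age, sex and three ancestry PCs, under three
  renal-disease strategies: additional adjustment for severe renal disease,
  exclusion of severe-renal patients, and the severe-renal-only subset.
  ORs with Wald 95% CIs (`exp(β ± 1.96·SE)`) and Wald p-values.
- **A restricted PheWAS** over five prespecified phecodes (081 prosthetic
  device infection, 038 septicemia, 994.1 SIRS, 994.2 sepsis, 994.21 septic
  shock) with the ≥ 2-occurrence case rule, related-code exclusions, the
  Bonferroni threshold 0.05/5 = 0.01, and a severe-renal-exclusion
  sensitivity pass.

The generator's defaults encode the study conditions: combined risk-
haplotype frequency 0.40 (so ~16% high-risk carriage under the recessive
model), severe renal disease at 35% vs 18% by genotype group, and a sepsis
risk that runs entirely through severe renal disease (OR 3, no direct
genotype effect) — the mediation structure the analyses are designed to
detect.

## Worked example

```r
library(apol1sepsis)

sim <- simulate_ehr(sim_config(n_patients = 2000, seed = 42))
coh <- assemble_cohort(sim$patients, sim$admissions, sim$events, sim$labs)
coh
#> <apol1_cohort>
#>   2000 patients | 307 high-risk | 533 sepsis | 394 severe renal
#>   attrition:
#>                    step n_patients n_removed
#>                   input       2000         0
#>                   adult       2000         0
#>          infection_code       2000         0
#>              antibiotic       2000         0
#>  no_exclusion_admission       2000         0
#>          labs_available       2000         0
#>                no_covid       2000         0
#>   genotype_classifiable       2000         0

fit_outcome_model(coh$cohort, "sepsis", "base")
#> <sepsis_fit> sepsis ~ high_risk [base]
#>   OR = 1.37 [95% CI, 1.05-1.78; p=0.02]  (n=2000, cases=533)
fit_outcome_model(coh$cohort, "sepsis", "adjust_renal")
#> <sepsis_fit> sepsis ~ high_risk [adjust_renal]
#>   OR = 1.10 [95% CI, 0.83-1.45; p=0.50]  (n=2000, cases=533)
fit_outcome_model(coh$cohort, "sepsis", "exclude_renal")
#> <sepsis_fit> sepsis ~ high_risk [exclude_renal]
#>   OR = 1.10 [95% CI, 0.78-1.57; p=0.59]  (n=1606, cases=351)
```

Read: the crude high-risk genotype effect on sepsis (OR 1.37, p = 0.02) is
attenuated to the null both by adjusting for pre-existing severe renal
disease and by excluding those patients — the signature of a
renal-mediated association. With the default noise-free generator the
attrition log removes nobody; contamination knobs (`p_covid`,
`p_missing_labs`, …) populate it. `run_analysis_suite()` fits the full
8-outcome × 4-strategy grid (`autoplot()` draws the forest plot),
`table_one()` builds the descriptive baseline table, and
`run_restricted_phewas()` runs the phecode replication analysis.
`run_pipeline()` chains everything with a reproducibility manifest; a thin
CLI lives at `inst/scripts/run_pipeline.R`.

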