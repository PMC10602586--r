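---
title: "Methods: APOL1 risk genotypes, sepsis phenotyping, and renal-disease mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: APOL1 risk genotypes, sepsis phenotyping, and renal-disease mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(apol1sepsis)
library(dplyr)
```

## The scientific question

Two *APOL1* haplotypes common in populations of recent African ancestry —
G1 (tagged by rs73885319) and G2 (tagged here by the proxy rs12106505) —
strongly increase the risk of chronic kidney disease under a recessive
model: carrying any two risk alleles (G1/G1, G2/G2, or G1/G2) defines the
*high-risk genotype*. High-risk genotypes have also been reported to be
associated with sepsis. The question this package operationalizes is
whether that sepsis association is *direct*, or whether it is carried by
pre-existing severe renal disease, itself a potent risk factor for
infection and sepsis. The analytic design compares the genotype–sepsis
odds ratio under three strategies: covariate adjustment for severe renal
disease, exclusion of severe-renal patients, and restriction to them. A
direct effect survives all three; a purely mediated effect attenuates
toward the null under the first and vanishes under the second.

## The synthetic cohort generator

Real patient-level EHR/biobank data of this kind are access-restricted, so
the package's first-class data source is a generator
(`sim_config()`, `simulate_ehr()`) whose latent layer has known truth:

1. Two haplotypes per patient are drawn from {G1, G2, reference} with
   frequencies (`freq_g1`, `freq_g2`, remainder). Defaults 0.27/0.13 give a
   combined risk frequency of 0.40, hence an expected high-risk fraction of
   $0.40^2 = 16\%$ — the carriage observed in the cohort the package
   models. Haplotype exclusivity makes `g1 + g2 <= 2` structural.
2. Severe renal disease is Bernoulli with probability 0.35 (high-risk) or
   0.18 (low-risk); these imply ~20.6% overall severe renal disease,
   matching the modelled cohort's 458/2242.
3. Latent sepsis follows
   $\text{logit}(p) = \text{logit}(p_0) + \log(\mathrm{OR}_\text{renal})\,R +
   \log(\mathrm{OR}_\text{direct})\,G$
   with baseline $p_0 = 0.205$, renal OR 3 and direct OR 1 by default, so
   the default effect is *purely renal-mediated* and the overall sepsis
   fraction is ~25%. Both ORs are knobs; setting the direct OR above 1
   creates a genuine genotype effect for power/recovery studies.
4. Among sepsis cases the five organ criteria and the shock code are drawn
   independently with the secondary-outcome mix observed among sepsis
   cases (shock 0.288, renal 0.536, respiratory 0.241, hematologic 0.181,
   circulatory 0.161, hepatic 0.147); a case drawing none is assigned the
   shock code so latent sepsis always has evidence. Short-term mortality is
   0.149 among cases.

Event emission then *constructs* records that deterministically satisfy or
fail each downstream rule: creatinine pairs with the peri-admission value
at ≥ 2.05 × baseline (true) or ≤ 1.8 × (false); bilirubin clearing or
missing both the 2 mg/dL and doubling conditions; platelet falls to
40–90 × 10³/µL from baselines of 180–320 × 10³/µL (true) versus declines
capped at 40% (false); ventilation + ICU code pairs versus one-sided
decoys; norepinephrine, or dobutamine/dopamine with keyword support —
with stress-echo-tied dopamine decoys that must *not* count. The margins
(2.05 vs 1.8, 0.45 vs 0.60 of baseline) keep every inclusive comparison
safely away from its boundary, which is what makes exact
sensitivity = specificity = 1 recovery a meaningful test of the
phenotyper rather than a coin flip at thresholds.

What the generator does **not** emulate: realistic ICD co-occurrence
structure, free-text notes (keywords arrive pre-counted), coding errors,
repeated admissions (one per patient by default; the cohort module still
supports many), informative missingness, or genotype–PC confounding (PCs
are standard normal and independent of genotype). Passing tests therefore
demonstrate algorithmic correctness and statistical calibration under the
stated generative model — not robustness to real-world coding noise.

## Phenotyping rules and their numerical conventions

* **Windows.** Day 0 is the admission day. Organ-dysfunction labs,
  vasopressors, stress-echo codes, keywords and shock codes are evaluated
  on days −1, 0, +1. Baselines use [admission − 365, discharge]: lowest
  creatinine/bilirubin, highest platelets. The baseline window deliberately
  extends through discharge, so a late low creatinine can lower the
  baseline; this mirrors the written definition rather than a
  strictly-prior convention.
* **Inclusive folds.** All fold comparisons are `>=` ("doubling or
  greater"). The hematologic rule additionally requires the baseline itself
  to be ≥ 100,000/µL.
* **Units.** Internal standards are mg/dL (creatinine, bilirubin) and /µL
  (platelets); µmol/L inputs are divided by 88.4 and 17.1, thousand-scale
  platelet units multiplied by 1000. Correctly tagged unit changes cannot
  change a call (tested). Unknown tags are validation errors; non-positive
  values are dropped with a warning.
* **Missing baseline ⇒ criterion false**, logged: dysfunction is never
  asserted without a reference value. This is conservative and mirrors the
  lab-availability inclusion rule.
* **Ambiguities resolved as documented choices.** The ≥ 2 keyword-mention
  requirement gates only the dobutamine/dopamine branch of the circulatory
  criterion (a `keyword_gate_branch_a` switch extends it to norepinephrine;
  the source text is ambiguous and we do not guess intent). The
  ventilation/ICU conjunction is evaluated over the whole index stay
  (`respiratory_window = "peri"` restricts it). Keyword mentions are summed
  across the three keywords and across days −1..+1.

## Cohort construction

Inclusion: age ≥ 18 at day 0 (from `birth_day`, floored integer years),
≥ 1 infection billing code and ≥ 1 antibiotic administration on days
−1/0/+1. Exclusions, in order: cardiac surgery / cardiogenic shock /
transplantation codes in the window; no relevant labs; COVID-19 (flag or
U07.1). "No relevant labs" is read as *all three* analytes absent (the
weaker exclusion; `lab_rule = "any_absent"` gives the stricter reading).
Only the first qualifying admission counts; same-day ties go to the longer
stay, then the lower admission id — fully deterministic, and the cohort is
invariant to row order. Attrition is tallied per patient at each step and
must conserve counts (tested).

Code lists are configuration, not code: the exact infection, antibiotic,
exclusion, ventilation and ICU lists of the modelled study live in an
unavailable appendix, so the package ships clearly labelled plausible
defaults in `inst/extdata/codes.yaml` and treats list contents as data.
The fifteen severe-renal codes (N18.4–N18.9, 585.4–586, Z99.2, Z49.0,
Z49.31, 39.95, V45.11, V56.0) and four shock codes *are* printed, and are
matched exactly (after dot-stripping) — child codes like N18.41 do not
match. Severe renal disease uses the whole prior record through day 0:
these are chronic states and the definition names no window. Charlson
categories use prefix matching over the lookback year [−365, −1] and are
kept fully independent of the severe-renal flag.

## Association analyses

Models are maximum-likelihood logistic regressions (IRLS, convergence
tolerance 1e−10) of each outcome on the high-risk indicator plus age, sex
and the first three ancestry PCs; the severe-renal strategies add the
covariate or subset the data. We report Wald CIs and p-values rather than
profile likelihood so the OR/CI/p triple is mutually consistent — the
convention of the results being emulated. Complete-case analysis with a
reported missing count. Separation or non-convergence flags the result
(with the diagnostic in `note`) instead of silently returning numbers;
degenerate subsets (no cases, constant exposure) raise typed errors that
the suite converts to flagged NA rows.

Descriptive comparisons use the chi-square test **with Yates continuity
correction** for all 2×2 tables — chosen because it reproduces the printed
renal-comorbidity p-value (order 1.6 × 10⁻¹⁰) where the uncorrected
statistic does not — and a two-sample t-test for age, even though age is
*displayed* as median (Q1–Q3); both the display and the test follow the
stated conventions, and we do not resolve that tension. p-values print
with two decimals down to 0.001 and in scientific notation below.

## Restricted PheWAS

Occurrences are counted on *distinct days* (standard phecode practice;
the source counts "occurrences" without granularity). Case ⇔ ≥ 2 days;
exactly one occurrence, or any phecode in the target's related-code
exclusion range, excludes the patient from that phecode's analysis (case
status takes precedence); everyone else is a control. The shipped map
covers the five targets plus the family codes their exclusion ranges need
(081: [80, 82); 038: [38, 42); 994.x: [994, 995)); the authors' exact
ranges are unpublished, so these are documented defaults, overridable like
any code list. Significance is `p < 0.05/5 = 0.01`, strictly less. The
sensitivity pass refits after dropping severe-renal patients.

`simulate_phewas_population()` mirrors the population-scale design:
severe renal disease at 0.38/0.10 by genotype group (~14.5% overall,
matching the modelled 2166/14,713) and a renal→phecode OR of 5 on baseline
prevalence 0.05, giving marginal genotype→phecode ORs near 1.7 — the range
of the replicated associations. These values were fixed once, from those
published quantities, before any calibration against test outcomes.

## Monte-Carlo test design and problem sizes

The suites run at sizes chosen to make their statistical tolerances
meaningful: exact phenotyper–oracle agreement on 1,000 patients including
degenerate records; perfect-fidelity recovery on 2,000 noise-free
patients; type-I error from 500 null replicates of n = 2,000 with an
acceptance band of [0.03, 0.07] (±2 Monte-Carlo SEs around 0.05);
mediation-signature recovery in ≥ 90% of 100 replicates at n = 20,000;
direct-effect recovery (OR 1.5) within 5% of the mean of 200 replicates at
n = 20,000. The null PheWAS multiplicity check deserves a note: the
expected number of Bonferroni-significant phecodes per null replicate is
*exactly* 5 × 0.01 = 0.05, so a strict sample-mean-≤-0.05 assertion would
fail about half the time at any replicate count. The test therefore uses
the exact one-sided binomial test that the per-model rejection rate does
not exceed 0.01 — the standard Monte-Carlo formulation of "the rate is at
its nominal expectation".

Determinism is end to end: one master seed fans out to per-stage child
seeds through a documented affine map, identical configurations are
byte-identical on disk, and no stage consumes hidden global RNG state
between runs.

## A compact demonstration

```{r demo}
sim <- simulate_ehr(sim_config(n_patients = 1500, seed = 7))
coh <- assemble_cohort(sim$patients, sim$admissions, sim$events, sim$labs)

# phenotyper fidelity against latent truth
m <- inner_join(coh$cohort, sim$ground_truth, by = "patient_id")
c(sensitivity = sum(m$sepsis & m$true_sepsis) / sum(m$true_sepsis),
  specificity = sum(!m$sepsis & !m$true_sepsis) / sum(!m$true_sepsis))

# the three renal strategies on the default (purely mediated) generator
suite <- run_analysis_suite(coh$cohort)
suite |>
  filter(outcome == "sepsis", strategy != "only_renal") |>
  select(strategy, n_total, n_cases, or, ci_low, ci_high, p)
```

## Known limitations

* Code lists beyond the printed severe-renal and shock lists are plausible
  defaults, not the study's appendix lists; results on real data depend on
  supplying the intended lists via `load_codes()`.
* The generator's organ-criterion mix is conditioned only on sepsis status
  (the source reports per-criterion prevalence only among sepsis cases),
  so criterion-specific genotype effects are not simulated unless added.
* Array QC, genome-wide imputation and PC computation are out of scope;
  PCs are simulated inputs and post-imputation QC thresholds are carried
  as documented constants (`variant_qc_defaults()`).
* Single-admission generation means index-selection tie-breaking is
  exercised by constructed fixtures, not the generator.
* Wald inference is asymptotic; no Firth correction is provided because
  none is used in the emulated analyses — heavily separated subsets are
  flagged instead.
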