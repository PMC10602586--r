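# Infection-cohort construction: inclusion, exclusion, index selection,
# attrition accounting.

# Normalized code vectors for the infection-inclusion rule (prefix match).
infection_prefixes <- function(codes) {
  list(
    icd10 = norm_code(unlist(lapply(codes$infection_types, `[[`, "icd10"))),
    icd9 = norm_code(unlist(lapply(codes$infection_types, `[[`, "icd9")))
  )
}

#' Identify admissions qualifying for the infection cohort
#'
#' An admission qualifies when the patient is at least 18 years old on the
#' admission day, has at least one infection billing code and at least one
#' antibiotic administration on days -1, 0 or +1 relative to admission.
#' Qualifying admissions are then excluded for: cardiac-surgery,
#' cardiogenic-shock or organ-transplantation codes in the window; absence of
#' all three relevant labs (creatinine, total bilirubin, platelets) in the
#' window; and a positive COVID-19 test flag or code U07.1 in the window.
#'
#' @param admissions Tibble `admission_id`, `patient_id`, `admission_day`,
#'   `discharge_day`.
#' @param patients Patient table (needs `birth_day` and `covid_positive`).
#' @param events,labs Event and lab tables.
#' @param codes Code configuration ([default_codes()]).
#' @param lab_rule `"all_absent"` (default) excludes an admission only when
#'   none of the three analytes has a window value; `"any_absent"` requires
#'   all three to be present.
#' @return The qualifying admissions, with an `"attrition"` attribute: a
#'   tibble of per-step patient counts (patients retained after each rule).
#' @export
qualify_admissions <- function(admissions, patients, events, labs,
                               codes = default_codes(),
                               lab_rule = c("all_absent", "any_absent")) {
  validate_codes(codes)
  lab_rule <- match.arg(lab_rule)
  bad_sys <- setdiff(unique(events$code_system),
                     c("ICD9CM", "ICD10CM", "CPT", "MED", "KEYWORD"))
  if (length(bad_sys) > 0) {
    abort(sprintf("Unknown code system tag(s): %s",
                  paste(bad_sys, collapse = ", ")),
          class = "apol1_validation_error")
  }

  adm <- dplyr::left_join(admissions,
                          patients[, c("patient_id", "birth_day", "covid_positive")],
                          by = "patient_id")
  adm$age_at_admission <- as.integer(
    floor((adm$admission_day - adm$birth_day) / 365.25))

  ew <- dplyr::inner_join(
    events,
    adm[, c("admission_id", "patient_id", "admission_day")],
    by = "patient_id", relationship = "many-to-many")
  ew <- dplyr::filter(ew, .data$day >= .data$admission_day - 1L,
                      .data$day <= .data$admission_day + 1L)
  ew$ncode <- norm_code(ew$code)

  inf <- infection_prefixes(codes)
  has_infection <- unique(ew$admission_id[
    (ew$code_system == "ICD10CM" & match_any_prefix(ew$ncode, inf$icd10)) |
      (ew$code_system == "ICD9CM" & match_any_prefix(ew$ncode, inf$icd9))])
  has_abx <- unique(ew$admission_id[
    ew$code_system == "MED" & tolower(ew$code) %in% tolower(codes$antibiotics)])

  excl_hit <- rep(FALSE, nrow(ew))
  for (rule in codes$exclusions) {
    excl_hit <- excl_hit |
      (ew$code_system == "CPT" & ew$ncode %in% norm_code(rule$cpt %||% character())) |
      (ew$code_system == "ICD9CM" & ew$ncode %in% norm_code(rule$icd9 %||% character())) |
      (ew$code_system == "ICD10CM" & ew$ncode %in% norm_code(rule$icd10 %||% character()))
  }
  has_excl <- unique(ew$admission_id[excl_hit])
  has_covid_code <- unique(ew$admission_id[
    ew$code_system == "ICD10CM" & ew$ncode %in% norm_code(codes$covid)])

  lw <- dplyr::inner_join(
    labs, adm[, c("admission_id", "patient_id", "admission_day")],
    by = "patient_id", relationship = "many-to-many")
  lw <- dplyr::filter(lw, .data$day >= .data$admission_day - 1L,
                      .data$day <= .data$admission_day + 1L)
  n_analytes <- dplyr::summarise(
    dplyr::group_by(lw, .data$admission_id),
    k = dplyr::n_distinct(.data$analyte), .groups = "drop")
  lab_count <- setNames(rep(0L, nrow(adm)), adm$admission_id)
  lab_count[as.character(n_analytes$admission_id)] <- n_analytes$k
  labs_ok <- if (lab_rule == "all_absent") lab_count > 0L else lab_count >= 3L

  steps <- list(
    adult = adm$age_at_admission >= 18L,
    infection_code = adm$admission_id %in% has_infection,
    antibiotic = adm$admission_id %in% has_abx,
    no_exclusion_admission = !(adm$admission_id %in% has_excl),
    labs_available = unname(labs_ok),
    no_covid = !(adm$admission_id %in% has_covid_code) &
      !dplyr::coalesce(adm$covid_positive, FALSE)
  )

  keep <- rep(TRUE, nrow(adm))
  attrition <- vector("list", length(steps) + 1L)
  attrition[[1]] <- tibble::tibble(
    step = "input", n_patients = dplyr::n_distinct(adm$patient_id),
    n_removed = 0L)
  for (i in seq_along(steps)) {
    before <- dplyr::n_distinct(adm$patient_id[keep])
    keep <- keep & steps[[i]]
    after <- dplyr::n_distinct(adm$patient_id[keep])
    attrition[[i + 1L]] <- tibble::tibble(
      step = names(steps)[i], n_patients = after,
      n_removed = before - after)
  }
  out <- adm[keep, c("admission_id", "patient_id", "admission_day",
                     "discharge_day", "age_at_admission")]
  out <- dplyr::arrange(out, .data$patient_id, .data$admission_day,
                        .data$admission_id)
  attr(out, "attrition") <- dplyr::bind_rows(attrition)
  out
}

#' Select one index admission per patient
#'
#' Only the first qualifying hospitalization counts: the earliest admission
#' day wins; ties are broken by the longer stay, then by the lower admission
#' id, so the choice is deterministic.
#'
#' @param candidates Qualifying admissions from [qualify_admissions()].
#' @return One row per patient, preserving any `"attrition"` attribute.
#' @export
select_index <- function(candidates) {
  att <- attr(candidates, "attrition")
  ord <- dplyr::arrange(candidates, .data$patient_id, .data$admission_day,
                        dplyr::desc(.data$discharge_day - .data$admission_day),
                        .data$admission_id)
  out <- dplyr::slice_head(dplyr::group_by(ord, .data$patient_id), n = 1L)
  out <- dplyr::ungroup(out)
  attr(out, "attrition") <- att
  out
}

#' Assemble the analysis-ready infection cohort
#'
#' Runs the full construction chain on raw tables: admission qualification,
#' index selection, APOL1 risk classification (unclassifiable genotypes are
#' removed and logged), covariate derivation (17 Charlson/Deyo flags, severe
#' renal disease, infection types) and Sepsis-3 phenotyping, producing one
#' analysis-ready row per patient plus an ordered attrition log.
#'
#' @param patients,admissions,events,labs Raw tables, e.g. from
#'   [simulate_ehr()] or [read_fixture()].
#' @param codes Code configuration.
#' @param thresholds Phenotyping thresholds ([sepsis_thresholds()]).
#' @param lab_rule Lab-availability exclusion rule, see
#'   [qualify_admissions()].
#' @return A list of class `"apol1_cohort"`: `cohort` (one row per patient
#'   with exposure, covariates and all outcomes), `attrition` (per-step
#'   patient counts), and `calls` (the full phenotyper output with evidence).
#' @export
#' @examples
#' sim <- simulate_ehr(sim_config(n_patients = 300, seed = 7))
#' coh <- assemble_cohort(sim$patients, sim$admissions, sim$events, sim$labs)
#' coh$attrition
assemble_cohort <- function(patients, admissions, events, labs,
                            codes = default_codes(),
                            thresholds = sepsis_thresholds(),
                            lab_rule = "all_absent") {
  if (anyDuplicated(patients$patient_id)) {
    abort("Duplicate patient ids in `patients`.", class = "apol1_validation_error")
  }
  cand <- qualify_admissions(admissions, patients, events, labs,
                             codes = codes, lab_rule = lab_rule)
  index <- select_index(cand)
  attrition <- attr(index, "attrition")

  idx_pat <- dplyr::inner_join(
    index, patients, by = "patient_id")
  risk <- apol1_risk_group(idx_pat$g1_dosage, idx_pat$g2_dosage)
  n_before <- nrow(idx_pat)
  idx_pat$apol1_risk <- risk
  idx_pat <- idx_pat[!is.na(risk), , drop = FALSE]
  attrition <- dplyr::bind_rows(attrition, tibble::tibble(
    step = "genotype_classifiable", n_patients = nrow(idx_pat),
    n_removed = n_before - nrow(idx_pat)))

  index_kept <- idx_pat[, c("patient_id", "admission_day", "discharge_day",
                            "admission_id", "age_at_admission")]
  charl <- charlson_flags(events, index_kept, codes)
  renal <- severe_renal_flag(events, index_kept, codes)
  itypes <- infection_types(events, index_kept, codes)
  calls <- phenotype_sepsis(index_kept, patients, events, labs,
                            codes = codes, thresholds = thresholds)

  cohort <- tibble::tibble(
    patient_id = idx_pat$patient_id,
    admission_id = idx_pat$admission_id,
    apol1_risk = idx_pat$apol1_risk,
    high_risk = idx_pat$apol1_risk == "high",
    age = idx_pat$age_at_admission,
    sex = idx_pat$sex,
    pc1 = idx_pat$pc1, pc2 = idx_pat$pc2, pc3 = idx_pat$pc3
  )
  cohort <- dplyr::left_join(cohort, charl, by = "patient_id")
  cohort <- dplyr::left_join(
    cohort, renal[, c("patient_id", "severe_renal")], by = "patient_id")
  cohort <- dplyr::left_join(cohort, itypes, by = "patient_id")
  cohort <- dplyr::left_join(
    cohort,
    calls[, c("patient_id", "sepsis", "via_shock_code", "circulatory",
              "respiratory", "renal", "hepatic", "hematologic",
              "short_term_mortality")],
    by = "patient_id")
  cohort <- dplyr::rename(cohort, shock_code = "via_shock_code")
  cohort <- dplyr::arrange(cohort, .data$patient_id)

  structure(list(cohort = cohort, attrition = attrition, calls = calls),
            class = "apol1_cohort")
}

#' @export
print.apol1_cohort <- function(x, ...) {
  cat("<apol1_cohort>\n")
  cat(sprintf("  %d patients | %d high-risk | %d sepsis | %d severe renal\n",
              nrow(x$cohort), sum(x$cohort$high_risk),
              sum(x$cohort$sepsis), sum(x$cohort$severe_renal)))
  cat("  attrition:\n")
  print(as.data.frame(x$attrition), row.names = FALSE)
  invisible(x)
}
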