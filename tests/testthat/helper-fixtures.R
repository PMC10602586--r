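# Hand-built miniature tables for rule-level tests. All days are offsets
# from the admission anchor (day 0) unless a test says otherwise.

adult_birth <- -40L * 366L  # ~40 years before day 0

make_patients <- function(ids, birth_day = adult_birth, sex = "female",
                          g1 = 0L, g2 = 0L, covid = FALSE,
                          death_day = NA_integer_, disposition = "home") {
  tibble::tibble(
    patient_id = as.integer(ids),
    birth_day = as.integer(birth_day),
    age = as.integer(floor(-birth_day / 365.25)),
    sex = sex, g1_dosage = as.integer(g1), g2_dosage = as.integer(g2),
    pc1 = 0, pc2 = 0, pc3 = 0,
    covid_positive = covid,
    death_day = as.integer(death_day), disposition = disposition
  )
}

make_admissions <- function(ids, admission_day = 0L, discharge_day = 7L,
                            admission_id = NULL) {
  tibble::tibble(
    admission_id = as.integer(admission_id %||% seq_along(ids)),
    patient_id = as.integer(ids),
    admission_day = as.integer(admission_day),
    discharge_day = as.integer(discharge_day)
  )
}

make_events <- function(patient_id, day, code_system, code, value = NA_real_) {
  tibble::tibble(
    event_id = seq_along(patient_id),
    patient_id = as.integer(patient_id), day = as.integer(day),
    code_system = code_system, code = code, value = as.double(value)
  )
}

make_labs <- function(patient_id, day, analyte, value, units = NULL) {
  default_units <- c(creatinine = "mg/dL", bilirubin_total = "mg/dL",
                     platelets = "/uL")
  tibble::tibble(
    lab_id = seq_along(patient_id),
    patient_id = as.integer(patient_id), day = as.integer(day),
    analyte = analyte, value = as.double(value),
    units = units %||% unname(default_units[analyte])
  )
}

# events that make patient(s) qualify for the infection cohort:
# an infection code and an antibiotic on day 0, all labs present
qualifying_events <- function(ids) {
  dplyr::bind_rows(
    make_events(ids, 0L, "ICD10CM", "N39.0"),
    make_events(ids, 0L, "MED", "vancomycin")
  ) |> reindex_events()
}

qualifying_labs <- function(ids) {
  dplyr::bind_rows(
    make_labs(ids, 0L, "creatinine", 1.0),
    make_labs(ids, 0L, "bilirubin_total", 0.5),
    make_labs(ids, 0L, "platelets", 250000)
  ) |> reindex_labs()
}

reindex_events <- function(ev) {
  ev$event_id <- seq_len(nrow(ev))
  ev
}

reindex_labs <- function(lb) {
  lb$lab_id <- seq_len(nrow(lb))
  lb
}

make_index <- function(ids, admission_day = 0L, discharge_day = 7L) {
  tibble::tibble(patient_id = as.integer(ids),
                 admission_day = as.integer(admission_day),
                 discharge_day = as.integer(discharge_day))
}

# expand a 2x2 exposure x outcome table into patient-level rows with inert
# covariates, for closed-form logistic checks
cells_to_rows <- function(a, b, c, d) {
  # a: exposed cases, b: exposed non-cases, c: unexposed cases, d: unexposed
  tibble::tibble(
    high_risk = rep(c(TRUE, TRUE, FALSE, FALSE), times = c(a, b, c, d)),
    sepsis = rep(c(TRUE, FALSE, TRUE, FALSE), times = c(a, b, c, d)),
    severe_renal = FALSE
  )
}
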