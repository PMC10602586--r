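#' Configuration for the synthetic EHR generator
#'
#' Bundles and validates every tunable of the synthetic-cohort generator.
#' Defaults encode the study conditions the package is built around: a
#' combined G1+G2 risk-haplotype frequency of 0.40 so that, under the
#' recessive model, 16% of patients carry a high-risk genotype; severe renal
#' disease enriched in the high-risk group (35% vs 18%); a sepsis risk acting
#' through severe renal disease (odds ratio 3) with no direct genotype effect;
#' an overall sepsis proportion near 25%; and organ-dysfunction / mortality
#' mixes matching the observed secondary-outcome proportions among sepsis
#' cases.
#'
#' @param n_patients Number of patients to simulate.
#' @param freq_g1,freq_g2 Population haplotype frequencies of the G1 and G2
#'   risk haplotypes; `freq_g1 + freq_g2` must not exceed 1 (G1, G2 and the
#'   reference haplotype are mutually exclusive).
#' @param p_severe_renal_given_highrisk,p_severe_renal_given_lowrisk
#'   Probability of pre-existing severe renal disease by genotype group.
#' @param or_sepsis_renal Odds ratio of sepsis for severe renal disease.
#' @param or_sepsis_genotype_direct Direct (renal-independent) odds ratio of
#'   sepsis for the high-risk genotype; 1 means purely renal-mediated risk.
#' @param baseline_sepsis_prob Sepsis probability for a low-risk patient
#'   without severe renal disease.
#' @param organ_mix Named probabilities, among sepsis cases, of each of the
#'   five organ-dysfunction criteria plus a septic-shock billing code. Drawn
#'   independently, so a case may satisfy several; a case drawing none is
#'   assigned the shock code so that latent sepsis always has support.
#' @param comorbidity_rates Named vector of 17 Charlson/Deyo category
#'   prevalences.
#' @param infection_type_rates Named vector of 10 infection-type prevalences
#'   (multi-label; a patient drawing none is assigned "other").
#' @param mortality_given_sepsis Probability of short-term mortality
#'   (in-hospital death or hospice discharge) among sepsis cases.
#' @param p_covid,p_under18,p_missing_labs,p_missing_genotype,p_excluded_admission
#'   Optional contamination knobs (all default 0, i.e. a noise-free cohort):
#'   probability of a COVID-19 code in the admission window, of being a minor,
#'   of having no peri-admission labs, of an uncallable genotype, and of
#'   carrying an admission-exclusion code (cardiac surgery).
#' @param seed Integer seed; identical configurations produce byte-identical
#'   output.
#' @return A validated list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 500, seed = 42)
#' pop <- simulate_ehr(cfg)
#' names(pop)
sim_config <- function(n_patients = 2000,
                       freq_g1 = 0.27,
                       freq_g2 = 0.13,
                       p_severe_renal_given_highrisk = 0.35,
                       p_severe_renal_given_lowrisk = 0.18,
                       or_sepsis_renal = 3.0,
                       or_sepsis_genotype_direct = 1.0,
                       baseline_sepsis_prob = 0.205,
                       organ_mix = c(circulatory = 0.161, respiratory = 0.241,
                                     renal = 0.536, hepatic = 0.147,
                                     hematologic = 0.181, shock_code = 0.288),
                       comorbidity_rates = default_comorbidity_rates(),
                       infection_type_rates = default_infection_type_rates(),
                       mortality_given_sepsis = 0.149,
                       p_covid = 0,
                       p_under18 = 0,
                       p_missing_labs = 0,
                       p_missing_genotype = 0,
                       p_excluded_admission = 0,
                       seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 0 ||
      n_patients != floor(n_patients)) {
    abort("`n_patients` must be a non-negative integer.", class = "apol1_config_error")
  }
  assert_prob(freq_g1, "freq_g1")
  assert_prob(freq_g2, "freq_g2")
  if (freq_g1 + freq_g2 > 1) {
    abort("`freq_g1 + freq_g2` must not exceed 1.", class = "apol1_config_error")
  }
  assert_prob(p_severe_renal_given_highrisk, "p_severe_renal_given_highrisk")
  assert_prob(p_severe_renal_given_lowrisk, "p_severe_renal_given_lowrisk")
  assert_pos(or_sepsis_renal, "or_sepsis_renal")
  assert_pos(or_sepsis_genotype_direct, "or_sepsis_genotype_direct")
  assert_prob(baseline_sepsis_prob, "baseline_sepsis_prob")
  needed_mix <- c("circulatory", "respiratory", "renal", "hepatic",
                  "hematologic", "shock_code")
  if (!all(needed_mix %in% names(organ_mix))) {
    abort(sprintf("`organ_mix` must name all of: %s.",
                  paste(needed_mix, collapse = ", ")),
          class = "apol1_config_error")
  }
  assert_prob(organ_mix, "organ_mix")
  if (length(comorbidity_rates) != 17L) {
    abort("`comorbidity_rates` must have 17 entries.", class = "apol1_config_error")
  }
  assert_prob(comorbidity_rates, "comorbidity_rates")
  if (length(infection_type_rates) != 10L) {
    abort("`infection_type_rates` must have 10 entries.", class = "apol1_config_error")
  }
  assert_prob(infection_type_rates, "infection_type_rates")
  assert_prob(mortality_given_sepsis, "mortality_given_sepsis")
  for (nm in c("p_covid", "p_under18", "p_missing_labs", "p_missing_genotype",
               "p_excluded_admission")) {
    assert_prob(get(nm), nm)
  }
  structure(list(
    n_patients = as.integer(n_patients),
    freq_g1 = freq_g1, freq_g2 = freq_g2,
    p_severe_renal_given_highrisk = p_severe_renal_given_highrisk,
    p_severe_renal_given_lowrisk = p_severe_renal_given_lowrisk,
    or_sepsis_renal = or_sepsis_renal,
    or_sepsis_genotype_direct = or_sepsis_genotype_direct,
    baseline_sepsis_prob = baseline_sepsis_prob,
    organ_mix = organ_mix[needed_mix],
    comorbidity_rates = comorbidity_rates,
    infection_type_rates = infection_type_rates,
    mortality_given_sepsis = mortality_given_sepsis,
    p_covid = p_covid, p_under18 = p_under18,
    p_missing_labs = p_missing_labs,
    p_missing_genotype = p_missing_genotype,
    p_excluded_admission = p_excluded_admission,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_comorbidity_rates <- function() {
  c(myocardial_infarction = 0.099, congestive_heart_failure = 0.139,
    peripheral_vascular = 0.063, cerebrovascular = 0.099, dementia = 0.017,
    chronic_pulmonary = 0.169, rheumatic = 0.033, peptic_ulcer = 0.010,
    mild_liver = 0.017, diabetes_uncomplicated = 0.076,
    diabetes_complicated = 0.109, hemiplegia_paraplegia = 0.021,
    renal_disease = 0.243, malignancy = 0.166, moderate_severe_liver = 0.022,
    metastatic_tumor = 0.088, aids_hiv = 0.020)
}

#' @rdname sim_config
#' @export
default_infection_type_rates <- function() {
  c(circulatory = 0.016, digestive = 0.110, genitourinary = 0.343,
    intestinal = 0.027, musculoskeletal = 0.049, neurologic = 0.019,
    other_bacterial = 0.393, respiratory = 0.318, skin = 0.145,
    other = 0.144)
}

#' Draw APOL1 G1/G2 allele counts under the trinomial haplotype model
#'
#' Each patient receives two haplotypes drawn independently from
#' \{G1, G2, reference\} with probabilities `(freq_g1, freq_g2,
#' 1 - freq_g1 - freq_g2)`, so `g1_dosage + g2_dosage <= 2` always holds and
#' the expected high-risk (two risk alleles) fraction is
#' `(freq_g1 + freq_g2)^2`. Uses the current RNG state.
#'
#' @param n Number of patients.
#' @param freq_g1,freq_g2 Haplotype frequencies; their sum must not exceed 1.
#' @return A tibble with integer columns `g1_dosage` and `g2_dosage`.
#' @export
#' @examples
#' set.seed(1)
#' g <- draw_genotypes(1000, 0.27, 0.13)
#' mean(g$g1_dosage + g$g2_dosage >= 2) # about 0.40^2 = 0.16
draw_genotypes <- function(n, freq_g1, freq_g2) {
  assert_prob(freq_g1, "freq_g1")
  assert_prob(freq_g2, "freq_g2")
  if (freq_g1 + freq_g2 > 1) {
    abort("`freq_g1 + freq_g2` must not exceed 1.", class = "apol1_config_error")
  }
  probs <- c(freq_g1, freq_g2, 1 - freq_g1 - freq_g2)
  h1 <- sample.int(3L, n, replace = TRUE, prob = probs)
  h2 <- sample.int(3L, n, replace = TRUE, prob = probs)
  tibble::tibble(
    g1_dosage = as.integer((h1 == 1L) + (h2 == 1L)),
    g2_dosage = as.integer((h1 == 2L) + (h2 == 2L))
  )
}

# Latent layer shared by simulate_cohort() and simulate_ehr(): one row per
# patient with genotype, demographics, disease status, per-criterion truth,
# infection types, comorbidity draws and admission frame.
simulate_latent <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  geno <- draw_genotypes(n, config$freq_g1, config$freq_g2)
  high_risk <- (geno$g1_dosage + geno$g2_dosage) >= 2L

  age <- as.integer(round(pmin(pmax(stats::rnorm(n, 48, 17), 18), 95)))
  under18 <- stats::runif(n) < config$p_under18
  age[under18] <- sample(5:17, sum(under18), replace = TRUE)
  sex <- ifelse(stats::runif(n) < 0.583, "female", "male")
  pcs <- matrix(stats::rnorm(3L * n), ncol = 3,
                dimnames = list(NULL, c("pc1", "pc2", "pc3")))

  p_renal <- ifelse(high_risk, config$p_severe_renal_given_highrisk,
                    config$p_severe_renal_given_lowrisk)
  severe_renal <- stats::runif(n) < p_renal

  lp <- stats::qlogis(config$baseline_sepsis_prob) +
    log(config$or_sepsis_renal) * severe_renal +
    log(config$or_sepsis_genotype_direct) * high_risk
  sepsis <- stats::runif(n) < stats::plogis(lp)

  draw_flags <- function(probs, gate = rep(TRUE, n)) {
    m <- matrix(FALSE, nrow = n, ncol = length(probs),
                dimnames = list(NULL, names(probs)))
    for (j in seq_along(probs)) {
      m[, j] <- gate & (stats::runif(n) < probs[j])
    }
    m
  }
  crit <- draw_flags(config$organ_mix, gate = sepsis)
  # latent sepsis must be witnessed by at least one criterion
  none <- sepsis & rowSums(crit) == 0L
  crit[none, "shock_code"] <- TRUE
  mortality <- sepsis & (stats::runif(n) < config$mortality_given_sepsis)

  itypes <- draw_flags(config$infection_type_rates)
  no_type <- rowSums(itypes) == 0L
  itypes[no_type, "other"] <- TRUE

  com <- draw_flags(config$comorbidity_rates)

  discharge_day <- sample(3:14, n, replace = TRUE)
  hospice <- mortality & stats::runif(n) < 0.5
  disposition <- ifelse(mortality, ifelse(hospice, "hospice", "expired"), "home")
  death_day <- ifelse(mortality & !hospice, discharge_day, NA_integer_)

  birth_offset <- sample(0:360, n, replace = TRUE)
  birth_day <- -(as.integer(ceiling(age * 365.25)) + birth_offset)

  missing_geno <- stats::runif(n) < config$p_missing_genotype
  g1 <- geno$g1_dosage; g2 <- geno$g2_dosage
  g1[missing_geno] <- NA_integer_; g2[missing_geno] <- NA_integer_

  list(
    patients = tibble::tibble(
      patient_id = seq_len(n),
      birth_day = as.integer(birth_day),
      age = age,
      sex = sex,
      g1_dosage = g1, g2_dosage = g2,
      pc1 = pcs[, 1], pc2 = pcs[, 2], pc3 = pcs[, 3],
      covid_positive = FALSE,
      death_day = as.integer(death_day),
      disposition = disposition
    ),
    admissions = tibble::tibble(
      admission_id = seq_len(n),
      patient_id = seq_len(n),
      admission_day = 0L,
      discharge_day = as.integer(discharge_day)
    ),
    high_risk = high_risk, severe_renal = severe_renal, sepsis = sepsis,
    criteria = crit, mortality = mortality, infection_types = itypes,
    comorbidity = com,
    covid = stats::runif(n) < config$p_covid,
    missing_labs = stats::runif(n) < config$p_missing_labs,
    excluded_admission = stats::runif(n) < config$p_excluded_admission
  )
}

#' Simulate an analysis-ready cohort table (latent layer only)
#'
#' Draws the generator's latent layer -- genotype, covariates, severe renal
#' disease, sepsis and its criteria, short-term mortality -- and returns it as
#' one analysis-ready row per patient, skipping event/lab emission and the
#' phenotyping round trip. This is the fast path for Monte-Carlo studies of
#' the association machinery; [simulate_ehr()] with the same configuration
#' produces event streams whose phenotyped calls equal these columns exactly.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per patient: `patient_id`, `high_risk`,
#'   dosages, `age`, `sex`, `pc1`--`pc3`, `severe_renal`, `sepsis`,
#'   `shock_code`, the five criterion flags, and `short_term_mortality`.
#' @export
simulate_cohort <- function(config) {
  lat <- simulate_latent(config)
  dplyr::bind_cols(
    lat$patients[, c("patient_id", "age", "sex", "g1_dosage", "g2_dosage",
                     "pc1", "pc2", "pc3")],
    tibble::tibble(
      high_risk = lat$high_risk,
      severe_renal = lat$severe_renal,
      sepsis = lat$sepsis,
      shock_code = lat$criteria[, "shock_code"],
      circulatory = lat$criteria[, "circulatory"],
      respiratory = lat$criteria[, "respiratory"],
      renal = lat$criteria[, "renal"],
      hepatic = lat$criteria[, "hepatic"],
      hematologic = lat$criteria[, "hematologic"],
      short_term_mortality = lat$mortality
    )
  )
}

new_events <- function(patient_id, day, code_system, code, value = NA_real_) {
  tibble::tibble(patient_id = as.integer(patient_id), day = as.integer(day),
                 code_system = code_system, code = code,
                 value = as.double(value))
}

new_labs <- function(patient_id, day, analyte, value, units) {
  tibble::tibble(patient_id = as.integer(patient_id), day = as.integer(day),
                 analyte = analyte, value = value, units = units)
}

#' Generate a synthetic longitudinal EHR population with known ground truth
#'
#' Emits patient, admission, coded-event and lab tables whose rows
#' deterministically satisfy -- or deterministically fail -- each rule the
#' downstream cohort and phenotyping modules evaluate, so that every latent
#' flag is exactly recoverable. Per criterion:
#' \itemize{
#'   \item renal: a baseline creatinine plus a peri-admission value at or
#'     above (true) / safely below (false) twice the baseline;
#'   \item hepatic: bilirubin at or above 2 mg/dL and twice baseline, or well
#'     below both;
#'   \item hematologic: platelets falling below 100,000/uL and to at most half
#'     of a baseline that exceeds 100,000, or staying above threshold;
#'   \item respiratory: ventilation plus ICU codes (true) vs at most one of
#'     the pair (decoy noise);
#'   \item circulatory: norepinephrine, or for a fraction of cases
#'     dobutamine/dopamine with enough keyword mentions and no stress-echo
#'     CPT; decoys carry dopamine together with a stress-echo code;
#'   \item shock: one of the four septic-shock/severe-sepsis billing codes.
#' }
#' Every patient receives an infection billing code and an antibiotic within
#' a day of admission, so that with the contamination knobs at their default
#' of zero the whole population qualifies for the infection cohort.
#'
#' @param config A [sim_config()].
#' @param codes A code configuration (defaults to [default_codes()]); event
#'   emission samples codes from these lists.
#' @return An object of class `"apol1_sim"`: a list with tibbles `patients`,
#'   `admissions`, `events`, `labs`, `ground_truth` and the `config`.
#' @export
simulate_ehr <- function(config, codes = default_codes()) {
  validate_codes(codes)
  lat <- simulate_latent(config)
  n <- config$n_patients
  ids <- seq_len(n)
  ev <- list()
  lb <- list()

  # infection billing codes (multi-label) in the peri-admission window
  for (ty in names(codes$infection_types)) {
    who <- ids[lat$infection_types[, ty]]
    if (length(who)) {
      ev[[length(ev) + 1L]] <- new_events(
        who, sample(-1:1, length(who), replace = TRUE), "ICD10CM",
        codes$infection_types[[ty]]$icd10[1])
    }
  }
  # an antibiotic for everyone, within a day of admission
  if (n > 0) {
    ev[[length(ev) + 1L]] <- new_events(
      ids, sample(-1:1, n, replace = TRUE), "MED",
      sample(codes$antibiotics, n, replace = TRUE))
  }
  # comorbidity codes in the Charlson lookback year
  for (cat in colnames(lat$comorbidity)) {
    who <- ids[lat$comorbidity[, cat]]
    if (length(who)) {
      ev[[length(ev) + 1L]] <- new_events(
        who, sample(-365:-30, length(who), replace = TRUE), "ICD10CM",
        codes$charlson[[cat]]$icd10[1])
    }
  }
  # pre-existing severe renal disease, anywhere in the prior record
  who <- ids[lat$severe_renal]
  if (length(who)) {
    srl <- codes$severe_renal
    ev[[length(ev) + 1L]] <- new_events(
      who, sample(-400:-30, length(who), replace = TRUE),
      ifelse(grepl("^[A-Z]", srl[pick <- sample(length(srl), length(who), replace = TRUE)]),
             "ICD10CM", "ICD9CM"),
      srl[pick])
  }
  # keyword mention counts: all sepsis cases clear the >=2 gate
  who <- ids[lat$sepsis]
  if (length(who)) {
    ev[[length(ev) + 1L]] <- new_events(
      who, 0L, "KEYWORD", sample(codes$keywords, length(who), replace = TRUE),
      sample(2:6, length(who), replace = TRUE))
  }
  who <- ids[!lat$sepsis & stats::runif(n) < 0.3]
  if (length(who)) {
    ev[[length(ev) + 1L]] <- new_events(who, 0L, "KEYWORD", "infection", 1)
  }

  crit <- lat$criteria
  # circulatory: branch (a) norepinephrine or branch (b) dobutamine/dopamine
  circ <- ids[crit[, "circulatory"]]
  use_b <- stats::runif(length(circ)) < 0.3
  if (any(!use_b)) {
    ev[[length(ev) + 1L]] <- new_events(circ[!use_b], 0L, "MED",
                                        codes$vasopressors$norepinephrine[1])
  }
  if (any(use_b)) {
    ev[[length(ev) + 1L]] <- new_events(
      circ[use_b], 0L, "MED",
      sample(codes$vasopressors$conditional, sum(use_b), replace = TRUE))
  }
  # decoys: dopamine tied to a stress echo never counts
  decoy <- ids[!crit[, "circulatory"] & stats::runif(n) < 0.05]
  if (length(decoy)) {
    ev[[length(ev) + 1L]] <- new_events(decoy, 0L, "MED",
                                        codes$vasopressors$conditional[1])
    ev[[length(ev) + 1L]] <- new_events(decoy, 0L, "CPT",
                                        sample(codes$stress_echo_cpt, length(decoy), replace = TRUE))
  }
  # respiratory: ventilation AND ICU; decoys carry only one of the pair
  resp <- ids[crit[, "respiratory"]]
  if (length(resp)) {
    ev[[length(ev) + 1L]] <- new_events(resp, 0L, "CPT", codes$ventilation$cpt[1])
    ev[[length(ev) + 1L]] <- new_events(resp, 0L, "CPT", codes$icu$cpt[1])
  }
  vent_only <- ids[!crit[, "respiratory"] & stats::runif(n) < 0.03]
  if (length(vent_only)) {
    ev[[length(ev) + 1L]] <- new_events(vent_only, 0L, "CPT", codes$ventilation$cpt[1])
  }
  # decoys stay one-sided: a patient never gets both halves of the pair
  icu_only <- ids[!crit[, "respiratory"] & !(ids %in% vent_only) &
                    stats::runif(n) < 0.05]
  if (length(icu_only)) {
    ev[[length(ev) + 1L]] <- new_events(icu_only, 0L, "CPT", codes$icu$cpt[1])
  }
  # septic shock / severe sepsis billing codes
  shock <- ids[crit[, "shock_code"]]
  if (length(shock)) {
    sc <- c(codes$shock_codes$icd9, codes$shock_codes$icd10)
    pick <- sample(length(sc), length(shock), replace = TRUE)
    ev[[length(ev) + 1L]] <- new_events(
      shock, sample(-1:1, length(shock), replace = TRUE),
      ifelse(pick <= length(codes$shock_codes$icd9), "ICD9CM", "ICD10CM"),
      sc[pick])
  }
  # contamination knobs
  who <- ids[lat$covid]
  if (length(who)) ev[[length(ev) + 1L]] <- new_events(who, 0L, "ICD10CM", codes$covid[1])
  who <- ids[lat$excluded_admission]
  if (length(who)) {
    ev[[length(ev) + 1L]] <- new_events(who, 0L, "CPT",
                                        codes$exclusions$cardiac_surgery$cpt[1])
  }

  # labs: baseline + peri-admission value per analyte, margins keep every
  # comparison safely away from the inclusive thresholds
  haslab <- !lat$missing_labs
  m <- sum(haslab)
  if (m > 0) {
    hid <- ids[haslab]
    base_day <- sample(-300:-20, m, replace = TRUE)
    win_day <- sample(-1:1, m, replace = TRUE)

    b_cr <- stats::runif(m, 0.6, 1.2)
    cr_true <- crit[haslab, "renal"]
    cr_win <- ifelse(cr_true, b_cr * stats::runif(m, 2.05, 3.0),
                     b_cr * stats::runif(m, 0.8, 1.8))
    lb[[length(lb) + 1L]] <- new_labs(rep(hid, 2), c(base_day, win_day),
                                      "creatinine", c(b_cr, cr_win), "mg/dL")

    b_bi <- stats::runif(m, 0.3, 0.7)
    bi_true <- crit[haslab, "hepatic"]
    bi_win <- ifelse(bi_true, pmax(2.05, 2.1 * b_bi) * stats::runif(m, 1.0, 1.15),
                     b_bi * stats::runif(m, 0.9, 1.8))
    lb[[length(lb) + 1L]] <- new_labs(rep(hid, 2), c(base_day, win_day),
                                      "bilirubin_total", c(b_bi, bi_win), "mg/dL")

    b_pl <- stats::runif(m, 180, 320)
    pl_true <- crit[haslab, "hematologic"]
    pl_win <- ifelse(pl_true,
                     40 + stats::runif(m) * (pmin(90, 0.45 * b_pl) - 40),
                     b_pl * stats::runif(m, 0.60, 0.85))
    lb[[length(lb) + 1L]] <- new_labs(rep(hid, 2), c(base_day, win_day),
                                      "platelets", c(b_pl, pl_win), "10^3/uL")
  }

  events <- if (length(ev)) dplyr::bind_rows(ev) else
    new_events(integer(), integer(), character(), character(), double())
  events <- dplyr::arrange(events, .data$patient_id, .data$day,
                           .data$code_system, .data$code)
  events$event_id <- seq_len(nrow(events))
  events <- dplyr::relocate(events, "event_id")

  labs <- if (length(lb)) dplyr::bind_rows(lb) else
    new_labs(integer(), integer(), character(), double(), character())
  labs <- dplyr::arrange(labs, .data$patient_id, .data$day, .data$analyte)
  labs$lab_id <- seq_len(nrow(labs))
  labs <- dplyr::relocate(labs, "lab_id")

  type_labels <- apply(lat$infection_types, 1, function(r)
    paste(colnames(lat$infection_types)[r], collapse = ";"))
  ground_truth <- tibble::tibble(
    patient_id = ids,
    true_high_risk = lat$high_risk,
    true_severe_renal = lat$severe_renal,
    true_sepsis = lat$sepsis,
    true_circulatory = crit[, "circulatory"],
    true_respiratory = crit[, "respiratory"],
    true_renal = crit[, "renal"],
    true_hepatic = crit[, "hepatic"],
    true_hematologic = crit[, "hematologic"],
    true_shock_code = crit[, "shock_code"],
    true_mortality = lat$mortality,
    infection_types = if (n > 0) type_labels else character()
  )

  structure(list(patients = lat$patients, admissions = lat$admissions,
                 events = events, labs = labs, ground_truth = ground_truth,
                 config = config),
            class = "apol1_sim")
}

#' @export
print.apol1_sim <- function(x, ...) {
  cat("<apol1_sim> synthetic EHR population\n")
  cat(sprintf("  patients: %d | admissions: %d | events: %d | labs: %d\n",
              nrow(x$patients), nrow(x$admissions), nrow(x$events),
              nrow(x$labs)))
  cat(sprintf("  seed: %d | latent sepsis: %d | high-risk: %d\n",
              x$config$seed, sum(x$ground_truth$true_sepsis),
              sum(x$ground_truth$true_high_risk)))
  invisible(x)
}

fixture_files <- c(patients = "patients.csv", admissions = "admissions.csv",
                   events = "events.csv", labs = "labs.csv",
                   ground_truth = "ground_truth.csv")

#' Write or read a synthetic population as a CSV fixture
#'
#' `write_fixture()` writes `patients.csv`, `admissions.csv`, `events.csv`,
#' `labs.csv` and `ground_truth.csv` (UTF-8, RFC-4180) into a directory;
#' `read_fixture()` reads them back with fully specified column types, so a
#' population round-trips losslessly.
#'
#' @param sim An `"apol1_sim"` object from [simulate_ehr()].
#' @param dir Directory to write into (created if absent) / read from.
#' @return `write_fixture()` returns the file paths invisibly;
#'   `read_fixture()` returns a list of the five tibbles.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "apol1_sim"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create directory: %s", dir), class = "apol1_io_error")
  }
  paths <- file.path(dir, fixture_files)
  names(paths) <- names(fixture_files)
  for (nm in names(fixture_files)) {
    readr::write_csv(sim[[nm]], paths[[nm]], progress = FALSE)
  }
  invisible(paths)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  paths <- file.path(dir, fixture_files)
  missing <- fixture_files[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(sprintf("Fixture directory %s is missing: %s", dir,
                  paste(missing, collapse = ", ")),
          class = "apol1_io_error")
  }
  types <- list(
    patients = readr::cols(
      patient_id = readr::col_integer(), birth_day = readr::col_integer(),
      age = readr::col_integer(), sex = readr::col_character(),
      g1_dosage = readr::col_integer(), g2_dosage = readr::col_integer(),
      pc1 = readr::col_double(), pc2 = readr::col_double(),
      pc3 = readr::col_double(), covid_positive = readr::col_logical(),
      death_day = readr::col_integer(), disposition = readr::col_character()),
    admissions = readr::cols(
      admission_id = readr::col_integer(), patient_id = readr::col_integer(),
      admission_day = readr::col_integer(), discharge_day = readr::col_integer()),
    events = readr::cols(
      event_id = readr::col_integer(), patient_id = readr::col_integer(),
      day = readr::col_integer(), code_system = readr::col_character(),
      code = readr::col_character(), value = readr::col_double()),
    labs = readr::cols(
      lab_id = readr::col_integer(), patient_id = readr::col_integer(),
      day = readr::col_integer(), analyte = readr::col_character(),
      value = readr::col_double(), units = readr::col_character()),
    ground_truth = readr::cols(
      patient_id = readr::col_integer(),
      true_high_risk = readr::col_logical(),
      true_severe_renal = readr::col_logical(),
      true_sepsis = readr::col_logical(),
      true_circulatory = readr::col_logical(),
      true_respiratory = readr::col_logical(),
      true_renal = readr::col_logical(),
      true_hepatic = readr::col_logical(),
      true_hematologic = readr::col_logical(),
      true_shock_code = readr::col_logical(),
      true_mortality = readr::col_logical(),
      infection_types = readr::col_character())
  )
  out <- lapply(names(fixture_files), function(nm) {
    readr::read_csv(file.path(dir, fixture_files[[nm]]), col_types = types[[nm]],
                    progress = FALSE)
  })
  names(out) <- names(fixture_files)
  out
}
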