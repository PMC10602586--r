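#' Evaluate the adapted EHR Sepsis-3 algorithm for each index admission
#'
#' A patient meets the sepsis definition when they carry one of the four
#' septic-shock / severe-sepsis billing codes (ICD-9-CM 995.92, 785.52;
#' ICD-10-CM R65.20, R65.21) on days -1, 0 or +1, or meet any of five
#' organ-dysfunction criteria:
#' \describe{
#'   \item{circulatory}{norepinephrine use, or dobutamine/dopamine use that is
#'     unrelated to a stress echocardiogram (no stress-echo CPT in the window)
#'     with at least two summed note mentions of infection/sepsis/septic;}
#'   \item{respiratory}{ventilation codes together with an ICU marker;}
#'   \item{renal}{peri-admission creatinine at least double the baseline
#'     (lowest value from one year before admission through discharge);}
#'   \item{hepatic}{total bilirubin at least 2 mg/dL (34.2 umol/L) and at
#'     least double the baseline;}
#'   \item{hematologic}{platelets below 100,000/uL having declined by at
#'     least half from a baseline that was itself at least 100,000.}
#' }
#' Lab criteria are evaluated on days -1, 0, +1 relative to admission; a
#' missing baseline makes the criterion false (dysfunction cannot be asserted
#' without a reference) and is tallied in the `"n_no_baseline"` attribute.
#' Every true flag carries machine-readable evidence: the ids
#' (`E<event_id>` / `L<lab_id>`) of the rows that triggered it.
#'
#' @param index Index admissions: tibble with `patient_id`, `admission_day`,
#'   `discharge_day` (one row per patient).
#' @param patients Patient table with `death_day` and `disposition` (used for
#'   short-term mortality).
#' @param events Coded events (`event_id`, `patient_id`, `day`,
#'   `code_system`, `code`, `value`).
#' @param labs Raw labs; normalized internally via [normalize_labs()].
#' @param codes Code configuration, see [default_codes()].
#' @param thresholds A [sepsis_thresholds()] object.
#' @return A tibble, one row per index patient: `sepsis`, `via_shock_code`,
#'   the five criterion flags, `short_term_mortality`, per-criterion evidence
#'   strings, and the three baseline values.
#' @export
phenotype_sepsis <- function(index, patients, events, labs,
                             codes = default_codes(),
                             thresholds = sepsis_thresholds()) {
  validate_codes(codes)
  stopifnot(inherits(thresholds, "sepsis_thresholds"))
  if (anyDuplicated(index$patient_id)) {
    abort("`index` must have one row per patient.", class = "apol1_validation_error")
  }
  idx <- index[, c("patient_id", "admission_day", "discharge_day")]
  if (!"event_id" %in% names(events)) {
    events <- dplyr::mutate(events, event_id = dplyr::row_number())
  }
  if (!"lab_id" %in% names(labs) && nrow(labs) > 0) {
    labs <- dplyr::mutate(labs, lab_id = dplyr::row_number())
  }

  labs_n <- normalize_labs(labs)
  base <- compute_baselines(labs_n, idx)
  base_wide <- tidyr::pivot_wider(base, names_from = "analyte",
                                  values_from = "baseline")
  for (an in c("creatinine", "bilirubin_total", "platelets")) {
    if (!an %in% names(base_wide)) base_wide[[an]] <- NA_real_
  }

  # peri-admission labs (days -1..+1), with that patient's baseline attached
  lw <- dplyr::inner_join(labs_n, idx, by = "patient_id")
  lw <- dplyr::filter(lw, .data$day >= .data$admission_day - 1L,
                      .data$day <= .data$admission_day + 1L)
  lw <- dplyr::left_join(lw, base, by = c("patient_id", "analyte"))

  lab_crit <- function(an, hit_fun) {
    d <- dplyr::filter(lw, .data$analyte == an, !is.na(.data$baseline))
    d <- dplyr::filter(d, hit_fun(.data$value, .data$baseline))
    dplyr::summarise(dplyr::group_by(d, .data$patient_id),
                     evidence = semi_join_ids(paste0("L", .data$lab_id)),
                     .groups = "drop")
  }
  renal_hits <- lab_crit("creatinine", function(v, b)
    v >= thresholds$creatinine_fold * b)
  hepatic_hits <- lab_crit("bilirubin_total", function(v, b)
    v >= thresholds$bilirubin_abs & v >= thresholds$bilirubin_fold * b)
  hema_hits <- lab_crit("platelets", function(v, b)
    b >= thresholds$platelet_abs & v < thresholds$platelet_abs &
      v <= (1 - thresholds$platelet_decline) * b)

  # events relative to each patient's index admission
  ew <- dplyr::inner_join(events, idx, by = "patient_id")
  ew <- dplyr::mutate(ew, rel = .data$day - .data$admission_day,
                      ncode = norm_code(.data$code))
  peri <- dplyr::filter(ew, .data$rel >= -1L, .data$rel <= 1L)
  stay <- dplyr::filter(ew, .data$rel >= -1L,
                        .data$day <= .data$discharge_day)
  resp_scope <- if (thresholds$respiratory_window == "stay") stay else peri

  collect <- function(d) {
    dplyr::summarise(dplyr::group_by(d, .data$patient_id),
                     evidence = semi_join_ids(paste0("E", .data$event_id)),
                     .groups = "drop")
  }
  in_set <- function(d, system, set) {
    dplyr::filter(d, .data$code_system == system,
                  .data$ncode %in% norm_code(set))
  }

  shock_set <- dplyr::bind_rows(
    in_set(peri, "ICD9CM", codes$shock_codes$icd9),
    in_set(peri, "ICD10CM", codes$shock_codes$icd10))
  shock_hits <- collect(shock_set)

  vent <- dplyr::bind_rows(
    in_set(resp_scope, "CPT", codes$ventilation$cpt),
    in_set(resp_scope, "ICD9CM", codes$ventilation$icd9),
    in_set(resp_scope, "ICD10CM", codes$ventilation$icd10))
  icu <- in_set(resp_scope, "CPT", codes$icu$cpt)
  resp_ids <- intersect(unique(vent$patient_id), unique(icu$patient_id))
  resp_hits <- collect(dplyr::bind_rows(
    dplyr::filter(vent, .data$patient_id %in% resp_ids),
    dplyr::filter(icu, .data$patient_id %in% resp_ids)))

  meds <- dplyr::mutate(dplyr::filter(peri, .data$code_system == "MED"),
                        drug = tolower(.data$code))
  norepi <- dplyr::filter(meds, .data$drug %in% tolower(codes$vasopressors$norepinephrine))
  condv <- dplyr::filter(meds, .data$drug %in% tolower(codes$vasopressors$conditional))
  echo_ids <- unique(in_set(peri, "CPT", codes$stress_echo_cpt)$patient_id)
  kw <- dplyr::filter(peri, .data$code_system == "KEYWORD",
                      tolower(.data$code) %in% tolower(codes$keywords))
  kw_sum <- dplyr::summarise(dplyr::group_by(kw, .data$patient_id),
                             mentions = sum(.data$value, na.rm = TRUE),
                             .groups = "drop")
  kw_ok <- kw_sum$patient_id[kw_sum$mentions >= thresholds$keyword_min_mentions]
  branch_a <- norepi
  if (thresholds$keyword_gate_branch_a) {
    branch_a <- dplyr::filter(branch_a, .data$patient_id %in% kw_ok)
  }
  branch_b <- dplyr::filter(condv, !(.data$patient_id %in% echo_ids),
                            .data$patient_id %in% kw_ok)
  circ_hits <- collect(dplyr::bind_rows(branch_a, branch_b))

  pt <- dplyr::left_join(
    idx, patients[, c("patient_id", "death_day", "disposition")],
    by = "patient_id")
  mortality <- with(pt, (!is.na(death_day) & death_day >= admission_day &
                           death_day <= discharge_day) |
                      (!is.na(disposition) & disposition == "hospice"))

  take <- function(hits, col_flag, col_ev) {
    m <- match(idx$patient_id, hits$patient_id)
    flag <- !is.na(m)
    ev <- ifelse(flag, hits$evidence[m], "")
    setNames(list(flag, ev), c(col_flag, col_ev))
  }
  parts <- c(
    take(shock_hits, "via_shock_code", "evidence_shock_code"),
    take(circ_hits, "circulatory", "evidence_circulatory"),
    take(resp_hits, "respiratory", "evidence_respiratory"),
    take(renal_hits, "renal", "evidence_renal"),
    take(hepatic_hits, "hepatic", "evidence_hepatic"),
    take(hema_hits, "hematologic", "evidence_hematologic"))

  bm <- match(idx$patient_id, base_wide$patient_id)
  out <- tibble::tibble(
    patient_id = idx$patient_id,
    sepsis = parts$via_shock_code | parts$circulatory | parts$respiratory |
      parts$renal | parts$hepatic | parts$hematologic,
    via_shock_code = parts$via_shock_code,
    circulatory = parts$circulatory,
    respiratory = parts$respiratory,
    renal = parts$renal,
    hepatic = parts$hepatic,
    hematologic = parts$hematologic,
    short_term_mortality = mortality,
    evidence_shock_code = parts$evidence_shock_code,
    evidence_circulatory = parts$evidence_circulatory,
    evidence_respiratory = parts$evidence_respiratory,
    evidence_renal = parts$evidence_renal,
    evidence_hepatic = parts$evidence_hepatic,
    evidence_hematologic = parts$evidence_hematologic,
    baseline_creatinine = base_wide$creatinine[bm],
    baseline_bilirubin = base_wide$bilirubin_total[bm],
    baseline_platelets = base_wide$platelets[bm]
  )
  attr(out, "n_no_baseline") <- c(
    creatinine = sum(is.na(out$baseline_creatinine)),
    bilirubin_total = sum(is.na(out$baseline_bilirubin)),
    platelets = sum(is.na(out$baseline_platelets)))
  dplyr::arrange(out, .data$patient_id)
}

#' Short-term mortality for an index admission
#'
#' True when a death is recorded within the index stay (admission through
#' discharge day, inclusive) or the discharge disposition is hospice.
#'
#' @param death_day Integer day of death (NA if alive).
#' @param disposition Discharge disposition string (`"hospice"` triggers).
#' @param admission_day,discharge_day Stay boundaries.
#' @return Logical vector.
#' @export
short_term_mortality <- function(death_day, disposition, admission_day,
                                 discharge_day) {
  (!is.na(death_day) & death_day >= admission_day & death_day <= discharge_day) |
    (!is.na(disposition) & disposition == "hospice")
}
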