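# Covariate derivation: Charlson/Deyo comorbidity flags, pre-existing severe
# renal disease, infection-type categories.

#' Charlson/Deyo comorbidity flags
#'
#' Sets each of the 17 category flags when at least one mapped diagnosis code
#' occurs in the lookback year, days `[admission - 365, admission - 1]`;
#' events on or after the admission day never contribute. Category maps use
#' prefix matching on dot-stripped codes and are configuration data
#' ([default_codes()]).
#'
#' @param events Coded events.
#' @param index Index admissions (`patient_id`, `admission_day`).
#' @param codes Code configuration; `codes$charlson` must define all 17
#'   categories.
#' @return A tibble: `patient_id` plus 17 logical columns.
#' @export
charlson_flags <- function(events, index, codes = default_codes()) {
  if (length(codes$charlson) != 17L) {
    abort("The Charlson/Deyo map must define exactly 17 categories.",
          class = "apol1_config_error")
  }
  ew <- dplyr::inner_join(events,
                          index[, c("patient_id", "admission_day")],
                          by = "patient_id")
  ew <- dplyr::filter(ew, .data$day >= .data$admission_day - 365L,
                      .data$day <= .data$admission_day - 1L,
                      .data$code_system %in% c("ICD9CM", "ICD10CM"))
  ew$ncode <- norm_code(ew$code)
  out <- tibble::tibble(patient_id = index$patient_id)
  for (cat in names(codes$charlson)) {
    spec <- codes$charlson[[cat]]
    hit <- (ew$code_system == "ICD10CM" &
              match_any_prefix(ew$ncode, norm_code(spec$icd10 %||% character()))) |
      (ew$code_system == "ICD9CM" &
         match_any_prefix(ew$ncode, norm_code(spec$icd9 %||% character())))
    out[[cat]] <- out$patient_id %in% unique(ew$patient_id[hit])
  }
  out
}

#' Pre-existing severe renal disease (Stage 4/5 CKD / ESRD)
#'
#' True when at least one of the fifteen listed diagnosis/procedure codes
#' appears anywhere in the record up to and including the index admission
#' day. The list is matched exactly (after dot normalization, so `585.6` and
#' `5856` are equal) -- child codes such as `N18.3` never match -- and there
#' is no lookback limit, since these codes denote chronic states.
#'
#' @inheritParams charlson_flags
#' @return A tibble: `patient_id`, `severe_renal`, `triggering_code` (the
#'   earliest matching code, `NA` if none).
#' @export
severe_renal_flag <- function(events, index, codes = default_codes()) {
  target <- norm_code(codes$severe_renal)
  ew <- dplyr::inner_join(events,
                          index[, c("patient_id", "admission_day")],
                          by = "patient_id")
  ew <- dplyr::filter(ew, .data$day <= .data$admission_day,
                      .data$code_system %in% c("ICD9CM", "ICD10CM"))
  hits <- dplyr::filter(ew, norm_code(.data$code) %in% target)
  first <- dplyr::slice_head(
    dplyr::group_by(dplyr::arrange(hits, .data$patient_id, .data$day,
                                   .data$code),
                    .data$patient_id), n = 1L)
  first <- dplyr::ungroup(first)
  m <- match(index$patient_id, first$patient_id)
  tibble::tibble(
    patient_id = index$patient_id,
    severe_renal = !is.na(m),
    triggering_code = ifelse(is.na(m), NA_character_, first$code[m])
  )
}

#' Infection-type categories for the index admission
#'
#' Multi-label assignment over the ten configured infection categories from
#' billing codes on days -1, 0, +1 relative to admission (prefix match); a
#' patient can carry several types.
#'
#' @inheritParams charlson_flags
#' @return A tibble: `patient_id`, one logical column `infection_<type>` per
#'   category, and `infection_types` (semicolon-joined labels).
#' @export
infection_types <- function(events, index, codes = default_codes()) {
  ew <- dplyr::inner_join(events,
                          index[, c("patient_id", "admission_day")],
                          by = "patient_id")
  ew <- dplyr::filter(ew, .data$day >= .data$admission_day - 1L,
                      .data$day <= .data$admission_day + 1L,
                      .data$code_system %in% c("ICD9CM", "ICD10CM"))
  ew$ncode <- norm_code(ew$code)
  out <- tibble::tibble(patient_id = index$patient_id)
  labels <- rep("", nrow(index))
  for (ty in names(codes$infection_types)) {
    spec <- codes$infection_types[[ty]]
    hit <- (ew$code_system == "ICD10CM" &
              match_any_prefix(ew$ncode, norm_code(spec$icd10 %||% character()))) |
      (ew$code_system == "ICD9CM" &
         match_any_prefix(ew$ncode, norm_code(spec$icd9 %||% character())))
    flag <- out$patient_id %in% unique(ew$patient_id[hit])
    out[[paste0("infection_", ty)]] <- flag
    labels <- ifelse(flag, ifelse(labels == "", ty, paste(labels, ty, sep = ";")),
                     labels)
  }
  out$infection_types <- labels
  out
}
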