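#' Thresholds of the adapted EHR Sepsis-3 organ-dysfunction rules
#'
#' All fold-change comparisons downstream are inclusive (`>=`), reflecting
#' "doubling or greater". Units are internal standards: mg/dL for creatinine
#' and total bilirubin, cells/uL for platelets.
#'
#' @param creatinine_fold Peri-admission creatinine must reach this multiple
#'   of baseline (default 2).
#' @param bilirubin_abs Absolute bilirubin threshold in mg/dL (default 2,
#'   i.e. 34.2 umol/L).
#' @param bilirubin_fold Fold increase over baseline bilirubin (default 2).
#' @param platelet_abs Platelets must fall below this count per uL
#'   (default 100,000).
#' @param platelet_decline Required fractional decline from baseline
#'   (default 0.5, i.e. the window value is at most half the baseline).
#' @param keyword_min_mentions Minimum summed mentions of
#'   infection/sepsis/septic gating circulatory branch (b) (default 2).
#' @param keyword_gate_branch_a Should the keyword gate also apply to the
#'   norepinephrine branch (a)? Default `FALSE` (the documented reading).
#' @param respiratory_window `"stay"` (default) evaluates ventilation/ICU
#'   codes over the whole index stay (admission-1 through discharge);
#'   `"peri"` restricts them to days -1, 0, +1.
#' @return A list of class `"sepsis_thresholds"`.
#' @export
sepsis_thresholds <- function(creatinine_fold = 2.0,
                              bilirubin_abs = 2.0,
                              bilirubin_fold = 2.0,
                              platelet_abs = 1e5,
                              platelet_decline = 0.5,
                              keyword_min_mentions = 2,
                              keyword_gate_branch_a = FALSE,
                              respiratory_window = c("stay", "peri")) {
  for (nm in c("creatinine_fold", "bilirubin_abs", "bilirubin_fold",
               "platelet_abs", "keyword_min_mentions")) {
    assert_pos(get(nm), nm)
  }
  if (!is.numeric(platelet_decline) || platelet_decline <= 0 || platelet_decline >= 1) {
    abort("`platelet_decline` must be in (0, 1).", class = "apol1_config_error")
  }
  structure(list(
    creatinine_fold = creatinine_fold, bilirubin_abs = bilirubin_abs,
    bilirubin_fold = bilirubin_fold, platelet_abs = platelet_abs,
    platelet_decline = platelet_decline,
    keyword_min_mentions = keyword_min_mentions,
    keyword_gate_branch_a = isTRUE(keyword_gate_branch_a),
    respiratory_window = match.arg(respiratory_window)
  ), class = "sepsis_thresholds")
}

# unit -> multiplicative factor to the internal standard, per analyte
unit_table <- function() {
  list(
    creatinine = c("mg/dl" = 1, "umol/l" = 1 / 88.4),
    bilirubin_total = c("mg/dl" = 1, "umol/l" = 1 / 17.1),
    platelets = c("/ul" = 1, "10^3/ul" = 1000, "x10^3/ul" = 1000,
                  "k/ul" = 1000, "10^9/l" = 1000)
  )
}

#' Normalize lab values to internal units
#'
#' Creatinine and total bilirubin are converted to mg/dL (umol/L inputs are
#' divided by 88.4 and 17.1 respectively); platelets to cells/uL (thousand-
#' scale units multiplied by 1000). Unit tags are matched case-insensitively;
#' an unrecognized tag for a known analyte is a validation error. Records
#' with non-positive values are dropped with a warning, never silently.
#'
#' @param labs A tibble with columns `patient_id`, `day`, `analyte`
#'   (`creatinine`, `bilirubin_total`, `platelets`), `value`, `units`, and
#'   optionally `lab_id`.
#' @return The same tibble with `value` in internal units and `units` set to
#'   the internal standard.
#' @export
#' @examples
#' labs <- tibble::tibble(patient_id = 1, day = 0, analyte = "bilirubin_total",
#'                        value = 34.2, units = "umol/L")
#' normalize_labs(labs)$value  # 2 mg/dL
normalize_labs <- function(labs) {
  stopifnot(all(c("patient_id", "day", "analyte", "value", "units") %in% names(labs)))
  tab <- unit_table()
  bad_an <- setdiff(unique(labs$analyte), names(tab))
  if (length(bad_an) > 0) {
    abort(sprintf("Unknown analyte(s): %s", paste(bad_an, collapse = ", ")),
          class = "apol1_validation_error")
  }
  if (nrow(labs) == 0L) return(labs)
  u <- tolower(gsub("µ", "u", labs$units))
  factor <- rep(NA_real_, nrow(labs))
  for (an in names(tab)) {
    i <- labs$analyte == an
    factor[i] <- unname(tab[[an]][u[i]])
  }
  if (anyNA(factor)) {
    bad <- unique(paste(labs$analyte[is.na(factor)], labs$units[is.na(factor)]))
    abort(sprintf("Unrecognized unit tag(s): %s", paste(bad, collapse = "; ")),
          class = "apol1_validation_error")
  }
  out <- labs
  out$value <- labs$value * factor
  std <- c(creatinine = "mg/dL", bilirubin_total = "mg/dL", platelets = "/uL")
  out$units <- unname(std[out$analyte])
  nonpos <- !is.na(out$value) & out$value <= 0
  if (any(nonpos)) {
    warn(sprintf("Dropping %d non-positive lab value(s).", sum(nonpos)))
    out <- out[!nonpos, , drop = FALSE]
  }
  out
}

#' Patient-specific baseline lab values
#'
#' The baseline is taken over days `[admission - 365, discharge]`: the lowest
#' creatinine and total bilirubin, and the highest platelet count, in that
#' window. The peri-admission values themselves are part of the window, so a
#' baseline can equal the index value. Labs must already be unit-normalized.
#'
#' @param labs Unit-normalized labs ([normalize_labs()]).
#' @param index A tibble with `patient_id`, `admission_day`, `discharge_day`
#'   (one row per patient).
#' @return A tibble `patient_id`, `analyte`, `baseline`.
#' @export
compute_baselines <- function(labs, index) {
  stopifnot(all(c("patient_id", "admission_day", "discharge_day") %in% names(index)))
  joined <- dplyr::inner_join(
    labs, index[, c("patient_id", "admission_day", "discharge_day")],
    by = "patient_id")
  inwin <- dplyr::filter(joined,
                         .data$day >= .data$admission_day - 365L,
                         .data$day <= .data$discharge_day)
  dplyr::summarise(
    dplyr::group_by(inwin, .data$patient_id, .data$analyte),
    baseline = if (.data$analyte[1] == "platelets") max(.data$value) else min(.data$value),
    .groups = "drop")
}
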