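# Restricted PheWAS over five prespecified sepsis-related phecodes.

phecode_defs <- function(codes) {
  defs <- codes$phecodes
  tibble::tibble(
    phecode = vapply(defs, `[[`, numeric(1), "phecode"),
    label = vapply(defs, `[[`, character(1), "label"),
    icd9 = lapply(defs, function(d) norm_code(d$icd9 %||% character())),
    icd10 = lapply(defs, function(d) norm_code(d$icd10 %||% character())),
    exclude_lo = vapply(defs, `[[`, numeric(1), "exclude_lo"),
    exclude_hi = vapply(defs, `[[`, numeric(1), "exclude_hi"),
    target = vapply(defs, `[[`, logical(1), "target")
  )
}

#' Map diagnosis events to phecode occurrence counts
#'
#' Matches ICD-9-CM/ICD-10-CM events against the phecode map (prefix match on
#' dot-stripped codes) and counts, per patient and phecode, the number of
#' *distinct days* with at least one occurrence -- same-day duplicates count
#' once. Codes not covered by the map are ignored; their count is attached as
#' the `"n_unmapped"` attribute.
#'
#' @param events Coded events.
#' @param codes Code configuration; `codes$phecodes` is the (miniature)
#'   phecode map, overridable via [load_codes()].
#' @return A tibble `patient_id`, `phecode`, `n_days`.
#' @export
map_icd_to_phecodes <- function(events, codes = default_codes()) {
  defs <- phecode_defs(codes)
  dx <- dplyr::filter(events, .data$code_system %in% c("ICD9CM", "ICD10CM"))
  dx$ncode <- norm_code(dx$code)
  mapped <- rep(FALSE, nrow(dx))
  out <- list()
  for (i in seq_len(nrow(defs))) {
    hit <- (dx$code_system == "ICD10CM" &
              match_any_prefix(dx$ncode, defs$icd10[[i]])) |
      (dx$code_system == "ICD9CM" &
         match_any_prefix(dx$ncode, defs$icd9[[i]]))
    mapped <- mapped | hit
    d <- dx[hit, c("patient_id", "day")]
    if (nrow(d) > 0) {
      cnt <- dplyr::summarise(dplyr::group_by(d, .data$patient_id),
                              n_days = dplyr::n_distinct(.data$day),
                              .groups = "drop")
      cnt$phecode <- defs$phecode[i]
      out[[length(out) + 1L]] <- cnt
    }
  }
  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(patient_id = integer(), n_days = integer(),
                   phecode = double())
  res <- res[, c("patient_id", "phecode", "n_days")]
  attr(res, "n_unmapped") <- sum(!mapped)
  res
}

#' Assign case/control/excluded status per target phecode
#'
#' For each target phecode: a case has the phecode on two or more distinct
#' days; a patient with exactly one occurrence, or with any phecode in the
#' target's related-code exclusion range (other than a case-qualifying count
#' of the target itself), is excluded; everyone else is a control. Case
#' status takes precedence over related-code exclusion.
#'
#' @param counts Output of [map_icd_to_phecodes()].
#' @param patient_ids All patient ids in the population (controls are
#'   patients with no occurrences, so the full roster is required).
#' @param codes Code configuration.
#' @return A tibble `patient_id`, `phecode`, `status`
#'   (factor case/control/excluded), one row per patient per target phecode.
#' @export
assign_case_control <- function(counts, patient_ids,
                                codes = default_codes()) {
  defs <- phecode_defs(codes)
  targets <- defs[defs$target, ]
  out <- list()
  for (i in seq_len(nrow(targets))) {
    ph <- targets$phecode[i]
    own <- counts[counts$phecode == ph, ]
    m <- match(patient_ids, own$patient_id)
    n_days <- ifelse(is.na(m), 0L, own$n_days[m])
    related <- counts[counts$phecode >= targets$exclude_lo[i] &
                        counts$phecode < targets$exclude_hi[i] &
                        counts$phecode != ph, ]
    has_related <- patient_ids %in% unique(related$patient_id)
    status <- dplyr::case_when(
      n_days >= 2L ~ "case",
      n_days == 1L | has_related ~ "excluded",
      TRUE ~ "control")
    out[[i]] <- tibble::tibble(
      patient_id = patient_ids, phecode = ph,
      status = factor(status, levels = c("case", "control", "excluded")))
  }
  dplyr::bind_rows(out)
}

#' Restricted PheWAS over the five sepsis-related phecodes
#'
#' For each target phecode (infection of internal prosthetic device 081,
#' septicemia 038, SIRS 994.1, sepsis 994.2, septic shock 994.21), fits
#' case/control status on the APOL1 risk group by logistic regression
#' adjusted for age, sex and three ancestry PCs, over the whole genotyped
#' population (not the infection cohort). Significance uses the Bonferroni
#' threshold `alpha / n_targets` (0.05 / 5 = 0.01) with a strictly-less
#' comparison. Setting `exclude_severe_renal = TRUE` reruns the analysis
#' after removing patients whose record carries a severe-renal-disease code.
#'
#' @param patients Population tibble with `patient_id`, `high_risk`, `age`,
#'   `sex`, `pc1`--`pc3` and (for the sensitivity pass) `severe_renal`.
#' @param events Diagnosis events for the same population.
#' @param codes Code configuration.
#' @param exclude_severe_renal Run on the severe-renal-free subset?
#' @param alpha Family-wise significance level (default 0.05).
#' @return A tibble of class `"phewas_result"`: one row per target phecode
#'   with counts, OR, Wald CI, p, `significant`, and `estimable`.
#' @export
run_restricted_phewas <- function(patients, events,
                                  codes = default_codes(),
                                  exclude_severe_renal = FALSE,
                                  alpha = 0.05) {
  defs <- phecode_defs(codes)
  targets <- defs[defs$target, ]
  threshold <- alpha / nrow(targets)
  pop <- patients
  if (exclude_severe_renal) {
    if (!"severe_renal" %in% names(pop)) {
      abort("`patients` needs a `severe_renal` column for the exclusion pass.",
            class = "apol1_validation_error")
    }
    pop <- dplyr::filter(pop, !.data$severe_renal)
    events <- dplyr::filter(events, .data$patient_id %in% pop$patient_id)
  }
  counts <- map_icd_to_phecodes(events, codes)
  status <- assign_case_control(counts, pop$patient_id, codes)
  rows <- list()
  for (i in seq_len(nrow(targets))) {
    ph <- targets$phecode[i]
    st <- status[status$phecode == ph, ]
    d <- dplyr::inner_join(pop, st, by = "patient_id")
    d <- dplyr::filter(d, .data$status != "excluded")
    d$case <- d$status == "case"
    n_case <- sum(d$case); n_ctrl <- sum(!d$case)
    n_excl <- sum(st$status == "excluded")
    if (n_case == 0L || n_ctrl == 0L) {
      rows[[i]] <- tibble::tibble(
        phecode = ph, label = targets$label[i], n_case = n_case,
        n_control = n_ctrl, n_excluded = n_excl, or = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
        significant = FALSE, estimable = FALSE)
      next
    }
    fit <- stats::glm(case ~ high_risk + age + sex + pc1 + pc2 + pc3,
                      data = d, family = stats::binomial(),
                      control = stats::glm.control(epsilon = 1e-10, maxit = 50))
    sm <- summary(fit)$coefficients
    beta <- sm["high_riskTRUE", "Estimate"]
    se <- sm["high_riskTRUE", "Std. Error"]
    p <- 2 * stats::pnorm(-abs(beta / se))
    rows[[i]] <- tibble::tibble(
      phecode = ph, label = targets$label[i], n_case = n_case,
      n_control = n_ctrl, n_excluded = n_excl, or = exp(beta),
      ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
      p = p, significant = p < threshold, estimable = fit$converged)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "threshold") <- threshold
  attr(out, "excluded_severe_renal") <- exclude_severe_renal
  class(out) <- c("phewas_result", class(out))
  out
}

#' Forest plot of a restricted PheWAS result
#'
#' @param object A `"phewas_result"` from [run_restricted_phewas()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot phewas_result
#' @export
autoplot.phewas_result <- function(object, ...) {
  d <- dplyr::filter(object, .data$estimable)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$label,
                                  xmin = .data$ci_low, xmax = .data$ci_high,
                                  colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% Wald CI, log scale)", y = NULL,
                  colour = sprintf("p < %.3g", attr(object, "threshold"))) +
    ggplot2::theme_minimal()
}

#' Simulate a genotyped population with phecode events
#'
#' Lightweight population-scale generator for the restricted PheWAS: draws
#' genotypes under the trinomial haplotype model, severe renal disease
#' enriched in high-risk carriers, and per-phecode latent case status from a
#' logistic model with a renal-disease effect and an optional direct genotype
#' effect. Cases receive the phecode on two distinct days; among non-cases a
#' small fraction receive a single mention or a related-range code (both of
#' which the case/control rules must exclude). Severe-renal patients also
#' carry a severe-renal diagnosis code so the exclusion pass is exercised end
#' to end.
#'
#' @param n Population size.
#' @param seed Integer seed.
#' @param freq_g1,freq_g2 Risk-haplotype frequencies.
#' @param p_renal_highrisk,p_renal_lowrisk Severe-renal-disease probability
#'   by genotype group (defaults 0.38 / 0.10, giving about 15% overall).
#' @param or_renal_phecode Odds ratio of each phecode for severe renal
#'   disease (default 5, a renal-mediated genotype effect).
#' @param or_direct_phecode Direct genotype odds ratio (default 1).
#' @param baseline_prev Baseline phecode prevalence (scalar or one value per
#'   target phecode).
#' @param p_single_mention,p_related_code Probability that a non-case carries
#'   one phecode mention / a related-range code.
#' @param codes Code configuration (for the phecode map and severe-renal
#'   list).
#' @return A list: `patients` (with `high_risk`, `severe_renal`, covariates),
#'   `events`, and `truth` (latent case matrix).
#' @export
simulate_phewas_population <- function(n, seed = 1L,
                                       freq_g1 = 0.27, freq_g2 = 0.13,
                                       p_renal_highrisk = 0.38,
                                       p_renal_lowrisk = 0.10,
                                       or_renal_phecode = 5,
                                       or_direct_phecode = 1,
                                       baseline_prev = 0.05,
                                       p_single_mention = 0.04,
                                       p_related_code = 0.03,
                                       codes = default_codes()) {
  set.seed(as.integer(seed))
  defs <- phecode_defs(codes)
  targets <- defs[defs$target, ]
  k <- nrow(targets)
  prev <- rep(baseline_prev, length.out = k)

  geno <- draw_genotypes(n, freq_g1, freq_g2)
  high_risk <- (geno$g1_dosage + geno$g2_dosage) >= 2L
  severe_renal <- stats::runif(n) <
    ifelse(high_risk, p_renal_highrisk, p_renal_lowrisk)
  patients <- tibble::tibble(
    patient_id = seq_len(n),
    g1_dosage = geno$g1_dosage, g2_dosage = geno$g2_dosage,
    high_risk = high_risk,
    age = as.integer(round(pmin(pmax(stats::rnorm(n, 52, 18), 18), 95))),
    sex = ifelse(stats::runif(n) < 0.55, "female", "male"),
    pc1 = stats::rnorm(n), pc2 = stats::rnorm(n), pc3 = stats::rnorm(n),
    severe_renal = severe_renal)

  ev <- list()
  truth <- matrix(FALSE, nrow = n, ncol = k,
                  dimnames = list(NULL, as.character(targets$phecode)))
  # non-target family codes usable as related-range noise for each target
  for (i in seq_len(k)) {
    lp <- stats::qlogis(prev[i]) + log(or_renal_phecode) * severe_renal +
      log(or_direct_phecode) * high_risk
    case <- stats::runif(n) < stats::plogis(lp)
    truth[, i] <- case
    code <- targets$icd10[[i]][1]
    who <- which(case)
    if (length(who)) {
      days <- sample(0:2000, length(who), replace = TRUE)
      ev[[length(ev) + 1L]] <- new_events(rep(who, 2), c(days, days + 30L),
                                          "ICD10CM", code)
    }
    single <- which(!case & stats::runif(n) < p_single_mention)
    if (length(single)) {
      ev[[length(ev) + 1L]] <- new_events(
        single, sample(0:2000, length(single), replace = TRUE), "ICD10CM", code)
    }
    rel <- defs[!defs$target &
                  defs$phecode >= targets$exclude_lo[i] &
                  defs$phecode < targets$exclude_hi[i], ]
    if (nrow(rel) > 0) {
      carriers <- which(!case & stats::runif(n) < p_related_code)
      if (length(carriers)) {
        ev[[length(ev) + 1L]] <- new_events(
          carriers, sample(0:2000, length(carriers), replace = TRUE),
          "ICD10CM", rel$icd10[[1]][1])
      }
    }
  }
  who <- which(severe_renal)
  if (length(who)) {
    ev[[length(ev) + 1L]] <- new_events(
      who, sample(0:2000, length(who), replace = TRUE), "ICD10CM", "N18.5")
  }
  events <- if (length(ev)) dplyr::bind_rows(ev) else
    new_events(integer(), integer(), character(), character(), double())
  events <- dplyr::arrange(events, .data$patient_id, .data$day, .data$code)
  events$event_id <- seq_len(nrow(events))
  list(patients = patients, events = dplyr::relocate(events, "event_id"),
       truth = truth)
}
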