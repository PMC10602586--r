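# Deliberately naive, loop-based re-implementations used as independent
# oracles. They share nothing with the package internals: plain base R,
# nested loops over raw rows, no joins.

oracle_norm <- function(x) toupper(gsub(".", "", x, fixed = TRUE))

# unit conversion by explicit case analysis
oracle_lab_value <- function(analyte, value, units) {
  u <- tolower(gsub("µ", "u", units))
  if (analyte == "creatinine") {
    if (u == "mg/dl") value else if (u == "umol/l") value / 88.4 else NA_real_
  } else if (analyte == "bilirubin_total") {
    if (u == "mg/dl") value else if (u == "umol/l") value / 17.1 else NA_real_
  } else if (analyte == "platelets") {
    if (u == "/ul") value
    else if (u %in% c("10^3/ul", "x10^3/ul", "k/ul")) value * 1000
    else if (u == "10^9/l") value * 1000
    else NA_real_
  } else NA_real_
}

# one patient at a time, straight from the written rules
oracle_phenotype_one <- function(pid, ad, dd, patients, events, labs, codes,
                                 th = apol1sepsis::sepsis_thresholds()) {
  pl <- labs[labs$patient_id == pid, , drop = FALSE]
  vals <- numeric(nrow(pl))
  for (i in seq_len(nrow(pl))) {
    vals[i] <- oracle_lab_value(pl$analyte[i], pl$value[i], pl$units[i])
  }
  keep <- !is.na(vals) & vals > 0
  pl <- pl[keep, , drop = FALSE]; vals <- vals[keep]

  base_of <- function(an, rule) {
    v <- vals[pl$analyte == an & pl$day >= ad - 365 & pl$day <= dd]
    if (length(v) == 0) return(NA_real_)
    if (rule == "min") min(v) else max(v)
  }
  win_of <- function(an) vals[pl$analyte == an & abs(pl$day - ad) <= 1]

  b_cr <- base_of("creatinine", "min")
  renal <- !is.na(b_cr) && any(win_of("creatinine") >= th$creatinine_fold * b_cr)
  b_bi <- base_of("bilirubin_total", "min")
  wb <- win_of("bilirubin_total")
  hepatic <- !is.na(b_bi) &&
    any(wb >= th$bilirubin_abs & wb >= th$bilirubin_fold * b_bi)
  b_pl <- base_of("platelets", "max")
  wp <- win_of("platelets")
  hematologic <- !is.na(b_pl) && b_pl >= th$platelet_abs &&
    any(wp < th$platelet_abs & wp <= (1 - th$platelet_decline) * b_pl)

  pe <- events[events$patient_id == pid, , drop = FALSE]
  nc <- oracle_norm(pe$code)
  in_peri <- abs(pe$day - ad) <= 1
  in_stay <- pe$day >= ad - 1 & pe$day <= dd
  resp_win <- if (th$respiratory_window == "stay") in_stay else in_peri

  shock_set <- oracle_norm(c(codes$shock_codes$icd9, codes$shock_codes$icd10))
  shock <- FALSE
  vent <- FALSE; icu <- FALSE
  norepi <- FALSE; condv <- FALSE; echo <- FALSE
  kwsum <- 0
  for (i in seq_len(nrow(pe))) {
    sys <- pe$code_system[i]
    if (in_peri[i]) {
      if (sys %in% c("ICD9CM", "ICD10CM") && nc[i] %in% shock_set) shock <- TRUE
      if (sys == "MED" &&
          tolower(pe$code[i]) %in% tolower(codes$vasopressors$norepinephrine)) norepi <- TRUE
      if (sys == "MED" &&
          tolower(pe$code[i]) %in% tolower(codes$vasopressors$conditional)) condv <- TRUE
      if (sys == "CPT" && nc[i] %in% oracle_norm(codes$stress_echo_cpt)) echo <- TRUE
      if (sys == "KEYWORD" &&
          tolower(pe$code[i]) %in% tolower(codes$keywords) && !is.na(pe$value[i])) {
        kwsum <- kwsum + pe$value[i]
      }
    }
    if (resp_win[i]) {
      if ((sys == "CPT" && nc[i] %in% oracle_norm(codes$ventilation$cpt)) ||
          (sys == "ICD9CM" && nc[i] %in% oracle_norm(codes$ventilation$icd9)) ||
          (sys == "ICD10CM" && nc[i] %in% oracle_norm(codes$ventilation$icd10))) vent <- TRUE
      if (sys == "CPT" && nc[i] %in% oracle_norm(codes$icu$cpt)) icu <- TRUE
    }
  }
  kw_ok <- kwsum >= th$keyword_min_mentions
  circulatory <- (norepi && (!th$keyword_gate_branch_a || kw_ok)) ||
    (condv && !echo && kw_ok)
  respiratory <- vent && icu

  pr <- patients[patients$patient_id == pid, , drop = FALSE]
  mortality <- (!is.na(pr$death_day) && pr$death_day >= ad && pr$death_day <= dd) ||
    (!is.na(pr$disposition) && pr$disposition == "hospice")

  c(sepsis = shock || circulatory || respiratory || renal || hepatic || hematologic,
    via_shock_code = shock, circulatory = circulatory,
    respiratory = respiratory, renal = renal, hepatic = hepatic,
    hematologic = hematologic, short_term_mortality = mortality)
}

oracle_phenotype <- function(index, patients, events, labs,
                             codes = apol1sepsis::default_codes(),
                             th = apol1sepsis::sepsis_thresholds()) {
  out <- matrix(NA, nrow = nrow(index), ncol = 8)
  for (i in seq_len(nrow(index))) {
    out[i, ] <- oracle_phenotype_one(index$patient_id[i],
                                     index$admission_day[i],
                                     index$discharge_day[i],
                                     patients, events, labs, codes, th)
  }
  colnames(out) <- c("sepsis", "via_shock_code", "circulatory", "respiratory",
                     "renal", "hepatic", "hematologic", "short_term_mortality")
  cbind(data.frame(patient_id = index$patient_id), as.data.frame(out == 1))
}

# textbook continuity-corrected chi-square for a 2x2 with cells
# [a b; c d] (rows = groups, cols = outcome yes/no)
oracle_chisq_yates <- function(a, b, c, d) {
  n <- a + b + c + d
  stat <- n * (abs(a * d - b * c) - n / 2)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  list(statistic = stat, p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# closed-form unadjusted odds ratio and Wald CI from 2x2 cells
oracle_or_2x2 <- function(a, b, c, d) {
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, ci_low = exp(log(or) - 1.96 * se),
       ci_high = exp(log(or) + 1.96 * se))
}
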