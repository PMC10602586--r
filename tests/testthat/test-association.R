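test_that("an unadjusted fit on a 2x2 equals the closed-form odds ratio", {
  for (cells in list(c(30, 70, 20, 80), c(105, 256, 460, 1421), c(5, 45, 12, 38))) {
    d <- cells_to_rows(cells[1], cells[2], cells[3], cells[4])
    fit <- fit_outcome_model(d, "sepsis", "base", covariates = character(0))
    res <- glance(fit)
    oracle <- oracle_or_2x2(cells[1], cells[2], cells[3], cells[4])
    expect_lt(abs(res$or - oracle$or), 1e-6)
    expect_lt(abs(res$ci_low - oracle$ci_low), 1e-6)
    expect_lt(abs(res$ci_high - oracle$ci_high), 1e-6)
    expect_true(res$ci_low <= res$or && res$or <= res$ci_high)
  }
})

test_that("tidy and glance agree on the exposure term", {
  cohort <- simulate_cohort(sim_config(n_patients = 4000, seed = 47))
  fit <- fit_outcome_model(cohort, "sepsis", "adjust_renal")
  td <- tidy(fit)
  gl <- glance(fit)
  row <- td[td$term == "high_riskTRUE", ]
  expect_equal(row$or, gl$or)
  expect_equal(row$ci_low, gl$ci_low)
  # Wald p and CI come from the same statistic: p < 0.05 iff CI excludes 1
  expect_identical(gl$p < 0.05, gl$ci_low > 1 || gl$ci_high < 1)
  expect_true("severe_renalTRUE" %in% td$term)
})

test_that("separation and degenerate outcomes are flagged, not silent", {
  d <- tibble::tibble(
    high_risk = rep(c(TRUE, FALSE), each = 40),
    sepsis = rep(c(TRUE, FALSE), each = 40),  # perfectly separated
    severe_renal = FALSE)
  fit <- fit_outcome_model(d, "sepsis", "base", covariates = character(0))
  expect_true(glance(fit)$flagged)
  expect_match(glance(fit)$note, "separation|converge")

  d2 <- dplyr::mutate(d, sepsis = FALSE)
  expect_error(fit_outcome_model(d2, "sepsis", "base", covariates = character(0)),
               class = "apol1_model_error")
  d3 <- dplyr::mutate(d, severe_renal = TRUE)
  expect_error(fit_outcome_model(d3, "sepsis", "exclude_renal",
                                 covariates = character(0)),
               class = "apol1_model_error")
})

test_that("the analysis suite covers the full outcome-by-strategy grid", {
  cohort <- simulate_cohort(sim_config(n_patients = 6000, seed = 53))
  suite <- run_analysis_suite(cohort)
  expect_identical(nrow(suite), 32L)
  expect_identical(dplyr::n_distinct(suite$outcome), 8L)
  expect_false(any(is.na(suite$or) & !suite$flagged))
  # subset consistency: exclude + only partitions the cohort
  base_n <- suite$n_total[suite$outcome == "sepsis" & suite$strategy == "base"]
  excl_n <- suite$n_total[suite$outcome == "sepsis" & suite$strategy == "exclude_renal"]
  only_n <- suite$n_total[suite$outcome == "sepsis" & suite$strategy == "only_renal"]
  expect_identical(excl_n + only_n, base_n)
  # secondary-outcome descriptive denominators are the sepsis cases
  sec <- secondary_outcome_counts(cohort)
  expect_identical(attr(sec, "n_sepsis"), sum(cohort$sepsis))
  expect_true(all(sec$n <= sum(cohort$sepsis)))
  p <- autoplot(suite)
  expect_s3_class(p, "ggplot")
})

test_that("renal-mediated risk attenuates under adjustment and exclusion", {
  cohort <- simulate_cohort(sim_config(n_patients = 30000, seed = 59))
  or_of <- function(strategy)
    glance(fit_outcome_model(cohort, "sepsis", strategy))$or
  or_base <- or_of("base")
  or_adj <- or_of("adjust_renal")
  expect_gt(or_base, 1)
  expect_gt(or_base, or_adj)  # adjustment removes the mediated part
})

test_that("missing covariates trigger complete-case analysis with a count", {
  cohort <- simulate_cohort(sim_config(n_patients = 2000, seed = 61))
  cohort$age[1:50] <- NA
  res <- glance(fit_outcome_model(cohort, "sepsis", "base"))
  expect_identical(res$n_missing, 50L)
  expect_identical(res$n_total, nrow(cohort) - 50L)
})

test_that("table one reproduces the descriptive conventions", {
  cohort <- simulate_cohort(sim_config(n_patients = 3000, seed = 67))
  tab <- table_one(cohort)
  expect_true(all(c("Female", "Age (at admission), median (Q1-Q3)",
                    "severe_renal") %in% tab$characteristic))
  expect_match(tab$overall[tab$characteristic == "severe_renal"],
               "^\\d+ \\(\\d+\\.\\d\\)$")
  # identical group proportions -> Yates-corrected p of 1 on large n
  bal <- tibble::tibble(
    high_risk = rep(c(TRUE, FALSE), each = 1000),
    age = 50L, sex = rep(c("female", "male"), 1000),
    flag = rep(c(TRUE, FALSE), 1000))
  tb <- table_one(bal, characteristics = "flag")
  expect_identical(tb$p_value[tb$characteristic == "flag"], "1.00")
  # zero-margin characteristics skip the test with a note
  degen <- dplyr::mutate(bal, flag = FALSE)
  td <- table_one(degen, characteristics = "flag")
  expect_identical(td$test[td$characteristic == "flag"], "skipped (zero margin)")
})

test_that("p-value display switches to scientific notation below 0.001", {
  fmt <- apol1sepsis:::format_pvalue
  expect_identical(fmt(c(0.996, 0.047, 1.6e-10)),
                   c("1.00", "0.05", "1.60E-10"))
  expect_identical(fmt(NA_real_), NA_character_)
})
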