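pheno_one <- function(events, labs, patients = make_patients(1L),
                      index = make_index(1L), ...) {
  phenotype_sepsis(index, patients, events, labs,
                   thresholds = sepsis_thresholds(...))
}

no_events <- make_events(integer(), integer(), character(), character())

test_that("lab normalization converts units and drops non-positive values", {
  labs <- tibble::tibble(
    patient_id = 1L, day = 0L,
    analyte = c("bilirubin_total", "creatinine", "platelets", "platelets"),
    value = c(34.2, 88.4, 250, 250000),
    units = c("umol/L", "µmol/L", "10^3/uL", "/uL"))
  out <- normalize_labs(labs)
  expect_equal(out$value, c(2, 1, 250000, 250000))
  expect_identical(out$units, c("mg/dL", "mg/dL", "/uL", "/uL"))
  expect_warning(
    out2 <- normalize_labs(make_labs(1L, 0L, "creatinine", c(-1, 2))),
    "non-positive")
  expect_equal(nrow(out2), 1L)
  expect_error(normalize_labs(make_labs(1L, 0L, "creatinine", 1, units = "mmol/L")),
               class = "apol1_validation_error")
  expect_error(normalize_labs(make_labs(1L, 0L, "sodium", 140, units = "mg/dL")),
               class = "apol1_validation_error")
})

test_that("baselines take the window extremum of the right sign", {
  idx <- make_index(1L)
  labs <- make_labs(rep(1L, 5), c(-30L, 0L, -100L, 0L, -400L),
                    c("creatinine", "creatinine", "platelets", "platelets",
                      "creatinine"),
                    c(1.0, 2.2, 250000, 80000, 0.4))
  b <- compute_baselines(normalize_labs(labs), idx)
  expect_equal(b$baseline[b$analyte == "creatinine"], 1.0)  # day -400 ignored
  expect_equal(b$baseline[b$analyte == "platelets"], 250000)
  # a single admission-day value is its own baseline
  b2 <- compute_baselines(normalize_labs(make_labs(1L, 0L, "creatinine", 2.0)), idx)
  expect_equal(b2$baseline, 2.0)
  # values after discharge do not enter the baseline window
  labs3 <- make_labs(c(1L, 1L), c(0L, 20L), "creatinine", c(2.0, 0.5))
  b3 <- compute_baselines(normalize_labs(labs3), idx)
  expect_equal(b3$baseline, 2.0)
})

test_that("renal criterion fires at doubling or greater, inclusively", {
  base <- make_labs(1L, -30L, "creatinine", 1.0)
  hit <- pheno_one(no_events, dplyr::bind_rows(base, make_labs(1L, 0L, "creatinine", 2.0)) |> reindex_labs())
  expect_true(hit$renal); expect_true(hit$sepsis)
  expect_match(hit$evidence_renal, "^L")
  miss <- pheno_one(no_events, dplyr::bind_rows(base, make_labs(1L, 1L, "creatinine", 1.99)) |> reindex_labs())
  expect_false(miss$renal)
  # no creatinine in the peri-admission window
  only_base <- pheno_one(no_events, reindex_labs(base))
  expect_false(only_base$renal)
  # no baseline at all -> criterion false, tallied as not evaluable
  none <- pheno_one(no_events, make_labs(1L, 0L, "platelets", 200000))
  expect_false(none$renal)
  expect_identical(unname(attr(none, "n_no_baseline")["creatinine"]), 1L)
})

test_that("hepatic criterion needs both the absolute and fold conditions", {
  run <- function(base, win) {
    labs <- make_labs(c(1L, 1L), c(-30L, 0L), "bilirubin_total", c(base, win))
    pheno_one(no_events, labs)$hepatic
  }
  expect_true(run(0.8, 2.1))
  expect_false(run(1.5, 2.5))   # above 2 mg/dL but not doubled
  expect_false(run(0.5, 1.9))   # doubled but below 2 mg/dL
})

test_that("hematologic criterion enforces the baseline-over-100k clause", {
  run <- function(base, win) {
    labs <- make_labs(c(1L, 1L), c(-30L, 0L), "platelets", c(base, win))
    pheno_one(no_events, labs)$hematologic
  }
  expect_true(run(220000, 90000))
  expect_false(run(90000, 40000))    # baseline already below 100k
  expect_false(run(150000, 99000))   # 34% decline < 50%
})

test_that("respiratory criterion is a ventilation-and-ICU conjunction", {
  labs <- qualifying_labs(1L)
  both <- make_events(c(1L, 1L), 0L, "CPT", c("94002", "99291"))
  expect_true(pheno_one(both, labs)$respiratory)
  expect_false(pheno_one(make_events(1L, 0L, "CPT", "94002"), labs)$respiratory)
  expect_false(pheno_one(make_events(1L, 0L, "CPT", "99291"), labs)$respiratory)
  # whole-stay scope by default: vent day 5 + ICU day 0 still counts
  spread <- make_events(c(1L, 1L), c(5L, 0L), "CPT", c("94002", "99291"))
  expect_true(pheno_one(spread, labs)$respiratory)
  expect_false(pheno_one(spread, labs, respiratory_window = "peri")$respiratory)
})

test_that("circulatory criterion separates the two vasopressor branches", {
  labs <- qualifying_labs(1L)
  kw2 <- make_events(c(1L, 1L), 0L, "KEYWORD", c("sepsis", "infection"),
                     value = c(1, 1))
  # branch (a): norepinephrine alone suffices
  expect_true(pheno_one(make_events(1L, 0L, "MED", "norepinephrine"), labs)$circulatory)
  # branch (b): dobutamine + keywords summing to 2, no echo
  ok_b <- dplyr::bind_rows(make_events(1L, 0L, "MED", "dobutamine"), kw2) |>
    reindex_events()
  expect_true(pheno_one(ok_b, labs)$circulatory)
  # a stress-echo CPT in the window voids branch (b)
  echo <- dplyr::bind_rows(ok_b, make_events(1L, 0L, "CPT", "93015")) |>
    reindex_events()
  expect_false(pheno_one(echo, labs)$circulatory)
  # fewer than 2 summed mentions fails branch (b)
  one_kw <- dplyr::bind_rows(make_events(1L, 0L, "MED", "dopamine"),
                             make_events(1L, 0L, "KEYWORD", "septic", value = 1)) |>
    reindex_events()
  expect_false(pheno_one(one_kw, labs)$circulatory)
  # the optional switch extends the keyword gate to branch (a)
  norepi <- make_events(1L, 0L, "MED", "norepinephrine")
  expect_false(pheno_one(norepi, labs, keyword_gate_branch_a = TRUE)$circulatory)
})

test_that("shock-code flag honors the code list and the day window", {
  labs <- qualifying_labs(1L)
  expect_true(pheno_one(make_events(1L, 1L, "ICD10CM", "R65.21"), labs)$via_shock_code)
  expect_true(pheno_one(make_events(1L, 0L, "ICD9CM", "995.92"), labs)$via_shock_code)
  expect_false(pheno_one(make_events(1L, 0L, "ICD10CM", "R65.10"), labs)$via_shock_code)
  expect_false(pheno_one(make_events(1L, -2L, "ICD9CM", "995.92"), labs)$via_shock_code)
})

test_that("short-term mortality is death in stay or hospice discharge", {
  expect_true(short_term_mortality(7L, "home", 0L, 7L))
  expect_true(short_term_mortality(NA_integer_, "hospice", 0L, 7L))
  expect_false(short_term_mortality(37L, "home", 0L, 7L))
  expect_false(short_term_mortality(NA_integer_, "home", 0L, 7L))
})

test_that("criterion calls are invariant to correctly tagged units", {
  ev <- no_events
  mg <- dplyr::bind_rows(
    make_labs(1L, -30L, "bilirubin_total", 0.9),
    make_labs(1L, 0L, "bilirubin_total", 2.1)) |> reindex_labs()
  umol <- mg
  umol$value <- umol$value * 17.1
  umol$units <- "umol/L"
  expect_identical(pheno_one(ev, mg)$hepatic, pheno_one(ev, umol)$hepatic)
  k <- dplyr::bind_rows(
    make_labs(1L, -30L, "platelets", 220, units = "10^3/uL"),
    make_labs(1L, 0L, "platelets", 90, units = "10^3/uL")) |> reindex_labs()
  expect_true(pheno_one(ev, k)$hematologic)
})

test_that("adding qualifying rows never turns a criterion off (monotonicity)", {
  sim <- simulate_ehr(sim_config(n_patients = 200, seed = 37))
  idx <- sim$admissions[, c("patient_id", "admission_day", "discharge_day")]
  before <- phenotype_sepsis(idx, sim$patients, sim$events, sim$labs)
  extra_ev <- dplyr::bind_rows(
    make_events(1:200, 0L, "ICD10CM", "R65.21"),
    make_events(1:200, 0L, "MED", "norepinephrine"))
  extra_ev$event_id <- max(sim$events$event_id) + seq_len(nrow(extra_ev))
  after <- phenotype_sepsis(idx, sim$patients,
                            dplyr::bind_rows(sim$events, extra_ev), sim$labs)
  for (col in c("sepsis", "via_shock_code", "circulatory", "respiratory",
                "renal", "hepatic", "hematologic")) {
    expect_true(all(after[[col]] >= before[[col]]), info = col)
  }
})

test_that("every true flag carries evidence pointing at real rows", {
  sim <- simulate_ehr(sim_config(n_patients = 300, seed = 41))
  idx <- sim$admissions[, c("patient_id", "admission_day", "discharge_day")]
  calls <- phenotype_sepsis(idx, sim$patients, sim$events, sim$labs)
  flags <- c(via_shock_code = "evidence_shock_code",
             circulatory = "evidence_circulatory",
             respiratory = "evidence_respiratory",
             renal = "evidence_renal", hepatic = "evidence_hepatic",
             hematologic = "evidence_hematologic")
  for (f in names(flags)) {
    ev <- calls[[flags[[f]]]][calls[[f]]]
    expect_true(all(nzchar(ev)), info = f)
    ids <- unlist(strsplit(ev, ";", fixed = TRUE))
    eids <- as.integer(sub("^E", "", ids[startsWith(ids, "E")]))
    lids <- as.integer(sub("^L", "", ids[startsWith(ids, "L")]))
    expect_true(all(eids %in% sim$events$event_id))
    expect_true(all(lids %in% sim$labs$lab_id))
  }
})
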