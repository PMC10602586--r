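test_that("inclusion requires infection code and antibiotic inside the window", {
  pts <- make_patients(1:4)
  adm <- make_admissions(1:4)
  labs <- qualifying_labs(1:4)
  ev <- dplyr::bind_rows(
    # p1: infection day 0, antibiotic day +1 -> qualifies
    make_events(1L, 0L, "ICD10CM", "N39.0"),
    make_events(1L, 1L, "MED", "vancomycin"),
    # p2: antibiotic day +2 -> outside the window
    make_events(2L, 0L, "ICD10CM", "N39.0"),
    make_events(2L, 2L, "MED", "vancomycin"),
    # p3: antibiotic only
    make_events(3L, 0L, "MED", "vancomycin"),
    # p4: infection day -2 -> outside the window
    make_events(4L, -2L, "ICD10CM", "N39.0"),
    make_events(4L, 0L, "MED", "vancomycin")
  ) |> reindex_events()
  cand <- qualify_admissions(adm, pts, ev, labs)
  expect_identical(cand$patient_id, 1L)
  att <- attr(cand, "attrition")
  expect_identical(att$n_removed[att$step == "infection_code"], 2L)
  expect_identical(att$n_removed[att$step == "antibiotic"], 1L)
})

test_that("minors and COVID-positive admissions are excluded", {
  pts <- make_patients(1:3, birth_day = c(adult_birth, -16L * 365L, adult_birth),
                       covid = c(FALSE, FALSE, TRUE))
  adm <- make_admissions(1:3)
  ev <- qualifying_events(1:3)
  labs <- qualifying_labs(1:3)
  cand <- qualify_admissions(adm, pts, ev, labs)
  expect_identical(cand$patient_id, 1L)

  # U07.1 on day 0 excludes even without the flag
  ev2 <- dplyr::bind_rows(qualifying_events(1:2),
                          make_events(2L, 0L, "ICD10CM", "U07.1")) |>
    reindex_events()
  cand2 <- qualify_admissions(make_admissions(1:2), make_patients(1:2), ev2,
                              qualifying_labs(1:2))
  expect_identical(cand2$patient_id, 1L)
})

test_that("admission-level exclusion codes remove otherwise qualifying stays", {
  pts <- make_patients(1:3)
  ev <- dplyr::bind_rows(
    qualifying_events(1:3),
    make_events(2L, 0L, "CPT", "33510"),     # cardiac surgery
    make_events(3L, 1L, "ICD10CM", "R57.0")  # cardiogenic shock
  ) |> reindex_events()
  cand <- qualify_admissions(make_admissions(1:3), pts, ev, qualifying_labs(1:3))
  expect_identical(cand$patient_id, 1L)
})

test_that("the lab-availability rule distinguishes all-absent from any-absent", {
  pts <- make_patients(1:3)
  adm <- make_admissions(1:3)
  ev <- qualifying_events(1:3)
  labs <- dplyr::bind_rows(
    make_labs(1L, 0L, "creatinine", 1.0),      # one analyte only
    make_labs(2L, -3L, "creatinine", 1.0)      # outside the window
    # patient 3: no labs at all
  ) |> reindex_labs()
  cand <- qualify_admissions(adm, pts, ev, labs, lab_rule = "all_absent")
  expect_identical(cand$patient_id, 1L)
  cand2 <- qualify_admissions(adm, pts, ev, labs, lab_rule = "any_absent")
  expect_identical(nrow(cand2), 0L)
})

test_that("index selection takes the first admission with deterministic tie-breaks", {
  pts <- make_patients(1L)
  ev <- dplyr::bind_rows(
    qualifying_events(1L),
    make_events(1L, 99:101, "ICD10CM", "N39.0"),
    make_events(1L, 100L, "MED", "vancomycin")
  ) |> reindex_events()
  labs <- dplyr::bind_rows(qualifying_labs(1L),
                           make_labs(1L, 100L, "creatinine", 1.0)) |>
    reindex_labs()
  adm <- make_admissions(c(1L, 1L), admission_day = c(100L, 0L),
                         discharge_day = c(110L, 7L), admission_id = c(9L, 2L))
  idx <- select_index(qualify_admissions(adm, pts, ev, labs))
  expect_identical(idx$admission_id, 2L)  # earlier admission wins

  # same-day admissions: longer stay wins, then lower id
  adm2 <- make_admissions(c(1L, 1L), admission_day = 0L,
                          discharge_day = c(5L, 12L), admission_id = c(1L, 2L))
  idx2 <- select_index(qualify_admissions(adm2, pts, ev, labs))
  expect_identical(idx2$admission_id, 2L)
  adm3 <- make_admissions(c(1L, 1L), admission_day = 0L, discharge_day = 7L,
                          admission_id = c(4L, 3L))
  idx3 <- select_index(qualify_admissions(adm3, pts, ev, labs))
  expect_identical(idx3$admission_id, 3L)
})

test_that("attrition counts conserve patients through every step", {
  cfg <- sim_config(n_patients = 1000, seed = 19, p_covid = 0.05,
                    p_under18 = 0.04, p_missing_labs = 0.06,
                    p_missing_genotype = 0.03, p_excluded_admission = 0.05)
  sim <- simulate_ehr(cfg)
  coh <- suppressMessages(
    assemble_cohort(sim$patients, sim$admissions, sim$events, sim$labs))
  att <- coh$attrition
  n_in <- att$n_patients[att$step == "input"]
  expect_identical(n_in, 1000L)
  expect_identical(n_in - sum(att$n_removed), nrow(coh$cohort))
  # patients dropped for genotype appear in the log, not the rows
  expect_gt(att$n_removed[att$step == "genotype_classifiable"], 0L)
})

test_that("the cohort is invariant to the order of event rows", {
  sim <- simulate_ehr(sim_config(n_patients = 300, seed = 23))
  coh1 <- assemble_cohort(sim$patients, sim$admissions, sim$events, sim$labs)
  set.seed(1)
  shuf <- sim$events[sample(nrow(sim$events)), ]
  coh2 <- assemble_cohort(sim$patients, sim$admissions, shuf, sim$labs)
  expect_equal(coh1$cohort, coh2$cohort)
})

test_that("noise-free synthetic eligibility is recovered exactly", {
  sim <- simulate_ehr(sim_config(n_patients = 400, seed = 29))
  coh <- assemble_cohort(sim$patients, sim$admissions, sim$events, sim$labs)
  # with all contamination knobs at zero, everyone is eligible
  expect_setequal(coh$cohort$patient_id, sim$patients$patient_id)
  m <- match(coh$cohort$patient_id, sim$ground_truth$patient_id)
  expect_identical(coh$cohort$high_risk, sim$ground_truth$true_high_risk[m])
})

test_that("malformed inputs raise typed validation errors", {
  pts <- make_patients(c(1L, 1L))
  expect_error(
    assemble_cohort(pts, make_admissions(1L), qualifying_events(1L),
                    qualifying_labs(1L)),
    class = "apol1_validation_error")
  bad_ev <- make_events(1L, 0L, "SNOMED", "12345")
  expect_error(
    qualify_admissions(make_admissions(1L), make_patients(1L), bad_ev,
                       qualifying_labs(1L)),
    class = "apol1_validation_error")
  expect_error(
    qualify_admissions(make_admissions(1L), make_patients(1L),
                       qualifying_events(1L), qualifying_labs(1L),
                       codes = list(infection_types = list())),
    class = "apol1_config_error")
})
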