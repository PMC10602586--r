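test_that("configuration validation rejects impossible parameters", {
  expect_error(sim_config(n_patients = -1), class = "apol1_config_error")
  expect_error(sim_config(freq_g1 = 0.7, freq_g2 = 0.5), class = "apol1_config_error")
  expect_error(sim_config(freq_g1 = 1.2), class = "apol1_config_error")
  expect_error(sim_config(or_sepsis_renal = 0), class = "apol1_config_error")
  expect_error(sim_config(baseline_sepsis_prob = 1.5), class = "apol1_config_error")
  expect_error(sim_config(comorbidity_rates = rep(0.1, 5)), class = "apol1_config_error")
})

test_that("genotype draws respect the trinomial haplotype model", {
  set.seed(401)
  g <- draw_genotypes(100000, 0.27, 0.13)
  expect_true(all(g$g1_dosage %in% 0:2))
  expect_true(all(g$g1_dosage + g$g2_dosage <= 2))
  # high-risk fraction converges to (f1+f2)^2 = 0.16; 3 binomial SEs
  frac <- mean(g$g1_dosage + g$g2_dosage >= 2)
  se <- sqrt(0.16 * 0.84 / 100000)
  expect_lt(abs(frac - 0.16), 3 * se)
})

test_that("degenerate haplotype frequencies produce degenerate dosages", {
  set.seed(1)
  g0 <- draw_genotypes(200, 0, 0)
  expect_true(all(g0$g1_dosage == 0L & g0$g2_dosage == 0L))
  g1 <- draw_genotypes(200, 1, 0)
  expect_true(all(g1$g1_dosage == 2L & g1$g2_dosage == 0L))
})

test_that("identical configurations reproduce byte-identical populations", {
  cfg <- sim_config(n_patients = 300, seed = 77,
                    p_covid = 0.02, p_missing_labs = 0.03)
  a <- simulate_ehr(cfg)
  b <- simulate_ehr(cfg)
  for (nm in c("patients", "admissions", "events", "labs", "ground_truth")) {
    expect_identical(a[[nm]], b[[nm]])
  }
  d <- simulate_ehr(sim_config(n_patients = 300, seed = 78))
  expect_false(identical(a$events, d$events))
})

test_that("latent sepsis is always witnessed by at least one criterion", {
  sim <- simulate_ehr(sim_config(n_patients = 1500, seed = 5))
  gt <- sim$ground_truth
  any_crit <- gt$true_circulatory | gt$true_respiratory | gt$true_renal |
    gt$true_hepatic | gt$true_hematologic | gt$true_shock_code
  expect_identical(gt$true_sepsis, any_crit)
  # mortality implies a death-in-stay or hospice disposition
  dead <- sim$patients[gt$true_mortality, ]
  expect_true(all(!is.na(dead$death_day) | dead$disposition == "hospice"))
})

test_that("an all-renal organ mix emits a qualifying creatinine pair for every case", {
  cfg <- sim_config(n_patients = 800, seed = 31,
                    organ_mix = c(circulatory = 0, respiratory = 0, renal = 1,
                                  hepatic = 0, hematologic = 0, shock_code = 0))
  sim <- simulate_ehr(cfg)
  gt <- sim$ground_truth
  expect_true(all(gt$true_renal[gt$true_sepsis]))
  cases <- gt$patient_id[gt$true_sepsis]
  cr <- sim$labs[sim$labs$analyte == "creatinine", ]
  for (pid in cases) {
    v <- cr[cr$patient_id == pid, ]
    baseline <- min(v$value)
    expect_gte(max(v$value), 2 * baseline)
  }
})

test_that("the fixture round-trips losslessly and deterministically", {
  cfg <- sim_config(n_patients = 100, seed = 13)
  sim <- simulate_ehr(cfg)
  dir1 <- withr::local_tempdir()
  paths <- write_fixture(sim, dir1)
  expect_setequal(basename(unname(paths)),
                  c("patients.csv", "admissions.csv", "events.csv",
                    "labs.csv", "ground_truth.csv"))
  back <- read_fixture(dir1)
  for (nm in names(back)) {
    expect_equal(as.data.frame(back[[nm]]), as.data.frame(sim[[nm]]),
                 ignore_attr = TRUE)
  }
  # same seed twice -> identical file checksums
  dir2 <- withr::local_tempdir()
  write_fixture(simulate_ehr(cfg), dir2)
  for (f in basename(unname(paths))) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))))
  }
})

test_that("an empty population writes valid empty files with headers", {
  sim <- simulate_ehr(sim_config(n_patients = 0, seed = 1))
  dir <- withr::local_tempdir()
  write_fixture(sim, dir)
  back <- read_fixture(dir)
  expect_equal(nrow(back$patients), 0L)
  expect_true(all(c("patient_id", "g1_dosage") %in% names(back$patients)))
  expect_equal(nrow(back$events), 0L)
})

test_that("read_fixture names the missing file", {
  dir <- withr::local_tempdir()
  expect_error(read_fixture(dir), "labs.csv", class = "apol1_io_error")
})
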