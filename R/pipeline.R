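#' Run the full pipeline end to end
#'
#' Orchestrates simulate -> cohort construction -> phenotyping -> association
#' suite -> baseline table (and optionally the restricted PheWAS on a
#' separately simulated genotyped population), with per-stage row counts and
#' reproducibility metadata collected in a manifest. A single master seed
#' fans out to deterministic per-stage child seeds, so identical
#' configuration plus seed reproduces every artifact byte for byte (the
#' manifest timestamp aside).
#'
#' @param config A [sim_config()]; its `seed` is overridden by `seed` here.
#' @param seed Master seed for the run.
#' @param out_dir Optional directory; when given, all stage artifacts
#'   (fixture CSVs, `cohort.csv`, `attrition.csv`, `sepsis_calls.csv`,
#'   `results.csv`, `table1.csv`, `phewas.csv`, `manifest.yaml`) are written
#'   there.
#' @param codes Code configuration.
#' @param thresholds Phenotyping thresholds.
#' @param phewas Also run the restricted PheWAS (on its own simulated
#'   population of `phewas_n` patients)?
#' @param phewas_n Population size for the PheWAS stage.
#' @return A list of class `"apol1_run"`: `sim`, `cohort` (an
#'   `"apol1_cohort"`), `suite`, `table1`, `phewas` (or `NULL`), `manifest`.
#' @export
#' @examples
#' run <- run_pipeline(sim_config(n_patients = 400), seed = 3)
#' run$manifest$counts
run_pipeline <- function(config = sim_config(), seed = config$seed,
                         out_dir = NULL, codes = default_codes(),
                         thresholds = sepsis_thresholds(),
                         phewas = FALSE, phewas_n = 14713L) {
  validate_codes(codes)
  config$seed <- child_seed(seed, 1L)
  sim <- simulate_ehr(config, codes = codes)
  coh <- assemble_cohort(sim$patients, sim$admissions, sim$events, sim$labs,
                         codes = codes, thresholds = thresholds)
  suite <- run_analysis_suite(coh$cohort)
  tab1 <- table_one(coh$cohort)
  phw <- NULL
  phw_excl <- NULL
  if (isTRUE(phewas)) {
    pop <- simulate_phewas_population(phewas_n, seed = child_seed(seed, 2L),
                                      codes = codes)
    phw <- run_restricted_phewas(pop$patients, pop$events, codes = codes)
    phw_excl <- run_restricted_phewas(pop$patients, pop$events, codes = codes,
                                      exclude_severe_renal = TRUE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("apol1sepsis")),
    seed = seed,
    stage_seeds = list(simulate = child_seed(seed, 1L),
                       phewas = child_seed(seed, 2L)),
    config_hash = rlang::hash(unclass(config)),
    counts = list(
      patients_simulated = nrow(sim$patients),
      events = nrow(sim$events),
      labs = nrow(sim$labs),
      cohort = nrow(coh$cohort),
      sepsis_cases = sum(coh$cohort$sepsis),
      association_rows = nrow(suite),
      phewas_rows = if (is.null(phw)) 0L else nrow(phw)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  run <- structure(list(sim = sim, cohort = coh, suite = suite, table1 = tab1,
                        phewas = phw, phewas_excluded = phw_excl,
                        manifest = manifest),
                   class = "apol1_run")
  if (!is.null(out_dir)) {
    write_run(run, out_dir)
  }
  run
}

#' @rdname run_pipeline
#' @param run An `"apol1_run"` object.
#' @export
write_run <- function(run, out_dir) {
  stopifnot(inherits(run, "apol1_run"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create directory: %s", out_dir),
                   class = "apol1_io_error")
  }
  write_fixture(run$sim, out_dir)
  readr::write_csv(run$cohort$cohort, file.path(out_dir, "cohort.csv"), progress = FALSE)
  readr::write_csv(run$cohort$attrition, file.path(out_dir, "attrition.csv"), progress = FALSE)
  readr::write_csv(run$cohort$calls, file.path(out_dir, "sepsis_calls.csv"), progress = FALSE)
  readr::write_csv(run$suite, file.path(out_dir, "results.csv"), progress = FALSE)
  readr::write_csv(run$table1, file.path(out_dir, "table1.csv"), progress = FALSE)
  if (!is.null(run$phewas)) {
    readr::write_csv(run$phewas, file.path(out_dir, "phewas.csv"), progress = FALSE)
    readr::write_csv(run$phewas_excluded,
                     file.path(out_dir, "phewas_excluded_severe_renal.csv"), progress = FALSE)
  }
  yaml::write_yaml(run$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' @export
print.apol1_run <- function(x, ...) {
  cat("<apol1_run>\n")
  cat(sprintf("  seed %d | config %s\n", x$manifest$seed,
              substr(x$manifest$config_hash, 1, 8)))
  str(x$manifest$counts, no.list = TRUE)
  invisible(x)
}
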