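#' Clinical code lists used by the cohort, phenotyping and covariate rules
#'
#' The algorithms in this package treat code lists as data, not code: every
#' rule (infection inclusion, admission exclusions, ventilation/ICU markers,
#' vasopressors, septic-shock codes, Charlson/Deyo category maps, infection
#' types, the severe-renal-disease list, and the restricted phecode map) looks
#' codes up in the list returned by this function. The shipped defaults are
#' clearly labelled, plausible stand-ins for the study-specific appendix lists
#' that are not publicly printed; the fifteen severe-renal codes and the four
#' septic-shock/severe-sepsis codes, which *are* printed, are reproduced
#' exactly. Override any entry by editing a YAML copy (see [load_codes()]).
#'
#' Diagnosis and procedure codes are matched after stripping dots and
#' upper-casing. Charlson category maps and infection-type maps use prefix
#' matching (so `"N18"` covers `N18.1`--`N18.9`); the severe-renal list,
#' shock codes, COVID code, stress-echocardiography CPTs and ventilation/ICU
#' markers are matched exactly.
#'
#' @return A named list with elements `infection_types`, `antibiotics`,
#'   `exclusions`, `covid`, `shock_codes`, `ventilation`, `icu`,
#'   `vasopressors`, `stress_echo_cpt`, `keywords`, `severe_renal`,
#'   `charlson`, and `phecodes`.
#' @seealso [load_codes()], [write_codes()]
#' @export
#' @examples
#' codes <- default_codes()
#' codes$severe_renal
default_codes <- function() {
  list(
    # Ten infection-type categories; any window-day match also satisfies the
    # "billing code indicating an infection" inclusion rule. Prefix match.
    infection_types = list(
      circulatory     = list(label = "Circulatory",     icd10 = c("I33.0", "I38"),          icd9 = c("421.0")),
      digestive       = list(label = "Digestive",       icd10 = c("K65.0", "K83.0"),        icd9 = c("567.2")),
      genitourinary   = list(label = "Genitourinary",   icd10 = c("N39.0", "N10"),          icd9 = c("599.0", "590.1")),
      intestinal      = list(label = "Intestinal",      icd10 = c("A04.7", "A09"),          icd9 = c("008.45", "009.0")),
      musculoskeletal = list(label = "Musculoskeletal", icd10 = c("M86.9", "M00.9"),        icd9 = c("730.2", "711.0")),
      neurologic      = list(label = "Neurologic",      icd10 = c("G00.9", "G04.2"),        icd9 = c("320.9")),
      other_bacterial = list(label = "Other bacterial", icd10 = c("A41", "A49"),            icd9 = c("038", "041")),
      respiratory     = list(label = "Respiratory",     icd10 = c("J18.9", "J15"),          icd9 = c("486", "482")),
      skin            = list(label = "Skin",            icd10 = c("L03", "L02"),            icd9 = c("682")),
      other           = list(label = "Other",           icd10 = c("B99.9", "T81.4"),        icd9 = c("999.39"))
    ),
    # Systemic antibiotics, matched (lower-cased) against MED events.
    antibiotics = c(
      "vancomycin", "piperacillin-tazobactam", "cefepime", "ceftriaxone",
      "levofloxacin", "meropenem", "ampicillin-sulbactam", "azithromycin",
      "metronidazole", "cefazolin"
    ),
    # Admission-level exclusions, evaluated on days -1, 0, +1.
    exclusions = list(
      cardiac_surgery   = list(cpt = c("33510", "33533", "33405"), icd9 = c("36.10", "36.11"), icd10 = character()),
      cardiogenic_shock = list(cpt = character(), icd9 = c("785.51"), icd10 = c("R57.0")),
      transplantation   = list(cpt = c("50360", "47135", "33945"), icd9 = c("996.80"), icd10 = c("T86.00"))
    ),
    covid = c("U07.1"),
    # Septic shock / severe sepsis billing codes (exact match).
    shock_codes = list(icd9 = c("995.92", "785.52"), icd10 = c("R65.20", "R65.21")),
    ventilation = list(
      cpt = c("94002", "94003", "94004", "94660"),
      icd9 = c("96.70", "96.71", "96.72"),
      icd10 = c("5A1935Z", "5A1945Z", "5A1955Z")
    ),
    icu = list(cpt = c("99291", "99292")),
    vasopressors = list(
      # branch (a): norepinephrine on its own is sufficient
      norepinephrine = c("norepinephrine", "levophed"),
      # branch (b): these require no stress-echo CPT and >= 2 keyword mentions
      conditional = c("dobutamine", "dopamine")
    ),
    stress_echo_cpt = c("78452", "93015", "93016", "93017", "93018", "93351"),
    keywords = c("infection", "sepsis", "septic"),
    # Stage 4/5 CKD / ESRD diagnosis and procedure codes (exact match; this
    # is the one list that is fixed by the analysis definition).
    severe_renal = c(
      "N18.4", "N18.5", "N18.6", "N18.9", "585.4", "585.5", "585.6", "585.9",
      "586", "Z99.2", "Z49.0", "Z49.31", "39.95", "V45.11", "V56.0"
    ),
    charlson = list(
      myocardial_infarction = list(label = "Myocardial infarction",
        icd9 = c("410", "412"), icd10 = c("I21", "I22", "I25.2")),
      congestive_heart_failure = list(label = "Congestive heart failure",
        icd9 = c("428"), icd10 = c("I50")),
      peripheral_vascular = list(label = "Peripheral vascular disease",
        icd9 = c("440", "441", "443.9"), icd10 = c("I70", "I71", "I73.9")),
      cerebrovascular = list(label = "Cerebrovascular disease",
        icd9 = c("430", "431", "432", "433", "434", "435", "436", "438"),
        icd10 = c("I60", "I61", "I62", "I63", "I64", "I65", "I66", "G45")),
      dementia = list(label = "Dementia",
        icd9 = c("290"), icd10 = c("F00", "F01", "F02", "F03", "G30")),
      chronic_pulmonary = list(label = "Chronic pulmonary disease",
        icd9 = c("490", "491", "492", "493", "494", "495", "496"),
        icd10 = c("J40", "J41", "J42", "J43", "J44", "J45", "J46", "J47")),
      rheumatic = list(label = "Rheumatic disease",
        icd9 = c("714", "710.0", "710.1"), icd10 = c("M05", "M06", "M32", "M33", "M34")),
      peptic_ulcer = list(label = "Peptic ulcer disease",
        icd9 = c("531", "532", "533", "534"), icd10 = c("K25", "K26", "K27", "K28")),
      mild_liver = list(label = "Mild liver disease",
        icd9 = c("571.2", "571.5", "571.6"), icd10 = c("B18", "K73", "K74", "K76.0")),
      diabetes_uncomplicated = list(label = "Diabetes without chronic complication",
        icd9 = c("250.0", "250.1", "250.2", "250.3"),
        icd10 = c("E10.9", "E11.9", "E13.9")),
      diabetes_complicated = list(label = "Diabetes with chronic complication",
        icd9 = c("250.4", "250.5", "250.6", "250.7"),
        icd10 = c("E10.2", "E10.3", "E11.2", "E11.3", "E11.4", "E11.5")),
      hemiplegia_paraplegia = list(label = "Hemiplegia or paraplegia",
        icd9 = c("342", "343", "344"), icd10 = c("G81", "G82", "G83")),
      renal_disease = list(label = "Renal disease",
        icd9 = c("582", "583", "585", "586", "V42.0", "V45.1", "V56"),
        icd10 = c("N03", "N05", "N18", "N19", "Z49", "Z94.0", "Z99.2")),
      malignancy = list(label = "Malignancy, including lymphoma and leukemia, except malignant neoplasm of skin",
        icd9 = c("153", "162", "174", "185", "200", "202", "204", "205"),
        icd10 = c("C18", "C34", "C50", "C61", "C81", "C85", "C91", "C92")),
      moderate_severe_liver = list(label = "Moderate or severe liver disease",
        icd9 = c("456.0", "456.1", "456.2", "572.2", "572.3", "572.4"),
        icd10 = c("I85.0", "I86.4", "K70.4", "K72.1", "K72.9", "K76.6", "K76.7")),
      metastatic_tumor = list(label = "Metastatic solid tumor",
        icd9 = c("196", "197", "198", "199.0"), icd10 = c("C77", "C78", "C79", "C80.0")),
      aids_hiv = list(label = "AIDS/HIV",
        icd9 = c("042"), icd10 = c("B20", "B21", "B22", "B24"))
    ),
    # Miniature phecode map: the five restricted-PheWAS targets plus the
    # family codes their related-code exclusion ranges need. `exclude_lo`/
    # `exclude_hi` bound the half-open phecode interval whose carriers are
    # removed from that phecode's control pool.
    phecodes = list(
      list(phecode = 81,     label = "Infection of internal prosthetic device",
           icd9 = c("996.6"), icd10 = c("T85.7"),
           exclude_lo = 80, exclude_hi = 82, target = TRUE),
      list(phecode = 38,     label = "Septicemia",
           icd9 = c("038"), icd10 = c("A40", "A41"),
           exclude_lo = 38, exclude_hi = 42, target = TRUE),
      list(phecode = 994.1,  label = "Systemic inflammatory response syndrome (SIRS)",
           icd9 = c("995.90", "995.93", "995.94"), icd10 = c("R65.10", "R65.11"),
           exclude_lo = 994, exclude_hi = 995, target = TRUE),
      list(phecode = 994.2,  label = "Sepsis",
           icd9 = c("995.91"), icd10 = c("R65.20"),
           exclude_lo = 994, exclude_hi = 995, target = TRUE),
      list(phecode = 994.21, label = "Septic shock",
           icd9 = c("785.52", "995.92"), icd10 = c("R65.21"),
           exclude_lo = 994, exclude_hi = 995, target = TRUE),
      # non-target family members, used only for related-code exclusion
      list(phecode = 41,  label = "Bacterial infection NOS",
           icd9 = c("041"), icd10 = c("A49"),
           exclude_lo = 38, exclude_hi = 42, target = FALSE),
      list(phecode = 80,  label = "Other device/implant infection",
           icd9 = c("996.7"), icd10 = c("T82.7"),
           exclude_lo = 80, exclude_hi = 82, target = FALSE),
      list(phecode = 994, label = "Sepsis/SIRS family NOS",
           icd9 = c("995.99"), icd10 = c("R65.9"),
           exclude_lo = 994, exclude_hi = 995, target = FALSE)
    )
  )
}

#' Read a code-list configuration from YAML
#'
#' Entries present in the file override the corresponding entries of
#' [default_codes()]; anything omitted keeps its default, so a configuration
#' file only needs the lists being changed.
#'
#' @param path Path to a YAML file (see `system.file("extdata", "codes.yaml",
#'   package = "apol1sepsis")` for the full shipped configuration).
#' @return A code-list configuration list.
#' @export
load_codes <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Code configuration file not found: %s", path),
          class = "apol1_io_error")
  }
  user <- yaml::read_yaml(path)
  utils::modifyList(default_codes(), user)
}

#' Write a code-list configuration to YAML
#'
#' @param codes A code-list configuration, e.g. from [default_codes()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_codes <- function(codes, path) {
  yaml::write_yaml(codes, path)
  invisible(path)
}

validate_codes <- function(codes) {
  needed <- c("infection_types", "antibiotics", "exclusions", "covid",
              "shock_codes", "ventilation", "icu", "vasopressors",
              "stress_echo_cpt", "keywords", "severe_renal", "charlson",
              "phecodes")
  missing <- setdiff(needed, names(codes))
  if (length(missing) > 0) {
    abort(sprintf("Code configuration is missing: %s",
                  paste(missing, collapse = ", ")),
          class = "apol1_config_error")
  }
  empty <- names(codes)[vapply(codes, function(x) length(x) == 0L, logical(1))]
  if (length(empty) > 0) {
    abort(sprintf("Code configuration has empty list(s): %s",
                  paste(empty, collapse = ", ")),
          class = "apol1_config_error")
  }
  if (length(codes$charlson) != 17L) {
    abort("The Charlson/Deyo map must define exactly 17 categories.",
          class = "apol1_config_error")
  }
  invisible(codes)
}

# Flat per-system normalized code vectors for one rule.
rule_codes <- function(lst) {
  lapply(lst, norm_code)
}
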