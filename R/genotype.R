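#' Convert fractional imputed dosages to allele counts
#'
#' Imputed genotypes arrive as expected allele dosages in `[0, 2]`; the
#' recessive risk model needs hard counts. The half-open thresholding rule is
#' `dosage < t1 -> 0`, `t1 <= dosage < t2 -> 1`, `dosage >= t2 -> 2`, with
#' defaults `t1 = 0.5`, `t2 = 1.5`. `NA` dosages stay `NA` (uncallable).
#'
#' @param dosage Numeric vector of dosages in `[0, 2]` (NA allowed).
#' @param thresholds Length-2 numeric `c(t1, t2)` with `0 < t1 < t2 < 2`.
#' @return Integer vector of allele counts in `0:2`.
#' @export
#' @examples
#' call_allele_count(c(0.49, 0.5, 1.49, 1.5, 1.92))
call_allele_count <- function(dosage, thresholds = c(0.5, 1.5)) {
  if (length(thresholds) != 2L || !(0 < thresholds[1]) ||
      !(thresholds[1] < thresholds[2]) || !(thresholds[2] < 2)) {
    abort("`thresholds` must satisfy 0 < t1 < t2 < 2.",
          class = "apol1_config_error")
  }
  bad <- !is.na(dosage) & (dosage < 0 | dosage > 2)
  if (any(bad)) {
    abort(sprintf("%d dosage value(s) outside [0, 2].", sum(bad)),
          class = "apol1_validation_error")
  }
  out <- rep(NA_integer_, length(dosage))
  ok <- !is.na(dosage)
  out[ok] <- ifelse(dosage[ok] < thresholds[1], 0L,
                    ifelse(dosage[ok] < thresholds[2], 1L, 2L))
  out
}

#' Classify the APOL1 risk group under the recessive two-allele model
#'
#' A patient is high risk when they carry two risk alleles in any
#' configuration: G1/G1 (`g1 == 2`), G2/G2 (`g2 == 2`), or the compound
#' heterozygote G1/G2 (`g1 >= 1` and `g2 >= 1`). Carriers of one or zero risk
#' alleles are low risk. Counts must respect haplotype exclusivity
#' (`g1 + g2 <= 2`); violations are data errors, not capped.
#'
#' @param g1,g2 Integer allele counts in `0:2` at the G1 site (rs73885319)
#'   and the G2 proxy site (rs12106505). `NA` at either site yields `NA`
#'   (unclassifiable).
#' @return A factor with levels `c("low", "high")`; high risk is coded 1 in
#'   all downstream models.
#' @export
#' @examples
#' apol1_risk_group(c(2, 1, 1, 0), c(0, 1, 0, 0))
apol1_risk_group <- function(g1, g2) {
  if (length(g1) != length(g2)) {
    abort("`g1` and `g2` must have equal length.", class = "apol1_validation_error")
  }
  known <- !is.na(g1) & !is.na(g2)
  rng_ok <- g1[known] %in% 0:2 & g2[known] %in% 0:2
  if (!all(rng_ok)) {
    abort("Allele counts must be integers in 0..2.", class = "apol1_validation_error")
  }
  if (any(g1[known] + g2[known] > 2)) {
    abort("g1 + g2 > 2 violates haplotype exclusivity; rejected as a data error.",
          class = "apol1_validation_error")
  }
  high <- g1 == 2L | g2 == 2L | (g1 >= 1L & g2 >= 1L)
  factor(ifelse(high, "high", "low"), levels = c("low", "high"))
}

#' Add the APOL1 risk classification to a patient table
#'
#' @param patients A tibble with integer columns `g1_dosage` and `g2_dosage`
#'   (hard calls; run [call_allele_count()] first for fractional dosages).
#' @return `patients` with columns `apol1_risk` (factor low/high) and
#'   `high_risk` (logical); patients with a missing call at either site get
#'   `NA` and the number of unclassifiable patients is attached as the
#'   `"n_unclassifiable"` attribute.
#' @export
classify_apol1_risk <- function(patients) {
  stopifnot(all(c("g1_dosage", "g2_dosage") %in% names(patients)))
  risk <- apol1_risk_group(patients$g1_dosage, patients$g2_dosage)
  out <- dplyr::mutate(patients, apol1_risk = risk,
                       high_risk = risk == "high")
  n_un <- sum(is.na(risk))
  if (n_un > 0) {
    inform(sprintf("%d patient(s) unclassifiable (missing genotype call).", n_un))
  }
  attr(out, "n_unclassifiable") <- n_un
  out
}

#' Read the two APOL1 sites from a VCF
#'
#' Extracts per-sample allele counts for the G1 site and the G2 proxy site
#' from a VCF, using hard genotypes (`GT`) when present or thresholded
#' imputed dosages (`DS`) otherwise. Sites are located by rs identifier or by
#' `"chrom:pos"` (1-based).
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param g1,g2 Site lookups: an rs id (e.g. `"rs73885319"`) or `"chrom:pos"`.
#' @param thresholds Dosage-calling thresholds, see [call_allele_count()].
#' @return A tibble with `sample_id`, `g1_dosage`, `g2_dosage`.
#' @export
read_apol1_vcf <- function(path, g1 = "rs73885319", g2 = "rs12106505",
                           thresholds = c(0.5, 1.5)) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("Reading VCFs requires the 'vcfR' package.", class = "apol1_io_error")
  }
  if (!file.exists(path)) {
    abort(sprintf("VCF not found: %s", path), class = "apol1_io_error")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  locate <- function(key) {
    i <- which(fix$ID == key)
    if (length(i) == 0L && grepl(":", key, fixed = TRUE)) {
      parts <- strsplit(key, ":", fixed = TRUE)[[1]]
      i <- which(fix$CHROM == parts[1] & fix$POS == parts[2])
    }
    if (length(i) != 1L) {
      abort(sprintf("Site '%s' not found (or not unique) in %s.", key, path),
            class = "apol1_validation_error")
    }
    i
  }
  site_counts <- function(i) {
    fmt <- strsplit(v@gt[i, 1], ":", fixed = TRUE)[[1]]
    fields <- v@gt[i, -1]
    parts <- strsplit(fields, ":", fixed = TRUE)
    if ("GT" %in% fmt) {
      k <- match("GT", fmt)
      gt <- vapply(parts, `[`, character(1), k)
      alt <- vapply(strsplit(gt, "[/|]"), function(a) {
        if (any(a == ".")) return(NA_integer_)
        sum(a != "0")
      }, integer(1))
      as.integer(alt)
    } else if ("DS" %in% fmt) {
      k <- match("DS", fmt)
      ds <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), k)))
      call_allele_count(ds, thresholds)
    } else {
      abort("VCF has neither GT nor DS genotype fields.",
            class = "apol1_validation_error")
    }
  }
  tibble::tibble(
    sample_id = colnames(v@gt)[-1],
    g1_dosage = site_counts(locate(g1)),
    g2_dosage = site_counts(locate(g2))
  )
}

#' Post-imputation variant QC thresholds (documentation constants)
#'
#' The source analysis filtered imputed variants with imputation quality
#' r-squared below 0.3, minor allele frequency below 0.5%, or an absolute MAF
#' difference above 0.3 versus the imputation reference panel. No raw
#' imputation data flows through this package, so these thresholds are
#' carried as a documented configuration constant and applied by
#' [apply_variant_qc()] to optional per-variant metadata only.
#'
#' @return Named list with `min_imputation_r2`, `min_maf`,
#'   `max_maf_diff_vs_reference`.
#' @export
variant_qc_defaults <- function() {
  list(min_imputation_r2 = 0.3, min_maf = 0.005,
       max_maf_diff_vs_reference = 0.3)
}

#' @rdname variant_qc_defaults
#' @param variants A tibble with optional columns `imputation_r2`, `maf`,
#'   `maf_reference`.
#' @param qc QC thresholds, see [variant_qc_defaults()].
#' @export
apply_variant_qc <- function(variants, qc = variant_qc_defaults()) {
  keep <- rep(TRUE, nrow(variants))
  if ("imputation_r2" %in% names(variants)) {
    keep <- keep & variants$imputation_r2 >= qc$min_imputation_r2
  }
  if ("maf" %in% names(variants)) {
    keep <- keep & variants$maf >= qc$min_maf
  }
  if (all(c("maf", "maf_reference") %in% names(variants))) {
    keep <- keep & abs(variants$maf - variants$maf_reference) <= qc$max_maf_diff_vs_reference
  }
  dplyr::mutate(variants, qc_pass = keep)
}
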