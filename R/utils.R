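# Internal helpers shared across modules.

#' @importFrom rlang %||% abort warn inform
#' @importFrom stats setNames
NULL

# ICD/CPT codes are compared after stripping dots and upper-casing, so
# "N18.4" and "n184" are the same code.
norm_code <- function(x) toupper(gsub(".", "", as.character(x), fixed = TRUE))

# TRUE where `code` starts with any of `prefixes` (both already normalized).
match_any_prefix <- function(code, prefixes) {
  if (length(prefixes) == 0L) {
    return(rep(FALSE, length(code)))
  }
  out <- rep(FALSE, length(code))
  for (p in prefixes) {
    out <- out | startsWith(code, p)
  }
  out
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name),
          class = "apol1_config_error")
  }
  invisible(x)
}

assert_pos <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x <= 0)) {
    abort(sprintf("`%s` must be strictly positive.", name),
          class = "apol1_config_error")
  }
  invisible(x)
}

# p-value display convention: two decimals at or above 0.001,
# scientific notation (e.g. "1.60E-10") below.
format_pvalue <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi >= 0.001) sprintf("%.2f", pi) else toupper(formatC(pi, format = "e", digits = 2))
  }, character(1))
}

# Deterministic per-stage child seeds from one master seed, kept inside
# 32-bit integer range so every stage is independently reproducible.
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.double(seed) + 999983 * as.double(stage)) %% 2147483647)
}

semi_join_ids <- function(ids) paste(sort(unique(ids)), collapse = ";")
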