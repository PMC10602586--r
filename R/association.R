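#' Fit one exposure-outcome logistic regression under a renal-disease strategy
#'
#' Fits `outcome ~ high_risk + covariates` by maximum likelihood (IRLS via
#' [stats::glm()]) and reports the exposure odds ratio with a 95% Wald
#' confidence interval (`exp(beta +/- 1.96 * SE)`) and two-sided Wald p-value,
#' so the OR/CI/p triple is mutually consistent. Analysis strategies mirror
#' the three ways of handling pre-existing severe renal disease:
#' \describe{
#'   \item{base}{adjust for age, sex and three ancestry PCs only;}
#'   \item{adjust_renal}{additionally adjust for severe renal disease;}
#'   \item{exclude_renal}{restrict to patients without severe renal disease;}
#'   \item{only_renal}{restrict to patients with severe renal disease.}
#' }
#' Rows with a missing value in any used column are dropped (complete-case);
#' the count is reported. Non-convergence or separation (an extreme
#' coefficient or a huge exposure standard error) flags the result rather
#' than silently returning numbers.
#'
#' @param data A cohort tibble (one row per patient) with a logical exposure
#'   column, logical outcome columns, `severe_renal`, and the covariates.
#' @param outcome Name of the logical outcome column (e.g. `"sepsis"`).
#' @param strategy One of `"base"`, `"adjust_renal"`, `"exclude_renal"`,
#'   `"only_renal"`.
#' @param covariates Adjustment covariates; default age, sex and the first
#'   three ancestry PCs.
#' @param exposure Name of the logical exposure column (default
#'   `"high_risk"`).
#' @return An object of class `"sepsis_fit"`; see [glance.sepsis_fit()] for
#'   the one-row summary and [tidy.sepsis_fit()] for the coefficient table.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 3000, seed = 11))
#' fit <- fit_outcome_model(cohort, "sepsis", "base")
#' glance(fit)
fit_outcome_model <- function(data, outcome,
                              strategy = c("base", "adjust_renal",
                                           "exclude_renal", "only_renal"),
                              covariates = c("age", "sex", "pc1", "pc2", "pc3"),
                              exposure = "high_risk") {
  strategy <- match.arg(strategy)
  needed <- unique(c(outcome, exposure, covariates,
                     if (strategy != "base") "severe_renal"))
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing column(s): %s", paste(missing_cols, collapse = ", ")),
          class = "apol1_validation_error")
  }
  d <- data
  if (strategy == "exclude_renal") d <- dplyr::filter(d, !.data$severe_renal)
  if (strategy == "only_renal") d <- dplyr::filter(d, .data$severe_renal)
  if (nrow(d) == 0L) {
    abort(sprintf("Strategy '%s' leaves an empty subset.", strategy),
          class = "apol1_model_error")
  }
  rhs <- c(exposure, covariates,
           if (strategy == "adjust_renal") "severe_renal")
  d <- d[, unique(c(outcome, rhs)), drop = FALSE]
  cc <- stats::complete.cases(d)
  n_missing <- sum(!cc)
  d <- d[cc, , drop = FALSE]
  y <- d[[outcome]]
  if (length(unique(y)) < 2L) {
    abort(sprintf("Outcome '%s' has no %s after subsetting.", outcome,
                  if (any(y)) "non-cases" else "cases"),
          class = "apol1_model_error")
  }
  # drop constant covariates (e.g. severe_renal within a renal subset)
  rhs <- rhs[vapply(rhs, function(v) length(unique(d[[v]])) > 1L, logical(1))]
  if (!exposure %in% rhs) {
    abort("Exposure is constant in this subset; model not estimable.",
          class = "apol1_model_error")
  }
  fml <- stats::as.formula(paste(outcome, "~", paste(rhs, collapse = " + ")))
  glm_warnings <- character()
  fit <- withCallingHandlers(
    stats::glm(fml, data = d, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 50)),
    warning = function(w) {
      glm_warnings <<- c(glm_warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  term <- paste0(exposure, "TRUE")
  if (!term %in% rownames(sm)) term <- exposure
  beta <- sm[term, "Estimate"]
  se <- sm[term, "Std. Error"]
  flagged <- !fit$converged || any(abs(stats::coef(fit)) > 15) || se > 10 ||
    length(glm_warnings) > 0
  note <- if (!fit$converged) {
    "IRLS did not converge"
  } else if (any(abs(stats::coef(fit)) > 15) || se > 10) {
    "possible separation (extreme coefficient or standard error)"
  } else if (length(glm_warnings) > 0) {
    paste(unique(glm_warnings), collapse = "; ")
  } else {
    ""
  }
  structure(list(
    fit = fit,
    spec = list(outcome = outcome, exposure = exposure, strategy = strategy,
                covariates = covariates),
    result = tibble::tibble(
      outcome = outcome, strategy = strategy,
      n_total = nrow(d), n_cases = sum(y), n_missing = n_missing,
      or = exp(beta),
      ci_low = exp(beta - 1.96 * se),
      ci_high = exp(beta + 1.96 * se),
      p = 2 * stats::pnorm(-abs(beta / se)),
      flagged = flagged, note = note)
  ), class = "sepsis_fit")
}

#' @export
print.sepsis_fit <- function(x, ...) {
  r <- x$result
  cat(sprintf("<sepsis_fit> %s ~ %s [%s]\n", r$outcome, x$spec$exposure,
              r$strategy))
  cat(sprintf("  OR = %.2f [95%% CI, %.2f-%.2f; p=%s]  (n=%d, cases=%d)%s\n",
              r$or, r$ci_low, r$ci_high, format_pvalue(r$p), r$n_total,
              r$n_cases, if (r$flagged) " [FLAGGED]" else ""))
  invisible(x)
}

#' Broom-style accessors for fitted sepsis models
#'
#' `tidy()` returns the per-term coefficient table on the odds-ratio scale;
#' `glance()` returns the one-row exposure summary (OR, Wald 95% CI, Wald p,
#' counts, convergence flag).
#'
#' @param x A `"sepsis_fit"` from [fit_outcome_model()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy sepsis_fit
#' @export
tidy.sepsis_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  est <- unname(sm[, "Estimate"])
  se <- unname(sm[, "Std. Error"])
  tibble::tibble(
    term = rownames(sm),
    estimate = est,
    std.error = se,
    statistic = unname(sm[, "z value"]),
    p.value = unname(sm[, "Pr(>|z|)"]),
    or = exp(est),
    ci_low = exp(est - 1.96 * se),
    ci_high = exp(est + 1.96 * se)
  )
}

#' @rdname tidy.sepsis_fit
#' @method glance sepsis_fit
#' @export
glance.sepsis_fit <- function(x, ...) {
  x$result
}

suite_outcomes <- function() {
  c("sepsis", "shock_code", "circulatory", "respiratory", "renal",
    "hepatic", "hematologic", "short_term_mortality")
}

#' Run the full outcome-by-strategy association grid
#'
#' Fits every combination of the eight outcomes (sepsis, septic-shock code,
#' the five organ-dysfunction criteria, short-term mortality) and the four
#' renal-disease strategies, returning a tidy forest-plot-ready table.
#' Combinations that are not estimable (no cases, empty subset, constant
#' exposure) yield a flagged row with `NA` estimates instead of an error.
#'
#' @inheritParams fit_outcome_model
#' @param outcomes Outcome columns to fit (default all eight).
#' @param strategies Strategies to fit (default all four).
#' @return A tibble of class `"sepsis_suite"`, one row per outcome-strategy
#'   pair; plot with [ggplot2::autoplot()].
#' @export
run_analysis_suite <- function(data,
                               outcomes = suite_outcomes(),
                               strategies = c("base", "adjust_renal",
                                              "exclude_renal", "only_renal"),
                               covariates = c("age", "sex", "pc1", "pc2", "pc3"),
                               exposure = "high_risk") {
  grid <- tidyr::expand_grid(outcome = outcomes, strategy = strategies)
  rows <- purrr::pmap(grid, function(outcome, strategy) {
    res <- tryCatch(
      glance(fit_outcome_model(data, outcome, strategy,
                               covariates = covariates, exposure = exposure)),
      apol1_model_error = function(e) {
        tibble::tibble(outcome = outcome, strategy = strategy,
                       n_total = NA_integer_, n_cases = NA_integer_,
                       n_missing = NA_integer_, or = NA_real_,
                       ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                       flagged = TRUE, note = conditionMessage(e))
      })
    res
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sepsis_suite", class(out))
  out
}

#' Secondary-outcome counts among sepsis cases
#'
#' Descriptive denominators as reported for secondary outcomes: among the
#' sepsis cases, the count and percentage with each component outcome.
#'
#' @param data A cohort tibble with outcome columns.
#' @return A tibble `outcome`, `n`, `pct` with the number of sepsis cases as
#'   the `"n_sepsis"` attribute.
#' @export
secondary_outcome_counts <- function(data) {
  cases <- dplyr::filter(data, .data$sepsis)
  outs <- setdiff(suite_outcomes(), "sepsis")
  out <- tibble::tibble(
    outcome = outs,
    n = vapply(outs, function(o) sum(cases[[o]]), integer(1)),
    pct = vapply(outs, function(o) 100 * mean(cases[[o]]), double(1))
  )
  attr(out, "n_sepsis") <- nrow(cases)
  out
}

#' Descriptive baseline table by APOL1 risk group
#'
#' Builds the baseline-characteristics table: categorical rows as n (%) per
#' risk group compared with a chi-square test using Yates continuity
#' correction (all comparisons are 2x2); age displayed as median (Q1-Q3) and
#' compared with a two-sample t-test. p-values are shown with two decimals
#' down to 0.001 and in scientific notation below that. Zero-margin tables
#' skip the test with a note.
#'
#' @param data A cohort tibble (needs `high_risk`, `age`, `sex`, and any
#'   logical characteristic columns).
#' @param characteristics Logical columns to tabulate; defaults to every
#'   Charlson flag, `severe_renal` and infection-type column present.
#' @return A tibble: `characteristic`, `overall`, `low_risk`, `high_risk`,
#'   `p_value` (formatted), `p_numeric`, `test`.
#' @export
table_one <- function(data, characteristics = NULL) {
  if (is.null(characteristics)) {
    skip <- c("sepsis", "shock_code", "circulatory", "respiratory", "renal",
              "hepatic", "hematologic", "short_term_mortality", "high_risk")
    characteristics <- setdiff(
      names(data)[vapply(data, is.logical, logical(1))], skip)
  }
  hr <- data$high_risk
  n_pct <- function(x) sprintf("%d (%.1f)", sum(x), 100 * mean(x))
  rows <- list()
  rows[[1]] <- tibble::tibble(
    characteristic = "Female",
    overall = n_pct(data$sex == "female"),
    low_risk = n_pct(data$sex[!hr] == "female"),
    high_risk = n_pct(data$sex[hr] == "female"),
    p_numeric = chisq_yates_p(data$sex == "female", hr),
    test = "chi-square (Yates)")
  q <- stats::quantile(data$age, c(0.5, 0.25, 0.75))
  qs <- function(x) {
    v <- stats::quantile(x, c(0.5, 0.25, 0.75))
    sprintf("%.0f (%.0f-%.0f)", v[1], v[2], v[3])
  }
  age_p <- tryCatch(stats::t.test(data$age[hr], data$age[!hr])$p.value,
                    error = function(e) NA_real_)
  rows[[2]] <- tibble::tibble(
    characteristic = "Age (at admission), median (Q1-Q3)",
    overall = qs(data$age), low_risk = qs(data$age[!hr]),
    high_risk = qs(data$age[hr]),
    p_numeric = age_p, test = "t-test")
  for (ch in characteristics) {
    x <- data[[ch]]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      characteristic = ch,
      overall = n_pct(x), low_risk = n_pct(x[!hr]), high_risk = n_pct(x[hr]),
      p_numeric = chisq_yates_p(x, hr),
      test = "chi-square (Yates)")
  }
  out <- dplyr::bind_rows(rows)
  out$p_value <- format_pvalue(out$p_numeric)
  out$test[is.na(out$p_numeric)] <- "skipped (zero margin)"
  dplyr::relocate(out, "characteristic", "overall", "low_risk", "high_risk",
                  "p_value")
}

# Continuity-corrected chi-square p for a 2x2 of logicals; NA on zero margin.
chisq_yates_p <- function(x, group) {
  tab <- table(factor(x, levels = c(FALSE, TRUE)),
               factor(group, levels = c(FALSE, TRUE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NA_real_)
  suppressWarnings(stats::chisq.test(tab, correct = TRUE)$p.value)
}

#' Continuity-corrected chi-square test for a 2x2 table
#'
#' Thin, explicit wrapper around [stats::chisq.test()] with Yates correction,
#' the test used for all categorical baseline comparisons.
#'
#' @param tab A 2x2 matrix or table of counts.
#' @return The `htest` object.
#' @export
#' @examples
#' chisq_yates(matrix(c(136, 225, 409, 1472), nrow = 2, byrow = TRUE))
chisq_yates <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) {
    abort("`tab` must be 2x2.", class = "apol1_validation_error")
  }
  stats::chisq.test(tab, correct = TRUE)
}

#' Forest plot of an association suite
#'
#' @param object A `"sepsis_suite"` from [run_analysis_suite()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sepsis_suite
#' @export
autoplot.sepsis_suite <- function(object, ...) {
  d <- dplyr::filter(object, !is.na(.data$or))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$outcome,
                                  xmin = .data$ci_low, xmax = .data$ci_high,
                                  colour = .data$strategy)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(position = ggplot2::position_dodge(width = 0.6)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% Wald CI, log scale)", y = NULL,
                  colour = "Renal-disease strategy") +
    ggplot2::theme_minimal()
}
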