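#' Prevalence per 1000
#'
#' @param case_count,population_count Non-negative counts (vectorised);
#'   `case_count <= population_count`, `population_count > 0`.
#' @param digits Rounding applied to the returned value; the conventional
#'   2 decimals by default. Use `digits = NULL` for the exact value.
#' @return `1000 * case_count / population_count`.
#' @export
#' @examples
#' prevalence_per_1000(54, 8850)    # 6.10
#' prevalence_per_1000(492, 8850)   # 55.59
prevalence_per_1000 <- function(case_count, population_count, digits = 2) {
  if (any(population_count <= 0)) {
    stop("`population_count` must be positive.", call. = FALSE)
  }
  if (any(case_count < 0) || any(case_count > population_count)) {
    stop("`case_count` must lie in [0, population_count].", call. = FALSE)
  }
  x <- 1000 * case_count / population_count
  if (is.null(digits)) x else round(x, digits)
}

#' Crude odds ratio from a 2x2 table
#'
#' OR = ad/bc with a Wald 95% confidence interval
#' `exp(log OR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is
#' zero the Haldane-Anscombe 0.5 correction is added to every cell and the
#' result flagged. Two zero cells on a margin leave the OR undefined.
#'
#' @param a,b,c,d Cell counts: exposed-case, exposed-noncase,
#'   unexposed-case, unexposed-noncase.
#' @return One-row tibble: `or`, `conf_low`, `conf_high`, `log_or`,
#'   `se_log_or`, `corrected` (logical).
#' @export
#' @examples
#' crude_or(54, 8850 - 54, 20793, 4265864 - 20793)
crude_or <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("cell counts must be non-negative.", call. = FALSE)
  if ((a == 0 && b == 0) || (c == 0 && d == 0) ||
      (a == 0 && c == 0) || (b == 0 && d == 0)) {
    stop("a zero margin leaves the odds ratio undefined.", call. = FALSE)
  }
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  lor <- log(cells[1]) - log(cells[2]) - log(cells[3]) + log(cells[4])
  se <- sqrt(sum(1 / cells))
  tibble::tibble(
    or = exp(lor),
    conf_low = exp(lor - stats::qnorm(0.975) * se),
    conf_high = exp(lor + stats::qnorm(0.975) * se),
    log_or = lor, se_log_or = se, corrected = corrected
  )
}

#' Covariate-adjusted logistic model for one disease
#'
#' Fits disease status on MS status plus the requested covariates by
#' binomial maximum likelihood (iteratively reweighted least squares,
#' relative deviance tolerance 1e-10, at most 100 iterations). The MS
#' coefficient is reported as an odds ratio with a Wald 95% interval,
#' matching conventional epidemiological output. Perfect separation and
#' non-convergence are flagged rather than silently reported.
#'
#' @param cohort Cohort tibble from [build_cohort()] (or any tibble with
#'   `ms`, the disease flag column, and the covariate columns).
#' @param disease Disease name; the outcome column is `aid_<disease>` (or
#'   `disease` itself if that column exists).
#' @param covariates Character subset of
#'   `c("age_years", "sex", "hosp_count_5y")`; default all three, the
#'   fully adjusted model. Use `character(0)` for the crude
#'   (exposure-only) model.
#' @return An object of class `aid_logit`; see [tidy.aid_logit()].
#' @export
fit_adjusted_logistic <- function(cohort,
                                  disease,
                                  covariates = c("age_years", "sex",
                                                 "hosp_count_5y")) {
  outcome_col <- if (disease %in% names(cohort)) disease
                 else paste0("aid_", disease)
  if (!outcome_col %in% names(cohort)) {
    stop(sprintf("no outcome column for disease `%s`.", disease),
         call. = FALSE)
  }
  if (length(covariates) > 0) {
    covariates <- match.arg(covariates,
                            c("age_years", "sex", "hosp_count_5y"),
                            several.ok = TRUE)
  }
  dat <- tibble::tibble(
    y = as.integer(cohort[[outcome_col]]),
    ms = as.integer(cohort$ms)
  )
  if ("age_years" %in% covariates) dat$age_years <- cohort$age_years
  if ("sex" %in% covariates) {
    dat$sex_female <- as.integer(cohort$sex == "female")
  }
  if ("hosp_count_5y" %in% covariates) {
    dat$hosp_count_5y <- cohort$hosp_count_5y
  }
  if (nrow(dat) <= ncol(dat)) {
    stop("more parameters than observations.", call. = FALSE)
  }
  fit <- stats::glm(y ~ ., family = stats::binomial(), data = dat,
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 100))
  eps <- 1e-8
  separated <- any(fit$fitted.values < eps | fit$fitted.values > 1 - eps) &&
    max(abs(stats::coef(fit)), na.rm = TRUE) > 15
  structure(list(fit = fit, disease = disease, covariates = covariates,
                 converged = fit$converged, separated = separated,
                 n_obs = nrow(dat)),
            class = "aid_logit")
}

#' @export
print.aid_logit <- function(x, ...) {
  cat(sprintf("<aid_logit> outcome: %s; covariates: %s; n = %d\n",
              x$disease,
              if (length(x$covariates)) paste(x$covariates, collapse = ", ")
              else "(crude)", x$n_obs))
  if (x$separated) cat("  WARNING: perfect separation detected\n")
  if (!x$converged) cat("  WARNING: IRLS did not converge\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy a fitted disease-association model
#'
#' @param x An `aid_logit` from [fit_adjusted_logistic()].
#' @param ... Unused.
#' @return A tibble with one row per model term: `term`, `estimate`
#'   (log-odds), `std_error`, `statistic`, `p_value`, `or`, `conf_low`,
#'   `conf_high` (Wald 95% interval on the OR scale). When separation was
#'   detected the OR columns are `NA` — there is no finite estimate to
#'   report.
#' @export
tidy.aid_logit <- function(x, ...) {
  s <- unname(summary(x$fit)$coefficients)
  terms <- rownames(summary(x$fit)$coefficients)
  out <- tibble::tibble(
    term = terms,
    estimate = s[, 1], std_error = s[, 2],
    statistic = s[, 3], p_value = s[, 4],
    or = exp(s[, 1]),
    conf_low = exp(s[, 1] - stats::qnorm(0.975) * s[, 2]),
    conf_high = exp(s[, 1] + stats::qnorm(0.975) * s[, 2])
  )
  if (x$separated) {
    out$or <- out$conf_low <- out$conf_high <- NA_real_
  }
  out
}

#' @rdname tidy.aid_logit
#' @return For `glance()`: a one-row tibble with `n_obs`, `converged`,
#'   `separated`, `deviance`, `null_deviance`, `aic`.
#' @export
glance.aid_logit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs, converged = x$converged, separated = x$separated,
    deviance = x$fit$deviance, null_deviance = x$fit$null.deviance,
    aic = x$fit$aic
  )
}

#' Odds ratio of MS from a fitted model
#'
#' Convenience accessor for the exposure row of [tidy.aid_logit()].
#'
#' @param x An `aid_logit`.
#' @return One-row tibble: `disease`, `or`, `conf_low`, `conf_high`,
#'   `p_value`.
#' @export
ms_odds_ratio <- function(x) {
  td <- tidy(x)
  row <- td[td$term == "ms", ]
  tibble::tibble(disease = x$disease, or = row$or,
                 conf_low = row$conf_low, conf_high = row$conf_high,
                 p_value = row$p_value)
}

#' Baseline group comparisons for one disease
#'
#' Among subjects flagged with the disease, compares the MS and non-MS
#' groups: Pearson chi-square (1 df, no continuity correction) for the sex
#' proportion, and one-way ANOVA F tests for mean age and mean
#' hospitalization count.
#'
#' @param cohort Cohort tibble.
#' @param disease Disease name (column `aid_<disease>` or `disease`).
#' @return One-row tibble: `chi2_p_sex`, `anova_p_age`,
#'   `anova_p_discharges`, plus group sizes `n_ms`, `n_nonms`.
#' @export
baseline_tests <- function(cohort, disease) {
  outcome_col <- if (disease %in% names(cohort)) disease
                 else paste0("aid_", disease)
  cases <- cohort[cohort[[outcome_col]], ]
  if (length(unique(cases$ms)) < 2) {
    stop("both MS and non-MS cases are required.", call. = FALSE)
  }
  tab <- table(factor(cases$ms, levels = c(FALSE, TRUE)),
               factor(cases$sex == "female", levels = c(FALSE, TRUE)))
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  anova_p <- function(y) {
    if (stats::var(y) == 0) {
      stop("zero-variance outcome in baseline ANOVA.", call. = FALSE)
    }
    stats::anova(stats::lm(y ~ cases$ms))[["Pr(>F)"]][1]
  }
  tibble::tibble(
    chi2_p_sex = chi$p.value,
    anova_p_age = anova_p(cases$age_years),
    anova_p_discharges = anova_p(cases$hosp_count_5y),
    n_ms = sum(cases$ms), n_nonms = sum(!cases$ms)
  )
}

#' Per-disease association table
#'
#' Assembles the per-disease summary a comorbidity study reports:
#' prevalence per 1000 in each group, the crude odds ratio, the
#' age/sex-adjusted odds ratio, and the fully adjusted odds ratio (age,
#' sex, hospitalizations), each with its Wald 95% interval.
#'
#' @param cohort Cohort tibble from [build_cohort()].
#' @param diseases Character vector of diseases; default: every `aid_*`
#'   column in the cohort.
#' @return A tibble with one row per disease.
#' @export
association_table <- function(cohort, diseases = NULL) {
  if (is.null(diseases)) {
    diseases <- sub("^aid_", "", grep("^aid_", names(cohort), value = TRUE))
  }
  n_ms <- sum(cohort$ms)
  n_nonms <- sum(!cohort$ms)
  purrr::map_dfr(diseases, function(d) {
    col <- paste0("aid_", d)
    a <- sum(cohort$ms & cohort[[col]])
    c_ <- sum(!cohort$ms & cohort[[col]])
    crude <- tryCatch(crude_or(a, n_ms - a, c_, n_nonms - c_),
                      error = function(e) NULL)
    fit_fmt <- function(covs) {
      res <- tryCatch(
        ms_odds_ratio(fit_adjusted_logistic(cohort, d, covariates = covs)),
        error = function(e) NULL)
      if (is.null(res)) rep(NA_real_, 3)
      else c(res$or, res$conf_low, res$conf_high)
    }
    adj_as <- fit_fmt(c("age_years", "sex"))
    adj_full <- fit_fmt(c("age_years", "sex", "hosp_count_5y"))
    tibble::tibble(
      disease = d,
      n_cases_ms = a, n_cases_nonms = c_,
      prev_ms = prevalence_per_1000(a, n_ms),
      prev_nonms = prevalence_per_1000(c_, n_nonms),
      or_crude = crude$or %||% NA_real_,
      or_crude_low = crude$conf_low %||% NA_real_,
      or_crude_high = crude$conf_high %||% NA_real_,
      or_age_sex = adj_as[1], or_age_sex_low = adj_as[2],
      or_age_sex_high = adj_as[3],
      or_full = adj_full[1], or_full_low = adj_full[2],
      or_full_high = adj_full[3]
    )
  })
}
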