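#' Simulate a ground-truth population
#'
#' Draws subjects with sex, age, true MS status, true status for each
#' configured autoimmune disease, and a 5-year hospitalization count.
#' Disease status is conditionally independent across diseases given MS
#' status: the per-disease log-odds is the baseline logit shifted by
#' `log(ms_odds_ratio)` for MS subjects (plus the optional sex/age
#' confounding terms, zero by default so a crude truth-table odds ratio
#' recovers the configured value). Hospitalization counts are negative
#' binomial with a mean scaled up by MS and by each disease present,
#' reproducing the overdispersed, group-dependent contact counts seen in
#' administrative data.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A tibble with one row per subject: `subject_id`, `sex`
#'   (`"female"`/`"male"`), `age_years`, `alive_at_reference`, `ms`
#'   (true status), one logical `aid_<disease>` column per configured
#'   disease (true status), and `hosp_count_5y`.
#' @export
#' @examples
#' pop <- simulate_population(sim_config(n_subjects = 500, seed = 42))
#' mean(pop$ms)
simulate_population <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(seed %||% config$seed)
  n <- config$n_subjects

  ms <- stats::runif(n) < config$ms_prevalence
  p_female <- ifelse(ms, config$female_fraction_ms, config$female_fraction)
  sex <- ifelse(stats::runif(n) < p_female, "female", "male")
  age <- round(ifelse(ms,
                      stats::rnorm(n, config$ms_age_mean, config$ms_age_sd),
                      stats::rnorm(n, config$age_mean, config$age_sd)))
  age <- pmin(pmax(age, config$age_range[1]), config$age_range[2])

  pop <- tibble::tibble(
    subject_id = sprintf("S%07d", seq_len(n)),
    sex = sex, age_years = as.integer(age),
    alive_at_reference = TRUE, ms = ms
  )

  log_hosp_mult <- rep(0, n)
  for (i in seq_len(nrow(config$diseases))) {
    d <- config$diseases[i, ]
    lp <- stats::qlogis(d$baseline_prevalence) +
      log(d$ms_odds_ratio) * ms +
      d$female_log_or * (sex == "female") +
      d$age_log_or_per10 * (age - 50) / 10
    has <- stats::runif(n) < stats::plogis(lp)
    pop[[paste0("aid_", d$disease)]] <- has
    log_hosp_mult <- log_hosp_mult + log(d$hosp_mult) * has
  }
  mu <- config$hosp_base_mean * exp(log_hosp_mult) *
    ifelse(ms, config$hosp_ms_mult, 1)
  pop$hosp_count_5y <- stats::rnbinom(n, size = config$hosp_size, mu = mu)
  pop
}

#' Calibrate per-stream emission rates from an algorithm-level operating point
#'
#' The validated operating point (e.g. sensitivity 95.9%, specificity
#' 99.9%) describes the whole any-stream algorithm. Under independent
#' streams, a union of `k` streams hits a true case unless every stream
#' misses, and stays silent on a non-case only if every stream stays
#' silent, so the per-stream rates solve
#' `1 - (1 - s_k)^k = s` and `spec_k = spec^(1/k)`.
#'
#' @param sensitivity,specificity Algorithm-level operating point.
#' @param k Number of streams in the algorithm.
#' @return List with `sensitivity` and `specificity` per stream.
#' @export
calibrate_stream_rates <- function(sensitivity, specificity, k) {
  stopifnot(k >= 1, sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  list(sensitivity = 1 - (1 - sensitivity)^(1 / k),
       specificity = specificity^(1 / k))
}

#' Simulate linked archive events from true disease status
#'
#' For every algorithm (MS plus each disease), each of its archive streams
#' independently "fires" with the calibrated per-stream sensitivity for
#' true cases and one minus the per-stream specificity for non-cases; a
#' firing stream emits the stream's minimum qualifying count of coded
#' events at dates uniform in the lookback window. Background
#' hospital-discharge events (code `HOSP_ANY`) are emitted according to
#' each subject's simulated hospitalization count, so the
#' contact-frequency confounder is reproducible. A positive
#' `surveillance_log_or` in the config shifts each subject's per-stream
#' emission log-odds by that amount per hospitalization, creating
#' surveillance bias (more contact, more detection — for true and false
#' positives alike).
#'
#' @param subjects Population tibble from [simulate_population()].
#' @param algorithms Named list of [case_algorithm()] objects (element
#'   `"ms"` plus one per disease); defaults to
#'   [default_algorithms()] on `config`.
#' @param config The [sim_config()] used for the population.
#' @param seed Optional seed overriding `config$seed + 1`.
#' @return Event tibble: `subject_id`, `stream`, `date`, `code`, sorted by
#'   subject, stream, date, code (byte-identical under a fixed seed).
#' @export
simulate_events <- function(subjects, algorithms = NULL, config,
                            seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  algorithms <- algorithms %||% default_algorithms(config)
  set.seed(seed %||% (config$seed + 1L))
  win <- lookback_window(config)
  n <- nrow(subjects)
  surv <- config$surveillance_log_or
  hosp <- subjects$hosp_count_5y %||% rep(0L, n)

  op_for <- function(disease) {
    if (disease == "ms") {
      return(list(sens = config$sensitivity, spec = config$specificity))
    }
    row <- config$diseases[config$diseases$disease == disease, ]
    if (nrow(row) == 1) {
      return(list(sens = row$sensitivity, spec = row$specificity))
    }
    list(sens = config$sensitivity, spec = config$specificity)
  }

  pieces <- vector("list", 4L * length(algorithms) + 1L)
  pi <- 1L
  for (nm in names(algorithms)) {
    alg <- algorithms[[nm]]
    truth_col <- if (alg$disease == "ms") "ms" else paste0("aid_", alg$disease)
    if (!truth_col %in% names(subjects)) {
      stop(sprintf("population table lacks truth column `%s`.", truth_col),
           call. = FALSE)
    }
    truth <- subjects[[truth_col]]
    op <- op_for(alg$disease)
    k <- length(alg$streams)
    rates <- calibrate_stream_rates(op$sens, op$spec, k)
    for (snm in names(alg$streams)) {
      s <- alg$streams[[snm]]
      p <- ifelse(truth, rates$sensitivity, 1 - rates$specificity)
      if (surv != 0) {
        p <- stats::plogis(stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12)) +
                             surv * hosp)
      }
      fired <- stats::runif(n) < p
      if (!any(fired)) next
      idx <- rep(which(fired), each = s$min_count)
      pieces[[pi]] <- tibble::tibble(
        subject_id = subjects$subject_id[idx],
        stream = snm,
        date = win[1] + floor(stats::runif(length(idx)) *
                                as.numeric(win[2] - win[1] + 1)),
        code = s$codes[1]
      )
      pi <- pi + 1L
    }
  }
  n_bg <- sum(hosp)
  if (n_bg > 0) {
    idx <- rep.int(seq_len(n), hosp)
    pieces[[pi]] <- tibble::tibble(
      subject_id = subjects$subject_id[idx],
      stream = "hospital_discharge",
      date = win[1] + floor(stats::runif(n_bg) *
                              as.numeric(win[2] - win[1] + 1)),
      code = "HOSP_ANY"
    )
  }
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0) {
    return(tibble::tibble(subject_id = character(), stream = character(),
                          date = as.Date(character()), code = character()))
  }
  dplyr::arrange(out, .data$subject_id, .data$stream, .data$date, .data$code)
}

#' Write simulated tables to disk as delimited text
#'
#' Writes the subjects table and one CSV per archive stream (ISO-8601
#' dates), the layout a linkage analysis would start from.
#'
#' @param subjects Population tibble.
#' @param events Event tibble.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(subjects, events, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  for (s in unique(events$stream)) {
    utils::write.csv(dplyr::filter(events, .data$stream == s),
                     file.path(dir, paste0(s, ".csv")), row.names = FALSE)
  }
  invisible(dir)
}
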