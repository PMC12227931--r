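#' Archive streams recognised by the case-finding machinery
#'
#' The four electronic health archives: hospital discharges, pharmacy drug
#' prescriptions, chronic-disease co-payment exemptions, and long-term-care
#' residence lists.
#'
#' @return Character vector of stream names.
#' @export
eha_streams <- function() {
  c("hospital_discharge", "drug_prescription", "copay_exemption",
    "ltc_residence")
}

#' Declare a multi-source case-finding algorithm
#'
#' A declarative rule mapping archive-event patterns to a disease flag:
#' per-stream qualifying code sets and minimum event counts, a combination
#' rule across streams, a lookback window, and an optional exclusion rule
#' (subjects with an exclusion code shortly before their first qualifying
#' event are not flagged — e.g. thyrotoxic-drug treatment in the 12 months
#' before an apparent Hashimoto diagnosis).
#'
#' @param disease Disease name the algorithm flags.
#' @param streams Named list keyed by archive stream; each element is a
#'   list with `codes` (character vector of qualifying code tokens) and
#'   optionally `min_count` (default 1).
#' @param rule `"any"` (default): any stream satisfied flags the subject;
#'   `"all"`: every listed stream must be satisfied.
#' @param window Date vector `c(start, end)` of the lookback window.
#' @param exclusion Optional list with `codes`, `days_before` (default
#'   365) and optionally `streams`; a subject is unflagged when any
#'   exclusion-code event occurs within `days_before` days before their
#'   first qualifying event.
#' @return An object of class `case_algorithm`.
#' @export
#' @examples
#' alg <- case_algorithm(
#'   "hypothyroidism",
#'   streams = list(copay_exemption = list(codes = "EX_HYPOTHYROIDISM")),
#'   window = as.Date(c("2013-01-01", "2017-12-31"))
#' )
case_algorithm <- function(disease, streams, rule = c("any", "all"),
                           window, exclusion = NULL) {
  rule <- match.arg(rule)
  if (length(streams) == 0) {
    stop("at least one stream must be declared.", call. = FALSE)
  }
  unknown <- setdiff(names(streams), eha_streams())
  if (length(unknown) > 0) {
    stop("unknown archive stream(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  streams <- lapply(streams, function(s) {
    if (is.character(s)) s <- list(codes = s)
    s$min_count <- as.integer(s$min_count %||% 1L)
    if (length(s$codes) == 0) stop("empty code set in stream.", call. = FALSE)
    s
  })
  window <- as.Date(window)
  if (anyNA(window) || window[1] > window[2]) {
    stop("`window` must be two ordered dates.", call. = FALSE)
  }
  if (!is.null(exclusion)) {
    exclusion$days_before <- exclusion$days_before %||% 365
    if (is.null(exclusion$codes)) {
      stop("exclusion rule needs `codes`.", call. = FALSE)
    }
  }
  structure(list(disease = disease, streams = streams, rule = rule,
                 window = window, exclusion = exclusion),
            class = "case_algorithm")
}

#' @export
print.case_algorithm <- function(x, ...) {
  cat(sprintf("<case_algorithm> %s [%s of %d stream(s)], window %s..%s%s\n",
              x$disease, x$rule, length(x$streams),
              format(x$window[1]), format(x$window[2]),
              if (is.null(x$exclusion)) "" else ", with exclusion rule"))
  invisible(x)
}

#' Default algorithm set for MS and the 14 autoimmune diseases
#'
#' MS is sought in all four archives; each autoimmune disease in hospital
#' discharges, drug prescriptions and co-payment exemptions. Codes are
#' opaque tokens shared with the event simulator. Hashimoto thyroiditis
#' carries the thyrotoxic-drug exclusion (window 365 days before the first
#' qualifying event).
#'
#' @param config A [sim_config()]; supplies the disease list and window.
#' @return Named list of [case_algorithm()] objects, including `"ms"`.
#' @export
default_algorithms <- function(config = sim_config()) {
  win <- lookback_window(config)
  mk_codes <- function(disease) list(
    hospital_discharge = list(codes = paste0("DX_", toupper(disease))),
    drug_prescription = list(codes = paste0("RX_", toupper(disease))),
    copay_exemption = list(codes = paste0("EX_", toupper(disease)))
  )
  algs <- list(
    ms = case_algorithm("ms", c(mk_codes("ms"), list(
      ltc_residence = list(codes = "LTC_MS"))), window = win)
  )
  for (d in config$diseases$disease) {
    excl <- if (d == "hashimoto_thyroiditis") {
      list(codes = "RX_THYROTOXIC", days_before = 365,
           streams = "drug_prescription")
    }
    algs[[d]] <- case_algorithm(d, mk_codes(d), window = win,
                                exclusion = excl)
  }
  algs
}

#' Apply a case-finding algorithm to an event table
#'
#' Flags every subject whose events satisfy the algorithm's per-stream
#' code/count logic inside the lookback window, subject to the combination
#' rule, and whose exclusion rule (if any) does not fire. The result is
#' independent of row order and idempotent.
#'
#' @param events Tibble of archive events with columns `subject_id`,
#'   `stream`, `date` (Date), `code`.
#' @param algorithm A [case_algorithm()].
#' @return Sorted character vector of flagged subject ids.
#' @export
apply_algorithm <- function(events, algorithm) {
  stopifnot(inherits(algorithm, "case_algorithm"))
  events <- as_event_table(events)
  if (nrow(events) == 0) return(character(0))

  per_stream <- purrr::imap(algorithm$streams, function(s, nm) {
    ev <- dplyr::filter(events, .data$stream == nm,
                        .data$code %in% s$codes,
                        .data$date >= algorithm$window[1],
                        .data$date <= algorithm$window[2])
    counts <- dplyr::count(ev, .data$subject_id)
    list(
      hit = counts$subject_id[counts$n >= s$min_count],
      qualifying = ev
    )
  })
  hits <- lapply(per_stream, `[[`, "hit")
  flagged <- if (algorithm$rule == "any") {
    unique(unlist(hits, use.names = FALSE))
  } else {
    Reduce(intersect, hits)
  }
  if (length(flagged) == 0) return(character(0))

  excl <- algorithm$exclusion
  if (!is.null(excl)) {
    qual <- dplyr::bind_rows(lapply(per_stream, `[[`, "qualifying"))
    first_qual <- qual |>
      dplyr::filter(.data$subject_id %in% flagged) |>
      dplyr::summarise(first_date = min(.data$date), .by = "subject_id")
    excl_ev <- events |>
      dplyr::filter(.data$code %in% excl$codes)
    if (!is.null(excl$streams)) {
      excl_ev <- dplyr::filter(excl_ev, .data$stream %in% excl$streams)
    }
    fired <- excl_ev |>
      dplyr::inner_join(first_qual, by = "subject_id") |>
      dplyr::filter(.data$date < .data$first_date,
                    .data$date >= .data$first_date - excl$days_before) |>
      dplyr::distinct(.data$subject_id)
    flagged <- setdiff(flagged, fired$subject_id)
  }
  sort(flagged)
}

#' Count hospitalizations for any cause in a window
#'
#' Counts `hospital_discharge` events regardless of code — qualifying
#' disease-coded discharges count too, as any discharge is a
#' hospitalization. Unknown subjects get 0.
#'
#' @param events Event tibble (see [apply_algorithm()]).
#' @param window Date vector `c(start, end)`.
#' @param subject_ids Optional character vector fixing the output rows (in
#'   that order, zeros filled in); default: all subjects seen in `events`.
#' @return Tibble with `subject_id` and integer `hosp_count`.
#' @export
count_hospitalizations <- function(events, window, subject_ids = NULL) {
  events <- as_event_table(events)
  window <- as.Date(window)
  counts <- events |>
    dplyr::filter(.data$stream == "hospital_discharge",
                  .data$date >= window[1], .data$date <= window[2]) |>
    dplyr::count(.data$subject_id, name = "hosp_count")
  if (is.null(subject_ids)) {
    return(dplyr::arrange(counts, .data$subject_id))
  }
  tibble::tibble(subject_id = subject_ids) |>
    dplyr::left_join(counts, by = "subject_id") |>
    dplyr::mutate(hosp_count = as.integer(tidyr::replace_na(.data$hosp_count, 0L)))
}

#' Operating characteristics of a case-finding algorithm
#'
#' Compares flags against ground truth and returns the standard 2x2
#' measures as exact ratios.
#'
#' @param flags Character vector of flagged subject ids, or a logical
#'   vector aligned with `truth`.
#' @param truth Either a tibble with `subject_id` and a logical `status`
#'   column, or a named logical vector, or (when `flags` is logical) a
#'   plain logical vector.
#' @return One-row tibble: `sensitivity`, `specificity`, `ppv`, `npv`,
#'   plus the underlying counts `tp`, `fp`, `fn`, `tn`.
#' @export
evaluate_algorithm <- function(flags, truth) {
  if (is.data.frame(truth)) {
    status <- truth$status
    names(status) <- truth$subject_id
  } else {
    status <- truth
  }
  if (is.logical(flags)) {
    if (length(flags) != length(status)) {
      stop("logical `flags` must align with `truth`.", call. = FALSE)
    }
    flagged <- flags
  } else {
    if (is.null(names(status))) {
      stop("`truth` must carry subject ids when `flags` are ids.",
           call. = FALSE)
    }
    flagged <- names(status) %in% flags
  }
  tp <- sum(flagged & status); fp <- sum(flagged & !status)
  fn <- sum(!flagged & status); tn <- sum(!flagged & !status)
  tibble::tibble(
    sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    ppv = tp / (tp + fp), npv = tn / (tn + fn),
    tp = tp, fp = fp, fn = fn, tn = tn
  )
}

#' Build the analysis cohort from population, events and algorithms
#'
#' Applies the MS algorithm and every disease algorithm, counts
#' hospitalizations over the lookback window, and assembles one analysis
#' row per alive subject. Subjects not flagged for MS are restricted to
#' the integer age range observed among flagged MS subjects, mirroring an
#' MS-free comparison population drawn from the same age span.
#'
#' @param subjects Population tibble with `subject_id`, `sex`,
#'   `age_years` and optionally `alive_at_reference` (default `TRUE`).
#' @param events Event tibble.
#' @param algorithms Named list of [case_algorithm()] objects; the element
#'   named `"ms"` defines MS, all others become `aid_*` flag columns.
#' @param reference_date Unused in flag logic (windows live in the
#'   algorithms) but recorded as an attribute of the cohort.
#' @return A cohort tibble: `subject_id`, `ms`, one logical `aid_<disease>`
#'   column per non-MS algorithm, `age_years`, `sex`, `hosp_count_5y`.
#' @export
build_cohort <- function(subjects, events, algorithms,
                         reference_date = NULL) {
  subjects <- tibble::as_tibble(subjects)
  if (anyDuplicated(subjects$subject_id)) {
    stop("duplicate subject_id in population table.", call. = FALSE)
  }
  if (!"ms" %in% names(algorithms)) {
    stop("`algorithms` must contain an element named \"ms\".", call. = FALSE)
  }
  if (!"alive_at_reference" %in% names(subjects)) {
    subjects$alive_at_reference <- TRUE
  }
  cohort <- subjects |>
    dplyr::filter(.data$alive_at_reference) |>
    dplyr::select("subject_id", "sex", "age_years")

  ms_ids <- apply_algorithm(events, algorithms$ms)
  cohort$ms <- cohort$subject_id %in% ms_ids
  for (nm in setdiff(names(algorithms), "ms")) {
    ids <- apply_algorithm(events, algorithms[[nm]])
    cohort[[paste0("aid_", nm)]] <- cohort$subject_id %in% ids
  }
  win <- algorithms$ms$window
  hosp <- count_hospitalizations(events, win, cohort$subject_id)
  cohort$hosp_count_5y <- hosp$hosp_count

  if (any(cohort$ms)) {
    rng <- range(cohort$age_years[cohort$ms])
    cohort <- dplyr::filter(cohort, .data$ms |
                              (.data$age_years >= rng[1] &
                               .data$age_years <= rng[2]))
  }
  cohort <- dplyr::relocate(cohort, "subject_id", "ms")
  attr(cohort, "reference_date") <- reference_date
  cohort
}

as_event_table <- function(events) {
  events <- tibble::as_tibble(events)
  need <- c("subject_id", "stream", "date", "code")
  if (!all(need %in% names(events))) {
    stop("event table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!inherits(events$date, "Date")) {
    parsed <- as.Date(as.character(events$date), format = "%Y-%m-%d")
    if (anyNA(parsed) && nrow(events) > 0) {
      stop("malformed event dates (expected ISO-8601).", call. = FALSE)
    }
    events$date <- parsed
  }
  events
}
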