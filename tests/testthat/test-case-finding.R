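test_that("algorithm declaration validates streams, codes and windows", {
  expect_error(simple_algorithm(stream = "outpatient_visits"), "unknown")
  expect_error(case_algorithm("x", list(), window = fixture_window),
               "at least one stream")
  expect_error(
    case_algorithm("x",
                   list(copay_exemption = list(codes = character(0))),
                   window = fixture_window),
    "empty code set")
  expect_error(simple_algorithm(exclusion = list(days_before = 10)), "codes")
  expect_error(
    case_algorithm("x", list(copay_exemption = list(codes = "C")),
                   window = rev(fixture_window)),
    "ordered")
})

test_that("one qualifying event flags under an any-stream rule", {
  alg <- simple_algorithm()
  ev <- event_row("s1", "copay_exemption", "2015-06-01", "EX_HYPOTHYROIDISM")
  expect_equal(apply_algorithm(ev, alg), "s1")
  # idempotent and order independent
  ev2 <- dplyr::bind_rows(ev, event_row("s0", "drug_prescription",
                                        "2015-06-01", "RX_OTHER"))
  expect_equal(apply_algorithm(ev2[2:1, ], alg), "s1")
})

test_that("empty event tables and out-of-window events flag nobody", {
  alg <- simple_algorithm()
  expect_equal(apply_algorithm(tibble::tibble(
    subject_id = character(), stream = character(),
    date = as.Date(character()), code = character()), alg), character(0))
  late <- event_row("s1", "copay_exemption", "2018-02-01",
                    "EX_HYPOTHYROIDISM")
  expect_equal(apply_algorithm(late, alg), character(0))
})

test_that("minimum event counts and all-stream rules are enforced", {
  alg2 <- simple_algorithm(min_count = 2L)
  one <- event_row("s1", "copay_exemption", "2015-06-01",
                   "EX_HYPOTHYROIDISM")
  expect_equal(apply_algorithm(one, alg2), character(0))
  two <- dplyr::bind_rows(one, event_row("s1", "copay_exemption",
                                         "2016-01-01", "EX_HYPOTHYROIDISM"))
  expect_equal(apply_algorithm(two, alg2), "s1")

  alg_all <- case_algorithm(
    "d", list(copay_exemption = list(codes = "EX_D"),
              drug_prescription = list(codes = "RX_D")),
    rule = "all", window = fixture_window)
  only_one_stream <- event_row("s1", "copay_exemption", "2015-06-01", "EX_D")
  expect_equal(apply_algorithm(only_one_stream, alg_all), character(0))
  both <- dplyr::bind_rows(
    only_one_stream,
    event_row("s1", "drug_prescription", "2015-07-01", "RX_D"))
  expect_equal(apply_algorithm(both, alg_all), "s1")
})

test_that("thyrotoxic-drug exclusion unflags treatment within 12 months
           before the first qualifying event", {
  alg <- simple_algorithm(
    disease = "hashimoto_thyroiditis", codes = "EX_HASHIMOTO",
    exclusion = list(codes = "RX_THYROTOXIC", days_before = 365))
  qual <- event_row("s1", "copay_exemption", "2015-06-01", "EX_HASHIMOTO")
  within <- dplyr::bind_rows(
    qual, event_row("s1", "drug_prescription", "2015-01-10",
                    "RX_THYROTOXIC"))
  expect_equal(apply_algorithm(within, alg), character(0))
  # same drug more than 12 months before, or after, does not exclude
  before <- dplyr::bind_rows(
    qual, event_row("s1", "drug_prescription", "2014-01-10",
                    "RX_THYROTOXIC"))
  expect_equal(apply_algorithm(before, alg), "s1")
  after <- dplyr::bind_rows(
    qual, event_row("s1", "drug_prescription", "2016-06-01",
                    "RX_THYROTOXIC"))
  expect_equal(apply_algorithm(after, alg), "s1")
})

test_that("adding qualifying events never unflags (monotonicity)", {
  alg <- simple_algorithm(min_count = 2L)
  set.seed(7)
  for (rep in 1:20) {
    n_ev <- sample(0:6, 1)
    ev <- tibble::tibble(
      subject_id = sample(c("a", "b"), n_ev, TRUE),
      stream = "copay_exemption",
      date = fixture_window[1] + sample(0:1500, n_ev, TRUE),
      code = sample(c("EX_HYPOTHYROIDISM", "OTHER"), n_ev, TRUE))
    base_flags <- apply_algorithm(ev, alg)
    extra <- event_row("a", "copay_exemption", "2015-01-01",
                       "EX_HYPOTHYROIDISM")
    grown <- apply_algorithm(dplyr::bind_rows(ev, extra), alg)
    expect_true(all(base_flags %in% grown))
  }
})

test_that("row permutation never changes any case-finding output", {
  cfg <- sim_config(n_subjects = 500, ms_prevalence = 0.1, seed = 44)
  pop <- simulate_population(cfg)
  algs <- default_algorithms(cfg)
  ev <- simulate_events(pop, algs, cfg)
  set.seed(1)
  shuffled <- ev[sample(nrow(ev)), ]
  expect_identical(apply_algorithm(ev, algs$ms),
                   apply_algorithm(shuffled, algs$ms))
  win <- lookback_window(cfg)
  expect_identical(count_hospitalizations(ev, win, pop$subject_id),
                   count_hospitalizations(shuffled, win, pop$subject_id))
  c1 <- build_cohort(pop, ev, algs)
  c2 <- build_cohort(pop, shuffled, algs)
  expect_identical(c1, c2)
})

test_that("hospitalization counting is window-bound, code-blind and zero
           for unknown subjects", {
  ev <- dplyr::bind_rows(
    event_row("s1", "hospital_discharge", "2013-05-01", "HOSP_ANY"),
    event_row("s1", "hospital_discharge", "2014-05-01", "DX_SOMETHING"),
    event_row("s1", "hospital_discharge", "2016-05-01", "HOSP_ANY"),
    event_row("s1", "hospital_discharge", "2012-12-31", "HOSP_ANY"),
    event_row("s1", "hospital_discharge", "2018-01-01", "HOSP_ANY"),
    event_row("s2", "drug_prescription", "2015-01-01", "RX_X"))
  counts <- count_hospitalizations(ev, fixture_window, c("s1", "s2", "s3"))
  expect_equal(counts$hosp_count, c(3L, 0L, 0L))
})

test_that("malformed event dates are an error", {
  ev <- tibble::tibble(subject_id = "s1", stream = "hospital_discharge",
                       date = "01/05/2013", code = "HOSP_ANY")
  expect_error(count_hospitalizations(ev, fixture_window), "malformed")
})

test_that("operating characteristics follow the exact 2x2 definitions", {
  truth <- tibble::tibble(subject_id = sprintf("s%02d", 1:10),
                          status = rep(c(TRUE, FALSE), c(4, 6)))
  perfect <- evaluate_algorithm(truth$subject_id[truth$status], truth)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$ppv, 1)
  expect_equal(perfect$npv, 1)
  inverted <- evaluate_algorithm(truth$subject_id[!truth$status], truth)
  expect_equal(inverted$sensitivity, 0)
  expect_equal(inverted$specificity, 0)
  mixed <- evaluate_algorithm(c("s01", "s02", "s05"), truth)
  expect_equal(mixed$sensitivity, 2 / 4)
  expect_equal(mixed$specificity, 5 / 6)
  expect_equal(mixed$ppv, 2 / 3)
  expect_equal(mixed$npv, 5 / 7)
})

test_that("noise-free event emission lets case finding recover truth
           exactly", {
  cfg <- sim_config(n_subjects = 3000, ms_prevalence = 0.05,
                    sensitivity = 1, specificity = 1, seed = 23)
  pop <- simulate_population(cfg)
  algs <- default_algorithms(cfg)
  ev <- simulate_events(pop, algs, cfg)
  for (nm in c("ms", "hypothyroidism", "hashimoto_thyroiditis")) {
    col <- if (nm == "ms") "ms" else paste0("aid_", nm)
    perf <- evaluate_algorithm(
      apply_algorithm(ev, algs[[nm]]),
      tibble::tibble(subject_id = pop$subject_id, status = pop[[col]]))
    expect_equal(perf$sensitivity, 1)
    expect_equal(perf$specificity, 1)
  }
  # cohort prevalence equals simulator truth in the noise-free limit
  cohort <- build_cohort(pop, ev, algs)
  truth_sub <- pop[match(cohort$subject_id, pop$subject_id), ]
  expect_equal(mean(cohort$aid_hypothyroidism),
               mean(truth_sub$aid_hypothyroidism))
})

test_that("cohort assembly restricts non-MS rows to the MS age range and
           rejects duplicate ids", {
  pop <- tibble::tibble(
    subject_id = c("m1", "m2", "n1", "n2", "n3"),
    sex = "female", age_years = c(18L, 80L, 85L, 50L, 17L),
    alive_at_reference = TRUE,
    ms = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    aid_d1 = FALSE, hosp_count_5y = 0L)
  alg_ms <- simple_algorithm("ms", codes = "EX_MS")
  alg_d1 <- simple_algorithm("d1", codes = "EX_D1")
  ev <- dplyr::bind_rows(
    event_row("m1", "copay_exemption", "2015-01-01", "EX_MS"),
    event_row("m2", "copay_exemption", "2015-01-01", "EX_MS"))
  cohort <- build_cohort(pop, ev, list(ms = alg_ms, d1 = alg_d1))
  expect_setequal(cohort$subject_id, c("m1", "m2", "n2"))
  expect_error(
    build_cohort(dplyr::bind_rows(pop, pop[1, ]), ev,
                 list(ms = alg_ms, d1 = alg_d1)),
    "duplicate")
  # no flags anywhere: full-size all-false cohort
  empty_cohort <- build_cohort(pop, ev[0, ], list(ms = alg_ms, d1 = alg_d1))
  expect_equal(nrow(empty_cohort), nrow(pop))
  expect_false(any(empty_cohort$ms))
  expect_false(any(empty_cohort$aid_d1))
})
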