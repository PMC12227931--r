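#' Published reference counts for 14 autoimmune diseases by MS status
#'
#' Per-disease case counts and group summaries from a population-based linkage
#' of administrative health archives covering the Piedmont region of Italy
#' (reference date 31 December 2017): 8,850 persons with multiple sclerosis
#' (pwMS) and 4,265,864 MS-free residents. These counts seed the simulator
#' defaults and serve as worked-example inputs for the prevalence and
#' odds-ratio machinery.
#'
#' Hashimoto thyroiditis counts exclude cases treated with certain thyrotoxic
#' drugs (interferons, alemtuzumab) in the 12 months before diagnosis; the
#' case-finding module expresses that rule as an exclusion window.
#'
#' @return A tibble with one row per disease: `disease` (snake-case
#'   identifier), `label` (display name), `n_ms` / `n_nonms` (case counts in
#'   each population), `pct_women_ms` / `pct_women_nonms`, `mean_age_ms` /
#'   `mean_age_nonms`, and `mean_hosp_ms` / `mean_hosp_nonms` (mean
#'   hospital discharges for any cause in the preceding 5 years).
#' @seealso [ms_population_totals()], [ms_genetic_subset()],
#'   [prevalence_per_1000()]
#' @export
#' @examples
#' ref <- aid_reference_counts()
#' dplyr::mutate(ref, prev_ms = prevalence_per_1000(n_ms, 8850))
aid_reference_counts <- function() {
  tibble::tribble(
    ~disease, ~label, ~n_ms, ~pct_women_ms, ~mean_age_ms, ~mean_hosp_ms,
    ~n_nonms, ~pct_women_nonms, ~mean_age_nonms, ~mean_hosp_nonms,
    "rheumatoid_arthritis", "Rheumatoid arthritis", 54L, 85.2, 53.8, 2.9,
    20793L, 73.6, 63.3, 1.3,
    "celiac_disease", "Celiac disease", 61L, 86.9, 43.6, 2.3,
    12802L, 72.0, 37.0, 0.7,
    "cidp", "Chronic inflammatory demyelinating polyneuropathy", 24L, 66.7,
    55.8, 4.8, 732L, 36.5, 63.5, 3.0,
    "t1dm", "Type 1 diabetes", 77L, 67.5, 49.3, 3.1,
    16692L, 45.0, 53.1, 1.7,
    "hashimoto_thyroiditis", "Hashimoto thyroiditis", 236L, 90.3, 47.2, 1.9,
    54821L, 89.3, 52.9, 0.7,
    "hypothyroidism", "Hypothyroidism", 492L, 90.9, 55.5, 2.2,
    142112L, 83.4, 64.3, 1.1,
    "sle", "Systemic lupus erythematosus", 15L, 100.0, 49.6, 3.5,
    3267L, 87.3, 55.3, 1.5,
    "myasthenia_gravis", "Myasthenia gravis", 10L, 80.0, 52.0, 3.5,
    1619L, 53.9, 65.4, 1.9,
    "psoriatic_arthritis", "Psoriatic arthritis", 26L, 53.9, 53.6, 2.4,
    8560L, 50.6, 58.1, 1.0,
    "sarcoidosis", "Sarcoidosis", 8L, 50.0, 46.4, 4.8,
    1648L, 52.2, 53.7, 1.6,
    "behcet_syndrome", "Behçet syndrome", 10L, 70.0, 39.1, 5.1,
    401L, 56.1, 45.8, 1.7,
    "gbs", "Guillain-Barré syndrome", 14L, 64.3, 52.9, 4.1,
    1446L, 49.3, 59.6, 2.3,
    "sjogren_syndrome", "Sjogren's syndrome", 11L, 100.0, 58.0, 4.0,
    2662L, 93.6, 64.7, 1.4,
    "ankylosing_spondylitis", "Ankylosing spondylitis", 7L, 42.9, 48.9, 3.9,
    1977L, 42.5, 52.4, 1.1
  )
}

#' Population totals for the two comparison groups
#'
#' @return A named list: `n_ms` (8,850 persons with MS), `n_nonms`
#'   (4,265,864 MS-free residents), `n_women_ms` (5,979), `n_men_ms` (2,871).
#' @export
ms_population_totals <- function() {
  list(n_ms = 8850L, n_nonms = 4265864L,
       n_women_ms = 5979L, n_men_ms = 2871L)
}

#' Composition of the genotyped MS subset
#'
#' Bookkeeping for the 637 pwMS with genome-wide genotyping data: comorbidity
#' split, sex split, and the clinical-course breakdown.
#'
#' @return A named list with tibbles `comorbidity` (group, n), `sex`
#'   (sex, n), and `course` (clinical course, n).
#' @export
#' @examples
#' sub <- ms_genetic_subset()
#' sum(sub$course$n)   # total genotyped subjects
ms_genetic_subset <- function() {
  list(
    comorbidity = tibble::tibble(
      group = c("comorbid", "non_comorbid"),
      n = c(65L, 572L)
    ),
    sex = tibble::tibble(
      sex = c("female", "male"),
      n = c(423L, 214L)
    ),
    course = tibble::tibble(
      course = c("clinically_isolated_syndrome", "relapsing_remitting",
                 "progressive_relapsing", "secondary_progressive",
                 "primary_progressive"),
      n = c(19L, 489L, 11L, 84L, 34L)
    )
  )
}

#' Diseases contributing to the cumulative polygenic risk score
#'
#' The nine diseases whose unweighted risk-allele scores are normalized and
#' summed into the cumulative score: MS itself plus eight autoimmune
#' comorbidities. Panel sizes for the built-in synthetic panels span the
#' 23-to-201 variant range of the underlying genome-wide-significant sets.
#'
#' @return A tibble: `disease`, `label`, `n_snps_default`,
#'   `n_hla_default` (synthetic panel sizes).
#' @export
prs_disease_panel_sizes <- function() {
  tibble::tribble(
    ~disease, ~label, ~n_snps_default, ~n_hla_default,
    "ms", "Multiple sclerosis", 201L, 5L,
    "rheumatoid_arthritis", "Rheumatoid arthritis", 100L, 4L,
    "celiac_disease", "Celiac disease", 57L, 3L,
    "t1dm", "Type 1 diabetes", 60L, 4L,
    "hashimoto_thyroiditis", "Hashimoto thyroiditis", 30L, 2L,
    "hypothyroidism", "Hypothyroidism", 40L, 2L,
    "sle", "Systemic lupus erythematosus", 90L, 3L,
    "psoriasis", "Psoriasis", 65L, 3L,
    "ankylosing_spondylitis", "Ankylosing spondylitis", 23L, 2L
  )
}
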