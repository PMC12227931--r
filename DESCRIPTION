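Package: comorbprs
Title: Autoimmune Comorbidity Association and Cumulative Polygenic Risk
    Scores in Multiple Sclerosis Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying autoimmune-disease comorbidity in multiple
    sclerosis from linked administrative health archives, together with a
    cumulative multi-disease polygenic risk score analysis of comorbid versus
    non-comorbid carriers. Provides a synthetic linked-cohort simulator
    (population, archive events, genotype dosages), declarative multi-source
    case-finding algorithms with operating-characteristic evaluation,
    prevalence and covariate-adjusted odds-ratio estimation, a genotype
    quality-control cascade (call rate, minor allele frequency,
    Hardy-Weinberg, imputation quality, principal-component outliers), and
    unweighted normalized polygenic risk scores cumulated across diseases
    with ANCOVA group comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
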