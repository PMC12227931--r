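#' Simulate disease-specific variant and HLA panels
#'
#' Builds synthetic genome-wide-significant panels for the nine score
#' diseases: per disease a set of SNP entries (variant id, risk allele)
#' and a small set of classical HLA alleles. Risk-allele frequencies are
#' drawn uniformly from the configured range; the risk allele is always
#' the alternate allele of the synthetic variant.
#'
#' @param config A [geno_sim_config()].
#' @param seed Optional override of `config$seed`.
#' @return List of two tibbles: `snp` (`disease`, `variant_id`,
#'   `risk_allele`, `chrom`, `pos`, `ref`, `alt`, `freq`) and `hla`
#'   (`disease`, `hla_allele`, `freq`).
#' @export
simulate_panels <- function(config = geno_sim_config(), seed = NULL) {
  stopifnot(inherits(config, "geno_sim_config"))
  set.seed(seed %||% config$seed)
  sizes <- config$panel_sizes
  bases <- c("A", "C", "G", "T")
  snp <- purrr::pmap_dfr(sizes, function(disease, n_snps_default,
                                         n_hla_default, ...) {
    m <- n_snps_default
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    tibble::tibble(
      disease = disease,
      variant_id = sprintf("rs_%s_%03d", disease, seq_len(m)),
      chrom = as.character(sample(1:22, m, replace = TRUE)),
      pos = sample.int(1e8, m),
      ref = ref, alt = alt, risk_allele = alt,
      freq = stats::runif(m, config$freq_range[1], config$freq_range[2])
    )
  })
  hla <- purrr::pmap_dfr(sizes, function(disease, n_snps_default,
                                         n_hla_default, ...) {
    tibble::tibble(
      disease = disease,
      hla_allele = sprintf("HLA_%s_%02d", toupper(disease),
                           seq_len(n_hla_default)),
      freq = stats::runif(n_hla_default, config$freq_range[1],
                          config$freq_range[2])
    )
  })
  list(snp = snp, hla = hla)
}

#' Simulate genotype dosages at panel variants
#'
#' Draws Hardy-Weinberg genotypes per variant at its panel frequency, with
#' the risk-allele frequency shifted on the logit scale by the configured
#' enrichment for subjects flagged as comorbid. Imputation is emulated by
#' adding Gaussian noise scaled by `1 - r2` (clipped to \[0, 2\]) and by
#' masking calls at the configured missingness rate. HLA alleles are
#' simulated the same way as diallelic carrier counts in \{0, 1, 2\}
#' (no dosage noise).
#'
#' @param subjects Tibble with `subject_id` and a logical `comorbid`
#'   column (and optionally `sex`, carried through as `reported_sex`).
#' @param panels Panel list from [simulate_panels()] (elements `snp`,
#'   `hla`); the `hla` element may be absent.
#' @param config A [geno_sim_config()].
#' @param seed Optional override of `config$seed + 1`.
#' @return List with `snp` (a [geno_matrix()] of noisy dosages) and `hla`
#'   (integer matrix subjects x HLA alleles, or `NULL`).
#' @export
simulate_genotypes <- function(subjects, panels, config = geno_sim_config(),
                               seed = NULL) {
  stopifnot(inherits(config, "geno_sim_config"))
  subjects <- tibble::as_tibble(subjects)
  if (!"comorbid" %in% names(subjects)) {
    stop("`subjects` needs a logical `comorbid` column.", call. = FALSE)
  }
  snp_panel <- panels$snp
  if (is.null(snp_panel) || nrow(snp_panel) == 0) {
    stop("empty variant panel.", call. = FALSE)
  }
  set.seed(seed %||% (config$seed + 1L))
  n <- nrow(subjects)
  m <- nrow(snp_panel)
  comorbid <- subjects$comorbid

  p_mat <- matrix(rep(snp_panel$freq, each = n), nrow = n)
  shift <- matrix(0, n, m)
  shift[comorbid, ] <- config$enrichment
  p_mat <- stats::plogis(stats::qlogis(p_mat) + shift)
  g <- matrix(stats::rbinom(n * m, 2L, as.vector(p_mat)), nrow = n)

  r2 <- stats::runif(m, config$r2_range[1], config$r2_range[2])
  noise <- matrix(stats::rnorm(n * m, 0, config$dosage_noise_sd), nrow = n) *
    rep(1 - r2, each = n)
  ds <- pmin(pmax(g + noise, 0), 2)
  if (config$missing_rate > 0) {
    ds[stats::runif(n * m) < config$missing_rate] <- NA_real_
  }
  variants <- tibble::tibble(
    variant_id = snp_panel$variant_id, chrom = snp_panel$chrom,
    pos = snp_panel$pos, ref = snp_panel$ref, alt = snp_panel$alt,
    r2 = r2, is_hla = FALSE
  )
  subj_meta <- tibble::tibble(subject_id = subjects$subject_id)
  if ("sex" %in% names(subjects)) subj_meta$reported_sex <- subjects$sex
  snp_geno <- geno_matrix(ds, variants, subj_meta)

  hla <- NULL
  if (!is.null(panels$hla) && nrow(panels$hla) > 0) {
    hp <- panels$hla
    ph <- matrix(rep(hp$freq, each = n), nrow = n)
    sh <- matrix(0, n, nrow(hp))
    sh[comorbid, ] <- config$enrichment
    ph <- stats::plogis(stats::qlogis(ph) + sh)
    hla <- matrix(stats::rbinom(n * nrow(hp), 2L, as.vector(ph)), nrow = n,
                  dimnames = list(subjects$subject_id, hp$hla_allele))
  }
  list(snp = snp_geno, hla = hla)
}
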