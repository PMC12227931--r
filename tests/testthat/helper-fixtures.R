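# shared fixture builders: everything is generated in code at test time

fixture_window <- as.Date(c("2013-01-01", "2017-12-31"))

# minimal one-stream algorithm
simple_algorithm <- function(disease = "hypothyroidism",
                             stream = "copay_exemption",
                             codes = "EX_HYPOTHYROIDISM",
                             min_count = 1L, rule = "any",
                             exclusion = NULL) {
  streams <- stats::setNames(list(list(codes = codes,
                                       min_count = min_count)), stream)
  case_algorithm(disease, streams, rule = rule, window = fixture_window,
                 exclusion = exclusion)
}

event_row <- function(subject_id, stream, date, code) {
  tibble::tibble(subject_id = subject_id, stream = stream,
                 date = as.Date(date), code = code)
}

# small geno_matrix from a dosage matrix; risk allele is always alt
make_geno <- function(dosage, r2 = NULL, chrom = NULL, sex = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  variants <- tibble::tibble(
    variant_id = sprintf("v%03d", seq_len(m)),
    chrom = chrom %||% rep("1", m),
    pos = seq_len(m) * 1000L,
    ref = rep("A", m), alt = rep("G", m),
    r2 = r2 %||% rep(1, m), is_hla = FALSE
  )
  subjects <- tibble::tibble(subject_id = sprintf("s%03d", seq_len(nrow(dosage))))
  if (!is.null(sex)) subjects$reported_sex <- sex
  geno_matrix(dosage, variants, subjects)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hardy-Weinberg genotype draw at frequency p
hw_genotypes <- function(n, p) {
  stats::rbinom(n, 2L, p)
}

# a clean equilibrium dosage matrix (no planted defects)
clean_geno <- function(n = 80, m = 60, seed = 1) {
  set.seed(seed)
  p <- stats::runif(m, 0.2, 0.8)
  g <- vapply(p, function(pp) hw_genotypes(n, pp), numeric(n))
  make_geno(g)
}

# PRS-style profile table with a planted (possibly zero) group difference
simulate_profiles <- function(n_comorbid = 65, n_noncomorbid = 572,
                              delta_sd = 0, resid_sd = 0.13, seed = 1) {
  set.seed(seed)
  n <- n_comorbid + n_noncomorbid
  comorbid <- rep(c(TRUE, FALSE), c(n_comorbid, n_noncomorbid))
  age <- stats::rnorm(n, 52, 11.5)
  sex <- sample(c("female", "male"), n, TRUE, prob = c(0.66, 0.34))
  pcs <- matrix(stats::rnorm(3 * n, 0, 0.05), ncol = 3)
  y <- 4.5 + delta_sd * resid_sd * comorbid + 0.001 * (age - 52) +
    0.2 * pcs[, 1] + stats::rnorm(n, 0, resid_sd)
  tibble::tibble(
    subject_id = sprintf("p%04d", seq_len(n)),
    prs_comorb_hla = y, prs_comorb = y,
    comorbid = comorbid, age = age, sex = sex,
    PC1 = pcs[, 1], PC2 = pcs[, 2], PC3 = pcs[, 3]
  )
}
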