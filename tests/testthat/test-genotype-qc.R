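test_that("best-guess conversion rounds to the nearest genotype with the
           heterozygote tie rule", {
  expect_equal(dosage_to_best_guess(c(0, 0.2, 1.2, 1.9, 2)),
               c(0L, 0L, 1L, 2L, 2L))
  expect_equal(dosage_to_best_guess(c(0.5, 1.5)), c(1L, 1L))
  expect_true(is.na(dosage_to_best_guess(NA_real_)))
  set.seed(2)
  d <- stats::runif(500, 0, 2)
  expect_true(all(abs(d - dosage_to_best_guess(d)) <= 0.5))
})

test_that("Hardy-Weinberg chi-square matches closed forms and symmetry", {
  expect_equal(hwe_test(25, 50, 25)$chi2, 0)
  expect_equal(hwe_test(25, 50, 25)$p_value, 1)
  het_def <- hwe_test(50, 0, 50)
  expect_equal(het_def$chi2, 100)
  expect_equal(het_def$p_value,
               stats::pchisq(100, df = 1, lower.tail = FALSE))
  # label swap symmetry
  expect_equal(hwe_test(60, 25, 15)$p_value, hwe_test(15, 25, 60)$p_value)
  # monomorphic variants cannot deviate
  expect_equal(hwe_test(100, 0, 0)$p_value, 1)
  expect_error(hwe_test(0, 0, 0), "positive")
})

test_that("HWE chi-square against brute-force expected counts on random
           draws", {
  set.seed(5)
  for (r in 1:25) {
    counts <- as.vector(stats::rmultinom(1, 200, stats::runif(3)))
    n <- sum(counts)
    p <- (2 * counts[1] + counts[2]) / (2 * n)
    expected <- c(p^2, 2 * p * (1 - p), (1 - p)^2) * n
    chi_oracle <- sum((counts - expected)^2 / expected)
    expect_equal(hwe_test(counts[1], counts[2], counts[3])$chi2,
                 chi_oracle, tolerance = 1e-12)
  }
})

test_that("HWE p-values are uniform under simulated equilibrium", {
  set.seed(11)
  n_subj <- 300; n_var <- 5000
  p <- stats::runif(n_var, 0.1, 0.9)
  pvals <- vapply(p, function(pp) {
    g <- hw_genotypes(n_subj, pp)
    hwe_test(sum(g == 2), sum(g == 1), sum(g == 0))$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("variant QC removes the planted defects and nothing else", {
  g <- clean_geno(n = 100, m = 40, seed = 3)
  d <- g$dosage
  # plant: monomorphic variant, HWE-violating variant (60, 0, 40)
  d <- cbind(d, mono = rep(0, 100),
             hwe_bad = rep(c(2, 0), c(60, 40)))
  planted <- make_geno(d)
  out <- snp_qc(planted)
  kept <- out$variants$variant_id
  expect_equal(ncol(out$dosage), 40)
  expect_false(sprintf("v%03d", 41) %in% kept)  # monomorphic
  expect_false(sprintf("v%03d", 42) %in% kept)  # HWE violation
  rep_tab <- qc_report(out)
  expect_equal(sum(rep_tab$removed), 2)
  # the HWE defect really is far beyond the 1e-6 threshold
  expect_lt(hwe_test(60, 0, 40)$p_value, 1e-20)
})

test_that("post-imputation filter applies a strict below-threshold rule", {
  g <- clean_geno(n = 60, m = 3, seed = 4)
  g$variants$r2 <- c(0.6, 0.59, 1)
  out <- post_imputation_filter(g)
  expect_setequal(out$variants$variant_id, c("v001", "v003"))
  all_good <- clean_geno(n = 60, m = 5, seed = 5)
  all_good$variants$r2 <- rep(1, 5)
  expect_equal(ncol(post_imputation_filter(all_good)$dosage), 5)
})

test_that("sample QC removes a planted duplicate (keeping the first) and a
           planted PC outlier, and nothing else", {
  g <- clean_geno(n = 50, m = 60, seed = 6)
  d <- g$dosage
  d[50, ] <- d[1, ]  # duplicate pair (1, 50)
  dup <- make_geno(d)
  out <- sample_qc(dup, pcs = matrix(0, 49, 3))
  expect_false("s050" %in% out$subjects$subject_id)
  expect_true("s001" %in% out$subjects$subject_id)
  expect_equal(nrow(out$dosage), 49)

  # PC outlier: subject planted at 5 SD on PC2 of supplied scores
  set.seed(99)
  pcs <- matrix(stats::rnorm(50 * 3), ncol = 3)
  pcs[, 2] <- pcs[, 2] / stats::sd(pcs[, 2])
  pcs[17, 2] <- mean(pcs[-17, 2]) + 5 * stats::sd(pcs[-17, 2])
  clean <- clean_geno(n = 50, m = 60, seed = 8)
  out2 <- sample_qc(clean, pcs = pcs)
  expect_false("s017" %in% out2$subjects$subject_id)
  expect_equal(nrow(out2$dosage), 49)
})

test_that("a homogeneous clean matrix passes sample QC untouched", {
  g <- clean_geno(n = 60, m = 80, seed = 16)
  out <- sample_qc(g)
  expect_equal(nrow(out$dosage), 60)
  expect_true(all(qc_report(out)$removed == 0))
  expect_error(sample_qc(clean_geno(n = 2, m = 10)), "3 subjects")
})

test_that("sex discrepancies are caught from X-chromosome heterozygosity", {
  set.seed(10)
  n <- 30
  auto <- vapply(stats::runif(20, 0.3, 0.7),
                 function(p) hw_genotypes(n, p), numeric(n))
  sex <- rep(c("male", "female"), c(15, 15))
  xg <- matrix(0, n, 10)
  xg[16:30, ] <- vapply(1:10, function(j) stats::rbinom(15, 1, 0.5),
                        numeric(15))  # females heterozygous on X
  xg[1:15, ] <- 2 * matrix(stats::rbinom(150, 1, 0.5), 15)  # males never
  xg[1, ] <- 1  # reported male with female-like X heterozygosity
  g <- make_geno(cbind(auto, xg), chrom = rep(c("1", "X"), c(20, 10)),
                 sex = sex)
  out <- sample_qc(g, pcs = matrix(0, n - 1, 3))
  # subject 1 is removed by the sex check (after no other filter fires)
  expect_false("s001" %in% out$subjects$subject_id)
  rep_tab <- qc_report(out)
  expect_equal(rep_tab$removed[rep_tab$filter == "sex_discrepancy"], 1)
})

test_that("the full QC cascade is idempotent on its own output", {
  g <- clean_geno(n = 100, m = 80, seed = 12)
  once <- qc_cascade(g)
  twice <- qc_cascade(once)
  expect_equal(dim(twice$dosage), dim(once$dosage))
  expect_true(all(qc_report(twice)$removed[-seq_len(nrow(qc_report(once)))]
                  == 0))
  # bookkeeping: removals reconcile with dimensions
  rep_tab <- qc_report(once)
  subj_removed <- sum(rep_tab$removed[rep_tab$axis == "subject"])
  var_removed <- sum(rep_tab$removed[rep_tab$axis == "variant"])
  expect_equal(nrow(once$dosage), 100 - subj_removed)
  expect_equal(ncol(once$dosage), 80 - var_removed)
})

test_that("principal components separate planted subpopulations and obey
           eigenvector properties", {
  set.seed(13)
  n <- 60; m <- 120
  p1 <- stats::runif(m, 0.2, 0.8)
  drift <- pmin(pmax(p1 + stats::rnorm(m, 0, 0.18), 0.02), 0.98)
  d <- rbind(
    vapply(p1, function(p) hw_genotypes(n / 2, p), numeric(n / 2)),
    vapply(drift, function(p) hw_genotypes(n / 2, p), numeric(n / 2)))
  g <- make_geno(d)
  pc <- compute_pcs(g, 4)
  grp <- rep(c(1, 2), each = n / 2)
  sep <- abs(mean(pc$scores$PC1[grp == 1]) - mean(pc$scores$PC1[grp == 2]))
  within_sd <- mean(c(stats::sd(pc$scores$PC1[grp == 1]),
                      stats::sd(pc$scores$PC1[grp == 2])))
  expect_gt(sep, 3 * within_sd)
  # orthogonality of score vectors
  s <- as.matrix(pc$scores[, -1])
  cross <- crossprod(s)
  expect_lt(max(abs(cross[upper.tri(cross)])) /
              max(diag(cross)), 1e-8)
  expect_equal(sum(pc$explained_variance <= 1), 4)
  expect_error(compute_pcs(g, 200), "exceeds")
})

test_that("identical subjects give all-zero principal components", {
  d <- matrix(rep(c(0, 1, 2), length.out = 20), nrow = 5, ncol = 20,
              byrow = TRUE)
  g <- make_geno(d)
  pc <- compute_pcs(g, 2)
  expect_equal(max(abs(as.matrix(pc$scores[, -1]))), 0, tolerance = 1e-10)
})

test_that("QC reports serialise to JSON", {
  g <- snp_qc(clean_geno(n = 40, m = 20, seed = 14))
  path <- withr::local_tempfile(fileext = ".json")
  write_qc_report(g, path)
  back <- jsonlite::read_json(path)
  expect_equal(length(back), nrow(qc_report(g)))
  expect_equal(back[[1]]$filter, "variant_call_rate")
})
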