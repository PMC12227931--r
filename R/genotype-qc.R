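#' Convert imputed dosages to best-guess genotypes
#'
#' Nearest integer in \{0, 1, 2\}; exact ties at 0.5 and 1.5 resolve
#' toward the heterozygote, so the rule is deterministic. Missing stays
#' missing. The absolute conversion error is at most 0.5.
#'
#' @param dosage Numeric vector or matrix of dosages in \[0, 2\].
#' @return Integer best-guess genotypes with the same shape.
#' @export
#' @examples
#' dosage_to_best_guess(c(0.2, 0.5, 1.2, 1.5, 1.9))  # 0 1 1 1 2
dosage_to_best_guess <- function(dosage) {
  out <- ifelse(dosage < 0.5, 0L, ifelse(dosage <= 1.5, 1L, 2L))
  storage.mode(out) <- "integer"
  out
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness of fit of observed genotype counts
#' against the expected counts `p^2 N, 2pq N, q^2 N` at the observed
#' allele frequency. Monomorphic variants cannot deviate and return
#' p = 1. Vectorised over the three arguments.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts.
#' @return Tibble with `chi2`, `p_value` (and the inputs).
#' @export
#' @examples
#' hwe_test(25, 50, 25)   # perfect equilibrium, p = 1
#' hwe_test(50, 0, 50)    # complete heterozygote deficit
hwe_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (any(n == 0)) stop("total genotype count must be positive.",
                        call. = FALSE)
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  exp_AA <- p^2 * n
  exp_Aa <- 2 * p * q * n
  exp_aa <- q^2 * n
  chi2 <- ifelse(p == 0 | q == 0, 0,
                 (n_AA - exp_AA)^2 / exp_AA +
                 (n_Aa - exp_Aa)^2 / exp_Aa +
                 (n_aa - exp_aa)^2 / exp_aa)
  tibble::tibble(n_AA = n_AA, n_Aa = n_Aa, n_aa = n_aa, chi2 = chi2,
                 p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

new_qc_entry <- function(filter, axis, tested, removed, threshold) {
  tibble::tibble(filter = filter, axis = axis, tested = as.integer(tested),
                 removed = as.integer(removed),
                 threshold = as.character(threshold))
}

append_report <- function(x, entries) {
  attr(x, "qc_report") <- dplyr::bind_rows(attr(x, "qc_report"), entries)
  x
}

#' Quality-control report of a filtered genotype matrix
#'
#' @param x A [geno_matrix()] returned by one of the QC steps.
#' @return Tibble with one row per applied filter: `filter`, `axis`
#'   (`"subject"` or `"variant"`), `tested`, `removed`, `threshold`.
#' @export
qc_report <- function(x) {
  attr(x, "qc_report") %||%
    tibble::tibble(filter = character(), axis = character(),
                   tested = integer(), removed = integer(),
                   threshold = character())
}

#' Write a QC report as JSON
#'
#' @param x A filtered [geno_matrix()] (or a report tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(x, path) {
  rep <- if (is.data.frame(x)) x else qc_report(x)
  jsonlite::write_json(rep, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

variant_stats <- function(x) {
  bg <- dosage_to_best_guess(x$dosage)
  call_rate <- colMeans(!is.na(bg))
  af <- colMeans(bg, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  list(bg = bg, call_rate = call_rate, af = af, maf = maf)
}

#' Variant-level quality control
#'
#' Drops variants failing, in order: genotype call rate, minor allele
#' frequency, and Hardy-Weinberg equilibrium — the conventional
#' pre-imputation SNP filters (call rate >= 90%, MAF >= 0.01,
#' HWE p >= 1e-6). All statistics are computed on best-guess genotypes,
#' each filter on the survivors of the previous.
#'
#' @param x A [geno_matrix()].
#' @param call_rate_min Minimum variant call rate kept (default 0.90).
#' @param maf_min Minimum minor allele frequency kept (default 0.01).
#' @param hwe_p_min Minimum HWE p-value kept (default 1e-6).
#' @return Filtered `geno_matrix` with the report appended (see
#'   [qc_report()]).
#' @export
snp_qc <- function(x, call_rate_min = 0.90, maf_min = 0.01,
                   hwe_p_min = 1e-6) {
  stopifnot(inherits(x, "geno_matrix"))
  rep0 <- qc_report(x)

  st <- variant_stats(x)
  keep <- st$call_rate >= call_rate_min
  e1 <- new_qc_entry("variant_call_rate", "variant", ncol(x$dosage),
                     sum(!keep), sprintf(">= %g", call_rate_min))
  x <- geno_subset(x, variants = keep)

  st <- variant_stats(x)
  keep <- st$maf >= maf_min
  e2 <- new_qc_entry("minor_allele_frequency", "variant", ncol(x$dosage),
                     sum(!keep), sprintf(">= %g", maf_min))
  x <- geno_subset(x, variants = keep)

  bg <- dosage_to_best_guess(x$dosage)
  n_aa <- colSums(bg == 0, na.rm = TRUE)
  n_het <- colSums(bg == 1, na.rm = TRUE)
  n_AA <- colSums(bg == 2, na.rm = TRUE)
  hwe_p <- hwe_test(n_AA, n_het, n_aa)$p_value
  keep <- hwe_p >= hwe_p_min
  e3 <- new_qc_entry("hardy_weinberg", "variant", ncol(x$dosage),
                     sum(!keep), sprintf("p >= %g", hwe_p_min))
  x <- geno_subset(x, variants = keep)

  attr(x, "qc_report") <- NULL
  append_report(x, dplyr::bind_rows(rep0, e1, e2, e3))
}

#' Post-imputation variant filter
#'
#' Keeps variants with imputation quality `r2 >= r2_min` (the threshold is
#' a strict "below fails": r2 of exactly 0.6 is retained) and best-guess
#' minor allele frequency `>= maf_min`.
#'
#' @param x A [geno_matrix()] with an `r2` column in its variant metadata.
#' @param r2_min Minimum imputation quality kept (default 0.6).
#' @param maf_min Minimum MAF kept (default 0.001).
#' @return Filtered `geno_matrix` with the report appended.
#' @export
post_imputation_filter <- function(x, r2_min = 0.6, maf_min = 0.001) {
  stopifnot(inherits(x, "geno_matrix"))
  rep0 <- qc_report(x)
  keep <- !is.na(x$variants$r2) & x$variants$r2 >= r2_min
  e1 <- new_qc_entry("imputation_r2", "variant", ncol(x$dosage),
                     sum(!keep), sprintf(">= %g", r2_min))
  x <- geno_subset(x, variants = keep)
  st <- variant_stats(x)
  keep <- st$maf >= maf_min
  e2 <- new_qc_entry("post_imputation_maf", "variant", ncol(x$dosage),
                     sum(!keep), sprintf(">= %g", maf_min))
  x <- geno_subset(x, variants = keep)
  attr(x, "qc_report") <- NULL
  append_report(x, dplyr::bind_rows(rep0, e1, e2))
}

#' Sample-level quality control
#'
#' Applies, in order, each filter recomputed on the survivors of the
#' previous: (1) duplicate removal — pairs whose best-guess genotypes are
#' identical at more than `dup_threshold` of jointly called variants
#' (a pairwise-identity proxy for genetic duplicates; the first of each
#' pair is kept); (2) heterozygosity-rate outliers beyond `het_sd`
#' standard deviations from the mean; (3) sample call-rate failures;
#' (4) sex discrepancies, when X-chromosome variants and reported sex are
#' available (X heterozygosity > 0.2 for reported males, < 0.02 for
#' reported females); (5) principal-component outliers beyond `pc_sd`
#' standard deviations on any of the first `k_pcs` components.
#'
#' @param x A [geno_matrix()].
#' @param pcs Optional matrix/data frame of precomputed PC scores (rows
#'   aligned with subjects, columns PCs). When `NULL`, PCs are computed on
#'   the survivors of the earlier filters via [compute_pcs()].
#' @param dup_threshold Identity proportion above which a pair counts as
#'   duplicate (default 0.95).
#' @param het_sd,pc_sd Outlier cutoffs in standard deviations (default 3).
#' @param call_rate_min Minimum sample call rate kept (default 0.95).
#' @param k_pcs Number of leading PCs screened (default 3).
#' @return Filtered `geno_matrix` with the report appended.
#' @export
sample_qc <- function(x, pcs = NULL, dup_threshold = 0.95, het_sd = 3,
                      call_rate_min = 0.95, pc_sd = 3, k_pcs = 3) {
  stopifnot(inherits(x, "geno_matrix"))
  if (nrow(x$dosage) < 3) {
    stop("sample QC needs at least 3 subjects.", call. = FALSE)
  }
  rep0 <- qc_report(x)

  bg <- dosage_to_best_guess(x$dosage)
  n <- nrow(bg)
  drop_dup <- rep(FALSE, n)
  if (n >= 2) {
    # matches over jointly-called variants via indicator cross-products
    obs <- !is.na(bg)
    joint <- obs %*% t(obs)
    matches <- matrix(0, n, n)
    for (g in 0:2) {
      ig <- (bg == g) & obs
      ig[is.na(ig)] <- FALSE
      matches <- matches + ig %*% t(ig)
    }
    ident <- matches / pmax(joint, 1)
    ident[joint == 0] <- 0
    for (i in seq_len(n - 1)) {
      if (drop_dup[i]) next
      js <- which(ident[i, ] > dup_threshold)
      js <- js[js > i]
      drop_dup[js] <- TRUE
    }
  }
  e1 <- new_qc_entry("duplicates", "subject", n, sum(drop_dup),
                     sprintf("identity > %g", dup_threshold))
  x <- geno_subset(x, subjects = !drop_dup)

  bg <- dosage_to_best_guess(x$dosage)
  het <- rowMeans(bg == 1, na.rm = TRUE)
  mu <- mean(het); sdv <- stats::sd(het)
  keep <- if (sdv == 0) rep(TRUE, length(het))
          else abs(het - mu) <= het_sd * sdv
  e2 <- new_qc_entry("heterozygosity", "subject", nrow(x$dosage),
                     sum(!keep), sprintf("|rate - mean| <= %g SD", het_sd))
  x <- geno_subset(x, subjects = keep)

  cr <- rowMeans(!is.na(x$dosage))
  keep <- cr >= call_rate_min
  e3 <- new_qc_entry("sample_call_rate", "subject", nrow(x$dosage),
                     sum(!keep), sprintf(">= %g", call_rate_min))
  x <- geno_subset(x, subjects = keep)

  e4 <- NULL
  x_variants <- x$variants$chrom %in% c("X", "23", "chrX")
  if (any(x_variants) && "reported_sex" %in% names(x$subjects)) {
    bg <- dosage_to_best_guess(x$dosage[, x_variants, drop = FALSE])
    xhet <- rowMeans(bg == 1, na.rm = TRUE)
    male <- x$subjects$reported_sex == "male"
    mismatch <- (male & xhet > 0.2) | (!male & xhet < 0.02)
    mismatch[is.na(mismatch)] <- FALSE
    e4 <- new_qc_entry("sex_discrepancy", "subject", nrow(x$dosage),
                       sum(mismatch), "X-het 0.02/0.2 heuristic")
    x <- geno_subset(x, subjects = !mismatch)
  }

  if (is.null(pcs)) {
    k <- min(k_pcs, nrow(x$dosage) - 1, ncol(x$dosage))
    scores <- compute_pcs(x, k)$scores
    pc_mat <- as.matrix(scores[, -1, drop = FALSE])
  } else {
    pc_mat <- as.matrix(pcs)
    if (nrow(pc_mat) != nrow(x$dosage)) {
      stop("`pcs` rows must align with the surviving subjects.",
           call. = FALSE)
    }
    pc_mat <- pc_mat[, seq_len(min(k_pcs, ncol(pc_mat))), drop = FALSE]
  }
  z <- scale(pc_mat)
  out_pc <- apply(abs(z) > pc_sd, 1, any)
  out_pc[is.na(out_pc)] <- FALSE
  e5 <- new_qc_entry("pc_outlier", "subject", nrow(x$dosage),
                     sum(out_pc), sprintf("> %g SD on first %d PCs",
                                          pc_sd, ncol(pc_mat)))
  x <- geno_subset(x, subjects = !out_pc)

  attr(x, "qc_report") <- NULL
  append_report(x, dplyr::bind_rows(rep0, e1, e2, e3, e4, e5))
}

#' Principal components of a genotype matrix
#'
#' Centers each variant at twice its allele frequency and scales by
#' `sqrt(2 p (1 - p))` — the conventional ancestry-PCA standardisation —
#' then takes the singular value decomposition of the standardized
#' subjects-by-variants matrix. Missing calls are mean-imputed before
#' standardisation; zero-variance variants are dropped. Each component's
#' sign is fixed so that its largest-magnitude variant loading is
#' positive.
#'
#' @param x A [geno_matrix()].
#' @param k Number of leading components (must not exceed either
#'   dimension).
#' @return List: `scores` (tibble `subject_id`, `PC1..PCk`),
#'   `explained_variance` (proportion per component), `loadings`
#'   (variants x k matrix).
#' @export
compute_pcs <- function(x, k = 3) {
  stopifnot(inherits(x, "geno_matrix"))
  d <- x$dosage
  if (k > min(dim(d))) {
    stop("`k` exceeds the matrix dimensions.", call. = FALSE)
  }
  cm <- colMeans(d, na.rm = TRUE)
  miss <- is.na(d)
  if (any(miss)) d[miss] <- rep(cm, each = nrow(d))[miss]
  p <- cm / 2
  sc <- sqrt(2 * p * (1 - p))
  keep <- sc > 0
  if (!any(keep)) {
    # every variant is constant: nothing to decompose, all scores are zero
    scores <- matrix(0, nrow(d), k, dimnames = list(NULL, paste0("PC", 1:k)))
    return(list(
      scores = dplyr::bind_cols(
        tibble::tibble(subject_id = x$subjects$subject_id),
        tibble::as_tibble(scores)
      ),
      explained_variance = rep(0, k),
      loadings = matrix(0, 0, k)
    ))
  }
  z <- sweep(d[, keep, drop = FALSE], 2, 2 * p[keep], "-")
  z <- sweep(z, 2, sc[keep], "/")
  sv <- svd(z, nu = k, nv = k)
  signs <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u %*% diag(sv$d[seq_len(k)], k, k), 2, signs, "*")
  loadings <- sweep(sv$v, 2, signs, "*")
  colnames(scores) <- paste0("PC", seq_len(k))
  list(
    scores = dplyr::bind_cols(
      tibble::tibble(subject_id = x$subjects$subject_id),
      tibble::as_tibble(scores)
    ),
    explained_variance = sv$d[seq_len(k)]^2 / sum(sv$d^2),
    loadings = loadings
  )
}

#' Run the full sample + variant QC cascade
#'
#' Convenience wrapper: [sample_qc()] then [snp_qc()] then
#' [post_imputation_filter()], reports concatenated in application order.
#'
#' @param x A [geno_matrix()].
#' @param sample_qc_args,snp_qc_args,post_imputation_args Named lists of
#'   arguments forwarded to the corresponding step.
#' @return Filtered `geno_matrix` with the combined report.
#' @export
qc_cascade <- function(x, sample_qc_args = list(), snp_qc_args = list(),
                       post_imputation_args = list()) {
  x <- do.call(sample_qc, c(list(x), sample_qc_args))
  x <- do.call(snp_qc, c(list(x), snp_qc_args))
  do.call(post_imputation_filter, c(list(x), post_imputation_args))
}
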