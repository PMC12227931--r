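#' Per-subject unweighted raw risk-allele score for one disease
#'
#' Counts risk alleles over a disease's variant panel from best-guess
#' genotypes: for each panel variant the contribution is the best-guess
#' alternate-allele count when the risk allele is the alternate allele,
#' and two minus that count when it is the reference allele. Post-QC data
#' are expected complete at panel variants; if some are missing the score
#' is rescaled by `n_panel / n_observed` and flagged (strict mode errors
#' instead, naming the variants).
#'
#' @param genotypes A [geno_matrix()] of post-QC dosages.
#' @param panel Tibble with columns `variant_id` and `risk_allele`
#'   restricted to one disease.
#' @param missing_rule `"rescale"` (default) or `"strict"`.
#' @return Tibble: `subject_id`, `raw_score`, `n_loci` (panel size),
#'   `n_observed`, `rescaled` (logical). With complete data `raw_score`
#'   is an integer in `[0, 2 * n_loci]`.
#' @export
disease_raw_score <- function(genotypes, panel,
                              missing_rule = c("rescale", "strict")) {
  missing_rule <- match.arg(missing_rule)
  stopifnot(inherits(genotypes, "geno_matrix"))
  absent <- setdiff(panel$variant_id, genotypes$variants$variant_id)
  if (length(absent) > 0 && missing_rule == "strict") {
    stop("panel variants absent from genotype data: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  present <- panel[panel$variant_id %in% genotypes$variants$variant_id, ]
  vi <- match(present$variant_id, genotypes$variants$variant_id)
  bg <- dosage_to_best_guess(genotypes$dosage[, vi, drop = FALSE])
  risk_is_alt <- present$risk_allele == genotypes$variants$alt[vi]
  counts <- bg
  if (any(!risk_is_alt)) {
    counts[, !risk_is_alt] <- 2L - counts[, !risk_is_alt, drop = FALSE]
  }
  if (missing_rule == "strict" && anyNA(counts)) {
    bad <- present$variant_id[colSums(is.na(counts)) > 0]
    stop("missing genotype calls at panel variants: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n_obs <- unname(rowSums(!is.na(counts))) + 0L
  raw <- unname(rowSums(counts, na.rm = TRUE))
  n_panel <- nrow(panel)
  rescaled <- n_obs < n_panel
  raw <- ifelse(n_obs > 0, raw * n_panel / n_obs, NA_real_)
  tibble::tibble(subject_id = genotypes$subjects$subject_id,
                 raw_score = raw, n_loci = n_panel,
                 n_observed = n_obs, rescaled = rescaled)
}

#' Normalize a raw score by its maximum achievable value
#'
#' @param raw Raw risk-allele count(s).
#' @param n_loci Number of loci in the panel; the maximum achievable score
#'   is `2 * n_loci`.
#' @return `raw / (2 * n_loci)`, in \[0, 1\].
#' @export
#' @examples
#' normalize_score(46, 23)    # all-risk subject on a 23-variant panel -> 1
#' normalize_score(201, 201)  # half the maximum -> 0.5
normalize_score <- function(raw, n_loci) {
  if (any(n_loci <= 0)) stop("`n_loci` must be positive.", call. = FALSE)
  out <- raw / (2 * n_loci)
  if (any(out < -1e-12 | out > 1 + 1e-12, na.rm = TRUE)) {
    stop("raw score outside [0, 2 * n_loci].", call. = FALSE)
  }
  pmin(pmax(out, 0), 1)
}

#' Cumulative multi-disease polygenic risk score
#'
#' Sums normalized per-disease scores; with nine diseases the result lies
#' in \[0, 9\] and is invariant to disease ordering.
#'
#' @param norm_scores Numeric matrix or data frame, subjects in rows and
#'   one column of normalized scores per disease.
#' @return Numeric vector of cumulative scores.
#' @export
cumulative_prs <- function(norm_scores) {
  m <- as.matrix(norm_scores)
  if (any(m < -1e-12 | m > 1 + 1e-12, na.rm = TRUE)) {
    stop("normalized scores must lie in [0, 1].", call. = FALSE)
  }
  rowSums(m)
}

#' Per-subject PRS profile across the nine score diseases
#'
#' Computes, for each disease panel, the unweighted raw risk-allele score
#' and its normalized value, the cumulative score over all diseases
#' (`prs_comorb`), and — when HLA panels and allele counts are supplied —
#' the HLA-augmented cumulative score (`prs_comorb_hla`). HLA integration
#' appends each disease's HLA carrier counts to its raw score and
#' enlarges the normalizing maximum to `2 * (n_snps + n_hla)` before the
#' nine normalized scores are resummed.
#'
#' @param genotypes A [geno_matrix()] of post-QC dosages.
#' @param panels SNP panel tibble: `disease`, `variant_id`, `risk_allele`.
#' @param hla_counts Optional integer matrix (subjects x HLA alleles) of
#'   carrier counts in \{0, 1, 2\}, rows aligned with `genotypes`.
#' @param hla_panels Optional tibble `disease`, `hla_allele`.
#' @param missing_rule Passed to [disease_raw_score()].
#' @return Tibble with one row per subject: `subject_id`,
#'   `norm_<disease>` columns, `prs_comorb`, and `prs_comorb_hla` (equal
#'   to `prs_comorb` when no HLA input is given).
#' @export
compute_prs <- function(genotypes, panels, hla_counts = NULL,
                        hla_panels = NULL,
                        missing_rule = c("rescale", "strict")) {
  missing_rule <- match.arg(missing_rule)
  diseases <- unique(panels$disease)
  if (!is.null(hla_counts)) {
    if (!is.null(rownames(hla_counts))) {
      # align by subject id so QC-filtered genotype sets still match
      idx <- match(genotypes$subjects$subject_id, rownames(hla_counts))
      if (anyNA(idx)) {
        stop("`hla_counts` lacks rows for some genotype subjects.",
             call. = FALSE)
      }
      hla_counts <- hla_counts[idx, , drop = FALSE]
    } else if (nrow(hla_counts) != nrow(genotypes$dosage)) {
      stop("`hla_counts` rows must align with the genotype subjects.",
           call. = FALSE)
    }
    if (any(!hla_counts %in% 0:2)) {
      stop("HLA allele counts must be 0, 1 or 2.", call. = FALSE)
    }
  }
  out <- tibble::tibble(subject_id = genotypes$subjects$subject_id)
  norm_cols <- character(0)
  hla_norm <- matrix(0, nrow(out), length(diseases),
                     dimnames = list(NULL, diseases))
  for (d in diseases) {
    pan <- panels[panels$disease == d, ]
    sc <- disease_raw_score(genotypes, pan, missing_rule)
    nc <- paste0("norm_", d)
    out[[nc]] <- normalize_score(sc$raw_score, sc$n_loci[1])
    norm_cols <- c(norm_cols, nc)

    hp <- if (!is.null(hla_panels)) {
      hla_panels[hla_panels$disease == d, ]
    }
    if (!is.null(hp) && nrow(hp) > 0) {
      if (is.null(hla_counts)) {
        stop("`hla_panels` given without `hla_counts`.", call. = FALSE)
      }
      missing_alleles <- setdiff(hp$hla_allele, colnames(hla_counts))
      if (length(missing_alleles) > 0) {
        stop("HLA alleles absent from `hla_counts`: ",
             paste(missing_alleles, collapse = ", "), call. = FALSE)
      }
      burden <- rowSums(hla_counts[, hp$hla_allele, drop = FALSE])
      hla_norm[, d] <- normalize_score(sc$raw_score + burden,
                                       sc$n_loci[1] + nrow(hp))
    } else {
      hla_norm[, d] <- out[[nc]]
    }
  }
  out$prs_comorb <- cumulative_prs(out[norm_cols])
  out$prs_comorb_hla <- cumulative_prs(hla_norm)
  out
}

#' HLA-augmented cumulative score for explicit inputs
#'
#' Thin wrapper over [compute_prs()] returning only the HLA-augmented
#' cumulative score.
#'
#' @inheritParams compute_prs
#' @return Numeric vector: `prs_comorb_hla` per subject.
#' @export
hla_augmented_score <- function(genotypes, hla_counts, panels, hla_panels) {
  compute_prs(genotypes, panels, hla_counts, hla_panels)$prs_comorb_hla
}
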