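#' Genotype dosage container
#'
#' A light container for imputed genotype dosages: a subjects-by-variants
#' numeric matrix plus tibble metadata for both axes. Dosages lie in
#' \[0, 2\] (expected count of the alternate allele); `NA` marks missing
#' calls, which are only expected before quality control.
#'
#' @param dosage Numeric matrix, subjects in rows, variants in columns.
#'   Row names are ignored; identity comes from the metadata tibbles.
#' @param variants Tibble with one row per column of `dosage`; must contain
#'   `variant_id` (unique), `chrom`, `pos`, `ref`, `alt`; optional `r2`
#'   (imputation quality in \[0, 1\]) and `is_hla`.
#' @param subjects Tibble with one row per row of `dosage`; must contain
#'   `subject_id` (unique); optional `reported_sex`.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, variants, subjects) {
  dosage <- as.matrix(dosage)
  variants <- tibble::as_tibble(variants)
  subjects <- tibble::as_tibble(subjects)
  if (ncol(dosage) != nrow(variants)) {
    stop("`variants` must have one row per column of `dosage`.", call. = FALSE)
  }
  if (nrow(dosage) != nrow(subjects)) {
    stop("`subjects` must have one row per row of `dosage`.", call. = FALSE)
  }
  if (!all(c("variant_id", "chrom", "pos", "ref", "alt") %in% names(variants))) {
    stop("`variants` needs columns variant_id, chrom, pos, ref, alt.",
         call. = FALSE)
  }
  if (!"subject_id" %in% names(subjects)) {
    stop("`subjects` needs a subject_id column.", call. = FALSE)
  }
  if (anyDuplicated(variants$variant_id)) {
    stop("variant ids must be unique.", call. = FALSE)
  }
  if (anyDuplicated(subjects$subject_id)) {
    stop("subject ids must be unique.", call. = FALSE)
  }
  rng <- range(dosage, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) {
    stop("dosages must lie in [0, 2].", call. = FALSE)
  }
  if (!"r2" %in% names(variants)) variants$r2 <- NA_real_
  if (!"is_hla" %in% names(variants)) variants$is_hla <- FALSE
  dimnames(dosage) <- list(subjects$subject_id, variants$variant_id)
  structure(list(dosage = dosage, variants = variants, subjects = subjects),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d subjects x %d variants\n",
              nrow(x$dosage), ncol(x$dosage)))
  n_miss <- sum(is.na(x$dosage))
  cat(sprintf("  missing calls: %d (%.2f%%)\n", n_miss,
              100 * n_miss / length(x$dosage)))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by subject and/or variant
#'
#' @param x A [geno_matrix()].
#' @param subjects,variants Logical or integer index vectors along the
#'   respective axis, or character vectors of ids; `NULL` keeps everything.
#' @return A `geno_matrix` restricted to the selection.
#' @export
geno_subset <- function(x, subjects = NULL, variants = NULL) {
  stopifnot(inherits(x, "geno_matrix"))
  si <- resolve_index(subjects, x$subjects$subject_id)
  vi <- resolve_index(variants, x$variants$variant_id)
  geno_matrix(x$dosage[si, vi, drop = FALSE],
              x$variants[vi, , drop = FALSE],
              x$subjects[si, , drop = FALSE])
}

resolve_index <- function(idx, ids) {
  if (is.null(idx)) return(seq_along(ids))
  if (is.character(idx)) {
    pos <- match(idx, ids)
    if (anyNA(pos)) stop("unknown ids: ",
                         paste(idx[is.na(pos)], collapse = ", "), call. = FALSE)
    return(pos)
  }
  if (is.logical(idx)) return(which(idx))
  as.integer(idx)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Long-format view of a genotype matrix
#'
#' @param x A [geno_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `subject_id`, `variant_id`, `dosage`.
#' @export
tidy.geno_matrix <- function(x, ...) {
  tibble::tibble(
    subject_id = rep(x$subjects$subject_id, times = ncol(x$dosage)),
    variant_id = rep(x$variants$variant_id, each = nrow(x$dosage)),
    dosage = as.vector(x$dosage)
  )
}

#' Read genotype dosages from a VCF file
#'
#' Parses a VCF with per-genotype `DS` (dosage) or `GT` fields and an
#' optional `R2` INFO key (imputation quality). When `DS` is absent the
#' dosage is the alternate-allele count derived from `GT`.
#'
#' @param path Path to an uncompressed or bgzipped VCF.
#' @return A [geno_matrix()] (subjects x variants).
#' @export
read_genotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(v@fix, stringsAsFactors = FALSE))
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  r2 <- suppressWarnings(as.numeric(vcfR::extract.info(v, "R2")))
  has_ds <- any(grepl("DS", v@gt[, "FORMAT"]))
  if (has_ds) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, 2, function(col) {
      cleaned <- gsub("\\|", "/", col)
      out <- rep(NA_real_, length(cleaned))
      known <- !is.na(cleaned) & !grepl("\\.", cleaned)
      out[known] <- vapply(strsplit(cleaned[known], "/"),
                           function(a) sum(as.numeric(a) > 0), numeric(1))
      out
    })
    if (is.null(dim(ds))) ds <- matrix(ds, nrow = length(ids))
  }
  variants <- tibble::tibble(
    variant_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, r2 = r2,
    is_hla = grepl("^HLA", ids)
  )
  subjects <- tibble::tibble(subject_id = colnames(v@gt)[-1])
  geno_matrix(t(ds), variants, subjects)
}

#' Write a genotype matrix as a plain-text VCF
#'
#' Emits a minimal VCFv4.2 file with a `DS` genotype field, a derived `GT`
#' (best-guess genotype), and per-variant `R2` in INFO.
#'
#' @param x A [geno_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(x, path) {
  stopifnot(inherits(x, "geno_matrix"))
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Best-guess genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$subjects$subject_id), collapse = "\t")
  )
  gt_string <- function(d) {
    bg <- dosage_to_best_guess(d)
    gt <- c("0/0", "0/1", "1/1")[bg + 1L]
    gt[is.na(bg)] <- "./."
    ds <- ifelse(is.na(d), ".", formatC(d, digits = 4, format = "g"))
    paste0(gt, ":", ds)
  }
  body <- vapply(seq_len(ncol(x$dosage)), function(j) {
    v <- x$variants[j, ]
    info <- if (is.na(v$r2)) "." else sprintf("R2=%.4g", v$r2)
    paste(c(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS", info,
            "GT:DS", gt_string(x$dosage[, j])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
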