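#' ANCOVA comparison of cumulative PRS between comorbid and non-comorbid MS
#'
#' Ordinary least squares of the cumulative score on the comorbidity
#' indicator plus covariates, with a two-sided t test on the group
#' coefficient (the covariate-adjusted mean difference,
#' comorbid minus non-comorbid). Two covariate sets are always fitted
#' side by side: the full model with age, sex and the first three
#' ancestry principal components, and a reduced model without sex —
#' the two specifications conventionally reported. PC outliers are
#' expected to have been removed beforehand (see [sample_qc()]).
#'
#' @param profiles Tibble with one row per subject containing the score
#'   column, a logical `comorbid` flag, `age`, `sex`
#'   (`"female"`/`"male"`), and `PC1`, `PC2`, `PC3`.
#' @param score Name of the score column (default `"prs_comorb_hla"`).
#' @return An object of class `prs_ancova` carrying both fits; see
#'   [tidy.prs_ancova()].
#' @export
compare_prs_groups <- function(profiles, score = "prs_comorb_hla") {
  profiles <- tibble::as_tibble(profiles)
  need <- c(score, "comorbid", "age", "sex", "PC1", "PC2", "PC3")
  miss <- setdiff(need, names(profiles))
  if (length(miss) > 0) {
    stop("`profiles` lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n_grp <- table(factor(profiles$comorbid, levels = c(FALSE, TRUE)))
  if (any(n_grp < 2)) {
    stop("each group needs at least 2 subjects.", call. = FALSE)
  }
  dat <- tibble::tibble(
    y = profiles[[score]],
    comorbid = as.integer(profiles$comorbid),
    age = profiles$age,
    sex_female = as.integer(profiles$sex == "female"),
    PC1 = profiles$PC1, PC2 = profiles$PC2, PC3 = profiles$PC3
  )
  full <- stats::lm(y ~ comorbid + age + sex_female + PC1 + PC2 + PC3,
                    data = dat)
  reduced <- stats::lm(y ~ comorbid + age + PC1 + PC2 + PC3, data = dat)
  collinear <- any(is.na(stats::coef(full))) ||
    any(is.na(stats::coef(reduced)))

  # adjusted group means: predictions at the pooled covariate means
  covs <- colMeans(dat[, c("age", "sex_female", "PC1", "PC2", "PC3")])
  newd <- tibble::as_tibble(as.list(covs))
  newd <- dplyr::bind_rows(newd, newd)
  newd$comorbid <- c(0L, 1L)
  adj_means <- stats::predict(full, newdata = newd)

  structure(list(
    full = full, reduced = reduced, score = score,
    collinear = collinear,
    n_comorbid = unname(n_grp["TRUE"]), n_noncomorbid = unname(n_grp["FALSE"]),
    adjusted_means = tibble::tibble(
      group = c("non_comorbid", "comorbid"),
      adjusted_mean = unname(adj_means)
    )
  ), class = "prs_ancova")
}

group_row <- function(fit, model_label) {
  s <- unname(summary(fit)$coefficients["comorbid", ])
  tibble::tibble(
    model = model_label,
    estimate = s[1], std_error = s[2],
    statistic = s[3], p_value = s[4]
  )
}

#' Tidy an ANCOVA PRS comparison
#'
#' @param x A `prs_ancova` from [compare_prs_groups()].
#' @param ... Unused.
#' @return A tibble with one row per fitted model
#'   (`"age_sex_pc"`, `"age_pc"`): the group coefficient (adjusted mean
#'   difference, comorbid minus non-comorbid), its standard error,
#'   t statistic and two-sided p-value.
#' @export
tidy.prs_ancova <- function(x, ...) {
  dplyr::bind_rows(group_row(x$full, "age_sex_pc"),
                   group_row(x$reduced, "age_pc"))
}

#' @rdname tidy.prs_ancova
#' @return For `glance()`: one row with group sizes, the score analysed,
#'   adjusted group means from the full model, and the collinearity flag.
#' @export
glance.prs_ancova <- function(x, ...) {
  tibble::tibble(
    score = x$score,
    n_comorbid = x$n_comorbid, n_noncomorbid = x$n_noncomorbid,
    adj_mean_comorbid = x$adjusted_means$adjusted_mean[2],
    adj_mean_noncomorbid = x$adjusted_means$adjusted_mean[1],
    collinear = x$collinear
  )
}

#' @export
print.prs_ancova <- function(x, ...) {
  cat(sprintf("<prs_ancova> %s: %d comorbid vs %d non-comorbid\n",
              x$score, x$n_comorbid, x$n_noncomorbid))
  if (x$collinear) cat("  WARNING: collinear covariates\n")
  print(tidy(x))
  invisible(x)
}

#' Write an ANCOVA result as JSON
#'
#' @param x A `prs_ancova`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ancova_json <- function(x, path) {
  payload <- list(
    score = x$score,
    models = tidy(x),
    n = list(comorbid = x$n_comorbid, non_comorbid = x$n_noncomorbid),
    adjusted_means = x$adjusted_means,
    collinear = x$collinear
  )
  jsonlite::write_json(payload, path, dataframe = "rows",
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Distribution plot of a cumulative PRS by comorbidity group
#'
#' Violin-and-box summary per group; purely presentational.
#'
#' @param profiles Tibble with the score column and a logical `comorbid`.
#' @param score Score column name.
#' @param file Optional output path; when given the figure is written
#'   there (device chosen from the extension via [ggplot2::ggsave()]).
#' @return The ggplot object, invisibly when `file` is given.
#' @export
plot_prs_distribution <- function(profiles, score = "prs_comorb_hla",
                                  file = NULL) {
  profiles <- tibble::as_tibble(profiles)
  if (!score %in% names(profiles)) {
    stop(sprintf("no column `%s` in `profiles`.", score), call. = FALSE)
  }
  counts <- table(factor(profiles$comorbid, levels = c(FALSE, TRUE)))
  if (any(counts == 0)) stop("both groups must be non-empty.", call. = FALSE)
  dat <- tibble::tibble(
    group = ifelse(profiles$comorbid, "With AID comorbidity",
                   "Without AID comorbidity"),
    score = profiles[[score]]
  )
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$score,
                                         fill = .data$group)) +
    ggplot2::geom_violin(alpha = 0.5, trim = FALSE) +
    ggplot2::geom_boxplot(width = 0.15, outlier.shape = NA, fill = "white") +
    ggplot2::labs(x = NULL, y = score) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 5, height = 4)
    return(invisible(p))
  }
  p
}

#' @export
autoplot.prs_ancova <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$model, y = .data$estimate)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$estimate - 1.96 * .data$std_error,
                   ymax = .data$estimate + 1.96 * .data$std_error),
      width = 0.1) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL,
                  y = "adjusted group difference (comorbid - non-comorbid)") +
    ggplot2::theme_minimal()
}

#' PC scatter of genotyped subjects
#'
#' Basic ancestry-PC scatter, optionally coloured by comorbidity.
#'
#' @param scores Tibble from [compute_pcs()] (`$scores`), optionally with
#'   a `comorbid` column joined on.
#' @param dims Which two PCs to draw (default 1:2).
#' @return A ggplot object.
#' @export
plot_pc_scatter <- function(scores, dims = c(1, 2)) {
  cols <- paste0("PC", dims)
  p <- ggplot2::ggplot(scores,
                       ggplot2::aes(x = .data[[cols[1]]],
                                    y = .data[[cols[2]]]))
  if ("comorbid" %in% names(scores)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$comorbid),
                                 alpha = 0.7)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.7)
  }
  p + ggplot2::theme_minimal()
}
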