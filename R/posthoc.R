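#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Characterises derived sub-groups against controls: for each variable, a
#' one-way ANOVA across the supplied groups and Tukey honestly-significant-
#' difference adjusted pairwise p-values, with per-group means and SDs.
#'
#' @param data A data frame holding the variables (e.g. a
#'   [feature_table()] on the raw scale).
#' @param groups Group label per row (>= 2 groups, each with >= 2 members).
#' @param variables Variables to compare; default every numeric column
#'   except `participant_id`/`group`.
#' @return A `painstrat_posthoc` object: `summary` (tibble `variable`,
#'   `group`, `n`, `mean`, `sd`), `anova` (tibble `variable`, `F`, `p`,
#'   `flagged`), `tukey` (tibble `variable`, `group1`, `group2`, `diff`,
#'   `p_adj`).
#' @export
#' @examples
#' tab <- toy_feature_table()
#' anova_tukey(tab, tab$group, "depressive_symptoms")
anova_tukey <- function(data, groups, variables = NULL) {
  data <- as.data.frame(data)
  g <- factor(groups)
  if (nlevels(g) < 2) abort_contract("Need >= 2 groups.")
  if (any(base::table(g) < 2)) {
    abort_contract("Every group needs >= 2 members.")
  }
  if (is.null(variables)) {
    variables <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                         c("participant_id", "group"))
  }
  summaries <- list()
  anovas <- list()
  tukeys <- list()
  for (v in variables) {
    x <- data[[v]]
    if (is.null(x)) abort_contract(paste0("Unknown variable: ", v))
    ok <- !is.na(x)
    summaries[[v]] <- tibble::tibble(
      variable = v, group = levels(g),
      n = as.integer(base::table(g[ok])[levels(g)]),
      mean = as.numeric(tapply(x[ok], g[ok], mean)[levels(g)]),
      sd = as.numeric(tapply(x[ok], g[ok], stats::sd)[levels(g)])
    )
    if (stats::sd(x[ok]) == 0) {
      anovas[[v]] <- tibble::tibble(variable = v, F = NA_real_, p = NA_real_,
                                    flagged = TRUE)
      next
    }
    fit <- stats::aov(x ~ g, data = data.frame(x = x[ok], g = g[ok]))
    an <- summary(fit)[[1]]
    anovas[[v]] <- tibble::tibble(variable = v, F = an$`F value`[1],
                                  p = an$`Pr(>F)`[1], flagged = FALSE)
    tk <- stats::TukeyHSD(fit)$g
    tukeys[[v]] <- tibble::tibble(
      variable = v,
      group1 = sub("-.*$", "", rownames(tk)),
      group2 = sub("^[^-]*-", "", rownames(tk)),
      diff = tk[, "diff"],
      p_adj = tk[, "p adj"]
    )
  }
  structure(
    list(summary = dplyr::bind_rows(summaries),
         anova = dplyr::bind_rows(anovas),
         tukey = dplyr::bind_rows(tukeys)),
    class = "painstrat_posthoc"
  )
}

#' @export
print.painstrat_posthoc <- function(x, ...) {
  cat(sprintf("<posthoc> %d variable(s), %d group(s)\n",
              nrow(x$anova), length(unique(x$summary$group))))
  print(x$anova)
  invisible(x)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y Numeric vectors with >= 4 complete pairs.
#' @param level Confidence level (default 0.95).
#' @return A tibble with `r`, `low`, `high`, `p`, `n`.
#' @export
#' @examples
#' pearson_ci(1:10, (1:10) + rnorm(10))
pearson_ci <- function(x, y, level = 0.95) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 4) abort_contract("Need >= 4 complete pairs.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_domain("x and y must have non-zero variance.")
  }
  ct <- stats::cor.test(x, y, conf.level = level)
  tibble::tibble(
    r = unname(ct$estimate),
    low = ct$conf.int[1], high = ct$conf.int[2],
    p = ct$p.value, n = length(x)
  )
}

#' Pearson chi-square test on a contingency table
#'
#' @param contingency Matrix of non-negative integer counts, at least 2x2,
#'   with no all-zero row or column.
#' @param correct Apply Yates continuity correction for 2x2 tables
#'   (default `FALSE`).
#' @return A tibble with `statistic`, `df`, `p`.
#' @export
chi_square_table <- function(contingency, correct = FALSE) {
  contingency <- as.matrix(contingency)
  if (any(contingency < 0) || any(contingency != round(contingency))) {
    abort_domain("Counts must be non-negative integers.")
  }
  if (nrow(contingency) < 2 || ncol(contingency) < 2) {
    abort_contract("Contingency table must be at least 2x2.")
  }
  if (any(rowSums(contingency) == 0) || any(colSums(contingency) == 0)) {
    abort_contract("Contingency table has an all-zero row or column.")
  }
  ct <- suppressWarnings(stats::chisq.test(contingency, correct = correct))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value)
}
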