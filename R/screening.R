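#' Benjamini-Hochberg step-up adjusted p-values
#'
#' The classic step-up rule: order the m p-values increasingly, set
#' `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1, and map back to the
#' original order. Monotone non-decreasing in p-rank by construction.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   returned as `NA`; the effective m is the number of non-missing values).
#' @return Adjusted q-values, same length and order as `p`.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.04, 0.03, 0.005))
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort_domain("p-values must lie in [0, 1].")
  }
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(q)
  ord <- order(p[ok])
  ranked <- p[ok][ord]
  adj <- rev(cummin(rev(m * ranked / seq_len(m))))
  q[ok[ord]] <- pmin(adj, 1)
  q
}

#' Between-group univariate t-tests
#'
#' One two-sample t-test per variable between cases and controls, with
#' Benjamini-Hochberg adjusted q-values. Following the pilot-study logic,
#' the `selected` flag retains variables significant *before* FDR
#' adjustment; the q-values are reported to show which survive it.
#'
#' @param table A [feature_table()].
#' @param alpha Significance level for selection (default 0.05).
#' @param var_equal `FALSE` (default) for Welch, `TRUE` for pooled variance.
#' @return A tibble with one row per variable: group means/SDs, `t`, `df`,
#'   `p`, `q`, `selected`, and `untestable` (fewer than two non-missing
#'   values in either group).
#' @export
group_t_tests <- function(table, alpha = 0.05, var_equal = FALSE) {
  vals <- ft_values(table)
  is_case <- table$group == "case"
  if (!any(is_case) || !all(c("case", "control") %in% table$group)) {
    abort_contract("Both case and control groups must be present.")
  }
  res <- purrr::map_dfr(colnames(vals), function(v) {
    x <- vals[is_case, v]
    y <- vals[!is_case, v]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    base <- tibble::tibble(
      variable = v,
      n_case = length(x), n_control = length(y),
      mean_case = mean(x), mean_control = mean(y),
      sd_case = stats::sd(x), sd_control = stats::sd(y)
    )
    if (length(x) < 2 || length(y) < 2 ||
        (stats::sd(x) == 0 && stats::sd(y) == 0)) {
      return(dplyr::mutate(base, t = NA_real_, df = NA_real_, p = NA_real_,
                           untestable = TRUE))
    }
    tt <- stats::t.test(x, y, var.equal = var_equal)
    dplyr::mutate(base, t = unname(tt$statistic), df = unname(tt$parameter),
                  p = tt$p.value, untestable = FALSE)
  })
  res$q <- bh_fdr(res$p)
  res$selected <- !is.na(res$p) & res$p < alpha
  res
}

#' Remove one member of each highly correlated variable pair
#'
#' Computes the pairwise-complete Pearson correlation matrix over the
#' candidate variables and, for each pair with `|r|` above the threshold,
#' drops the member with the larger univariate p-value (ties: the later
#' column). Zero-variance candidates are excluded with a reason.
#'
#' @param table A [feature_table()].
#' @param candidates Variable names to consider (subset of the table).
#' @param r_threshold Absolute-correlation threshold in (0, 1); default 0.8.
#' @param p_values Optional named vector of univariate p-values used for the
#'   tie rule; defaults to equal (drop the later column).
#' @return A list: `kept` (surviving names, input order), `removed` (tibble
#'   `variable`, `reason`), `pairs` (tibble `var1`, `var2`, `r` of all
#'   flagged pairs).
#' @export
collinearity_filter <- function(table, candidates = ft_variables(table),
                                r_threshold = 0.8, p_values = NULL) {
  if (r_threshold <= 0 || r_threshold >= 1) {
    abort_contract("r_threshold must lie in (0, 1).")
  }
  missing_vars <- setdiff(candidates, ft_variables(table))
  if (length(missing_vars) > 0) {
    abort_contract(paste0("Unknown candidate(s): ",
                          paste(missing_vars, collapse = ", ")))
  }
  vals <- ft_values(table)[, candidates, drop = FALSE]
  removed <- tibble::tibble(variable = character(), reason = character())
  sds <- apply(vals, 2, stats::sd, na.rm = TRUE)
  degenerate <- candidates[!is.finite(sds) | sds == 0]
  if (length(degenerate) > 0) {
    removed <- dplyr::bind_rows(removed, tibble::tibble(
      variable = degenerate, reason = "zero variance"
    ))
    candidates <- setdiff(candidates, degenerate)
    vals <- vals[, candidates, drop = FALSE]
  }
  pairs <- tibble::tibble(var1 = character(), var2 = character(), r = numeric())
  if (length(candidates) >= 2) {
    cm <- stats::cor(vals, use = "pairwise.complete.obs")
    idx <- which(upper.tri(cm) & abs(cm) > r_threshold, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      pairs <- tibble::tibble(
        var1 = candidates[idx[, 1]], var2 = candidates[idx[, 2]],
        r = cm[idx]
      )
      # resolve pairs in decreasing |r|; skip pairs already broken
      pairs <- dplyr::arrange(pairs, dplyr::desc(abs(r)))
      dropped <- character()
      for (i in seq_len(nrow(pairs))) {
        v1 <- pairs$var1[i]
        v2 <- pairs$var2[i]
        if (v1 %in% dropped || v2 %in% dropped) next
        loser <- collinear_loser(v1, v2, p_values, candidates)
        dropped <- c(dropped, loser)
        removed <- dplyr::bind_rows(removed, tibble::tibble(
          variable = loser,
          reason = sprintf("|r| = %.3f with %s exceeds %.2f",
                           abs(pairs$r[i]), setdiff(c(v1, v2), loser),
                           r_threshold)
        ))
      }
      candidates <- setdiff(candidates, dropped)
    }
  }
  list(kept = candidates, removed = removed, pairs = pairs)
}

collinear_loser <- function(v1, v2, p_values, order_ref) {
  if (!is.null(p_values) && !is.na(p_values[v1]) && !is.na(p_values[v2]) &&
      p_values[v1] != p_values[v2]) {
    return(if (p_values[v1] > p_values[v2]) v1 else v2)
  }
  # equal or unknown p: drop the later column
  if (match(v1, order_ref) > match(v2, order_ref)) v1 else v2
}

#' Screen variables for the data-analytic steps
#'
#' The first pipeline stage: between-group t-tests with FDR q-values,
#' selection of unadjusted-significant variables, multicollinearity
#' filtering among the selected, and an explicit forced-removal list for
#' judgment calls (e.g. dropping a near-duplicate pain-site count).
#'
#' @inheritParams group_t_tests
#' @inheritParams collinearity_filter
#' @param force_remove Variables removed from the surviving set regardless
#'   of the statistics, each logged with reason `"forced removal"`.
#' @return A `painstrat_screening` object: list with `tests` (the
#'   [group_t_tests()] tibble), `collinearity_pairs`, `removed`,
#'   `surviving` (character vector in table column order), `alpha`,
#'   `r_threshold`.
#' @export
#' @examples
#' screen_features(toy_feature_table(), alpha = 0.2)
screen_features <- function(table, alpha = 0.05, r_threshold = 0.8,
                            var_equal = FALSE, force_remove = character()) {
  tests <- group_t_tests(table, alpha = alpha, var_equal = var_equal)
  selected <- tests$variable[tests$selected]
  pv <- stats::setNames(tests$p, tests$variable)
  cf <- collinearity_filter(table, candidates = selected,
                            r_threshold = r_threshold, p_values = pv)
  removed <- cf$removed
  kept <- cf$kept
  forced <- intersect(force_remove, kept)
  if (length(forced) > 0) {
    removed <- dplyr::bind_rows(removed, tibble::tibble(
      variable = forced, reason = "forced removal"
    ))
    kept <- setdiff(kept, forced)
  }
  structure(
    list(
      tests = tests,
      collinearity_pairs = cf$pairs,
      removed = removed,
      surviving = intersect(ft_variables(table), kept),
      alpha = alpha,
      r_threshold = r_threshold
    ),
    class = "painstrat_screening"
  )
}

#' @export
print.painstrat_screening <- function(x, ...) {
  cat(sprintf(
    "<screening> %d variables tested; %d selected at alpha = %g; %d after FDR; %d surviving\n",
    nrow(x$tests), sum(x$tests$selected, na.rm = TRUE), x$alpha,
    sum(x$tests$q < x$alpha, na.rm = TRUE), length(x$surviving)
  ))
  if (nrow(x$removed) > 0) {
    cat("  removed:", paste(x$removed$variable, collapse = ", "), "\n")
  }
  invisible(x)
}
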