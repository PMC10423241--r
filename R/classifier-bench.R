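#' Mean and t-based confidence interval of holdout error rates
#'
#' @param errors Error rates in `[0, 1]`, length >= 2.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return A tibble with `mean`, `low`, `high` (interval truncated to
#'   `[0, 1]`).
#' @export
error_ci <- function(errors, level = 0.95) {
  if (length(errors) < 2) abort_contract("Need >= 2 error values.")
  if (any(errors < 0 | errors > 1)) {
    abort_domain("Error rates must lie in [0, 1].")
  }
  if (level <= 0 || level >= 1) abort_contract("level must lie in (0, 1).")
  n <- length(errors)
  m <- mean(errors)
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * stats::sd(errors) / sqrt(n)
  tibble::tibble(mean = m, low = max(0, m - half), high = min(1, m + half))
}

# Stratified train/test split indices: per class, round(n * fraction)
# (at least 1) test rows.
stratified_split <- function(labels, test_fraction) {
  test <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_test <- max(1L, round(length(idx) * test_fraction))
    if (n_test >= length(idx)) n_test <- length(idx) - 1L
    test <- c(test, sample(idx, n_test))
  }
  sort(test)
}

fit_predict <- function(classifier, x_train, y_train, x_test, seed) {
  switch(classifier,
    svm = {
      fit <- e1071::svm(x = x_train, y = y_train, kernel = "radial", cost = 1)
      stats::predict(fit, x_test)
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(x = x_train, y = y_train)
      stats::predict(fit, x_test)
    },
    knn = {
      k <- min(5, nrow(x_train))
      class::knn(train = x_train, test = x_test, cl = y_train, k = k)
    },
    random_forest = {
      set.seed(seed)
      fit <- randomForest::randomForest(x = as.data.frame(x_train),
                                        y = y_train, ntree = 500)
      stats::predict(fit, as.data.frame(x_test))
    },
    abort_contract(paste0("Unknown classifier: ", classifier))
  )
}

#' Repeated-holdout classifier benchmark of derived sub-groups
#'
#' Quantifies how re-identifiable the sub-groups are: for each of `n_runs`
#' stratified 80/20 train/test splits, four classifiers (radial SVM with
#' one-vs-one multiclass, Gaussian naive Bayes, 5-nearest-neighbour, and a
#' 500-tree random forest) are trained on the same split and scored by
#' their misclassified fraction of the test set.
#'
#' @param table A [normalise_01()] table (cases only, or cases plus
#'   controls when benchmarking against the pain-free class).
#' @param labels Named or positional class labels per row of `table` (e.g.
#'   sub-group ids, optionally with `"control"` as an extra class). Every
#'   class needs >= 2 members.
#' @param features Variables used as predictors.
#' @param n_runs Number of holdout repetitions (default 30).
#' @param test_fraction Test proportion in (0, 0.5] (default 0.2).
#' @param seed Master seed; run r uses `seed + r` for its split.
#' @return A `painstrat_benchmark` object: `runs` (tibble `run`,
#'   `classifier`, `error`), `summary` (tibble `classifier`, `mean_error`,
#'   `ci_low`, `ci_high`), `setting`, `n_runs`, `seed`.
#' @export
holdout_benchmark <- function(table, labels, features = ft_variables(table),
                              n_runs = 30, test_fraction = 0.2, seed = 1) {
  if (test_fraction <= 0 || test_fraction > 0.5) {
    abort_contract("test_fraction must lie in (0, 0.5].")
  }
  x <- ft_values(table)[, features, drop = FALSE]
  y <- factor(labels)
  if (length(y) != nrow(x)) {
    abort_contract("labels must have one value per table row.")
  }
  complete <- stats::complete.cases(x)
  x <- x[complete, , drop = FALSE]
  y <- droplevels(y[complete])
  if (nlevels(y) < 2) abort_contract("Need >= 2 classes.")
  counts <- base::table(y)
  if (any(counts < 2)) {
    abort_contract(paste0(
      "Class(es) with < 2 members: ",
      paste(names(counts)[counts < 2], collapse = ", ")
    ))
  }
  classifiers <- c("svm", "naive_bayes", "knn", "random_forest")
  runs <- purrr::map_dfr(seq_len(n_runs), function(r) {
    set.seed(seed + r)
    test_idx <- stratified_split(as.character(y), test_fraction)
    x_tr <- x[-test_idx, , drop = FALSE]
    y_tr <- droplevels(y[-test_idx])
    x_te <- x[test_idx, , drop = FALSE]
    y_te <- y[test_idx]
    purrr::map_dfr(classifiers, function(clf) {
      pred <- fit_predict(clf, x_tr, y_tr, x_te, seed = seed + r)
      tibble::tibble(run = r, classifier = clf,
                     error = mean(as.character(pred) != as.character(y_te)))
    })
  })
  summary <- runs |>
    dplyr::group_by(.data$classifier) |>
    dplyr::summarise(ci = list(error_ci(.data$error)), .groups = "drop") |>
    tidyr::unnest("ci") |>
    dplyr::rename(mean_error = "mean", ci_low = "low", ci_high = "high")
  structure(
    list(runs = runs, summary = summary,
         setting = if (any(y == "control")) "cases_plus_controls" else "cases_only",
         n_runs = n_runs, test_fraction = test_fraction, seed = seed),
    class = "painstrat_benchmark"
  )
}

#' @export
print.painstrat_benchmark <- function(x, ...) {
  cat(sprintf("<classifier benchmark> %s, %d runs of %.0f/%.0f holdout\n",
              x$setting, x$n_runs, 100 * (1 - x$test_fraction),
              100 * x$test_fraction))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-14s %.1f%% (%.1f, %.1f)\n", s$classifier[i],
                100 * s$mean_error[i], 100 * s$ci_low[i], 100 * s$ci_high[i]))
  }
  invisible(x)
}
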