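#' Run the full sub-grouping pipeline
#'
#' Executes the analysis end to end on a case-control feature table:
#'
#' 1. between-group t-tests with FDR q-values and multicollinearity
#'    filtering ([screen_features()]);
#' 2. unit-interval normalisation over the reference rows
#'    ([normalise_01()]) and random-forest case/control feature weighting
#'    ([rf_feature_weighting()]);
#' 3. Laplacian-score ranking within cases ([laplacian_rank()]) on the
#'    screening survivors minus `force_remove`;
#' 4. incremental cluster-validity scan ([validity_scan()]) selecting the
#'    feature count and cluster number;
#' 5. fuzzy c-means sub-grouping with quality metrics ([fuzzy_cmeans()],
#'    [cluster_metrics()]);
#' 6. repeated-holdout classifier benchmarks, cases only and with controls
#'    added as an extra class ([holdout_benchmark()]);
#' 7. post-hoc ANOVA + Tukey comparisons of controls and sub-groups on the
#'    clustering variables ([anova_tukey()]).
#'
#' @param table A [feature_table()] with both cases and controls.
#' @param alpha Screening significance level (default 0.05).
#' @param r_threshold Absolute-correlation collinearity threshold
#'   (default 0.8).
#' @param force_remove Variables dropped between feature weighting and
#'   ranking regardless of statistics (default `"pain_sites_7d"`, the
#'   near-duplicate of the 12-month pain-site count).
#' @param k_range Candidate cluster numbers (default `2:6`).
#' @param m Fuzzifier (default 2).
#' @param k_neighbours Laplacian graph neighbourhood size (default 5).
#' @param n_runs Holdout repetitions (default 30).
#' @param test_fraction Holdout test proportion (default 0.2).
#' @param reference Normalisation reference rows (default `"all"`).
#' @param seed Master seed used by every stochastic stage.
#' @return A `painstrat_pipeline` object: list with `screening`,
#'   `normalised`, `rf_ranking`, `laplacian`, `validity`, `model`,
#'   `subgroups` (tibble `participant_id`, `subgroup`),
#'   `benchmark_cases`, `benchmark_with_controls`, `posthoc`, `config`.
#' @export
#' @examples
#' \donttest{
#' cohort <- generate_cohort(seed = 7)
#' fit <- clbp_pipeline(cohort$table, seed = 7)
#' fit$validity$selected_features
#' }
clbp_pipeline <- function(table, alpha = 0.05, r_threshold = 0.8,
                          force_remove = "pain_sites_7d", k_range = 2:6,
                          m = 2, k_neighbours = 5, n_runs = 30,
                          test_fraction = 0.2, reference = "all", seed = 1) {
  config <- list(alpha = alpha, r_threshold = r_threshold,
                 force_remove = force_remove, k_range = k_range, m = m,
                 k_neighbours = k_neighbours, n_runs = n_runs,
                 test_fraction = test_fraction, reference = reference,
                 seed = seed)
  screening <- screen_features(table, alpha = alpha,
                               r_threshold = r_threshold)
  if (length(screening$surviving) < 1) {
    abort_contract("Screening left no variables; nothing to cluster.")
  }
  ntable <- normalise_01(table, reference = reference)
  rf_ranking <- rf_feature_weighting(ntable,
                                     variables = screening$surviving,
                                     seed = seed)
  rank_vars <- setdiff(screening$surviving, force_remove)
  if (length(rank_vars) < 2) {
    abort_contract("Fewer than 2 variables enter the ranking stage.")
  }
  cases <- filter_group(ntable, "case")
  lap <- laplacian_rank(cases, variables = rank_vars,
                        k_neighbours = k_neighbours)
  validity <- validity_scan(cases, lap, k_range = k_range, seed = seed)
  model <- fuzzy_cmeans(cases, features = validity$selected_features,
                        k = validity$selected_k, m = m, seed = seed)
  model <- cluster_metrics(model, cases)
  subgroups <- tibble::tibble(
    participant_id = model$participant_id,
    subgroup = paste0("subgroup_", model$hard_labels)
  )
  bench_cases <- holdout_benchmark(
    cases, labels = subgroups$subgroup[match(cases$participant_id,
                                             subgroups$participant_id)],
    features = model$feature_names, n_runs = n_runs,
    test_fraction = test_fraction, seed = seed
  )
  all_labels <- ifelse(
    ntable$group == "control", "control",
    subgroups$subgroup[match(ntable$participant_id,
                             subgroups$participant_id)]
  )
  keep <- !is.na(all_labels)
  bench_all <- holdout_benchmark(
    ntable[keep, , drop = FALSE] |> restore_ft(ntable),
    labels = all_labels[keep], features = model$feature_names,
    n_runs = n_runs, test_fraction = test_fraction, seed = seed
  )
  group3 <- ifelse(table$group == "control", "control",
                   subgroups$subgroup[match(table$participant_id,
                                            subgroups$participant_id)])
  ok3 <- !is.na(group3)
  posthoc <- anova_tukey(as.data.frame(table)[ok3, , drop = FALSE],
                         group3[ok3], variables = model$feature_names)
  structure(
    list(screening = screening, normalised = ntable,
         rf_ranking = rf_ranking, laplacian = lap, validity = validity,
         model = model, subgroups = subgroups,
         benchmark_cases = bench_cases,
         benchmark_with_controls = bench_all,
         posthoc = posthoc, config = config),
    class = "painstrat_pipeline"
  )
}

# re-attach feature_table attributes lost by row-subsetting a tibble
restore_ft <- function(x, template) {
  for (a in c("meta", "norm_params", "reference")) {
    attr(x, a) <- attr(template, a)
  }
  class(x) <- class(template)
  x
}

#' @export
print.painstrat_pipeline <- function(x, ...) {
  cat("<painstrat pipeline>\n")
  cat(sprintf(
    "  screening: %d/%d selected (%d after FDR), %d surviving\n",
    sum(x$screening$tests$selected, na.rm = TRUE), nrow(x$screening$tests),
    sum(x$screening$tests$q < x$screening$alpha, na.rm = TRUE),
    length(x$screening$surviving)
  ))
  cat(sprintf("  clustering: %d features, k = %d, sizes %s\n",
              x$validity$selected_n_features, x$model$k,
              paste(x$model$sizes, collapse = "/")))
  cat(sprintf("  silhouette %.2f; within %s; between %.2f\n",
              x$model$silhouette_index,
              paste(sprintf("%.2f", x$model$within_cluster_distances),
                    collapse = "/"),
              x$model$between_cluster_distance))
  cat("  cases-only errors: ")
  s <- x$benchmark_cases$summary
  cat(paste(sprintf("%s %.1f%%", s$classifier, 100 * s$mean_error),
            collapse = ", "), "\n")
  invisible(x)
}

#' Sub-domain clustering (sensitivity analysis)
#'
#' Repeats the case-only stages (Laplacian ranking, validity scan, fuzzy
#' c-means, metrics) within a single biopsychosocial domain, using only
#' variables that survived the primary screening, and names the resulting
#' clusters against the control profile ([label_clusters()]). A domain
#' with fewer than 2 surviving variables is skipped with a reason, not an
#' error.
#'
#' @param table The full [feature_table()].
#' @param domain `"nervous"`, `"spinal"` or `"psychosocial"`.
#' @param surviving Variables that survived primary screening (e.g.
#'   `fit$screening$surviving` minus forced removals).
#' @inheritParams clbp_pipeline
#' @return A `painstrat_subdomain` object with `domain`, `skipped`,
#'   `reason`, and when run: `validity`, `model`, `labels` (tibble
#'   `participant_id`, `label`, `normal`).
#' @export
run_subdomain <- function(table, domain, surviving, k_range = 2:6, m = 2,
                          k_neighbours = 5, reference = "all", seed = 1) {
  domain <- match.arg(domain, painstrat_domains)
  meta <- ft_meta(table)
  vars <- intersect(surviving, meta$name[meta$domain == domain])
  if (length(vars) < 2) {
    return(structure(
      list(domain = domain, skipped = TRUE,
           reason = sprintf(
             "only %d surviving variable(s) in domain '%s'; need >= 2",
             length(vars), domain)),
      class = "painstrat_subdomain"
    ))
  }
  ntable <- normalise_01(table, reference = reference)
  cases <- filter_group(ntable, "case")
  lap <- laplacian_rank(cases, variables = vars,
                        k_neighbours = k_neighbours)
  validity <- validity_scan(cases, lap, k_range = k_range, seed = seed)
  model <- fuzzy_cmeans(cases, features = validity$selected_features,
                        k = validity$selected_k, m = m, seed = seed)
  model <- cluster_metrics(model, cases)
  labels <- label_clusters(model, ntable)
  structure(
    list(domain = domain, skipped = FALSE, reason = NULL,
         validity = validity, model = model, labels = labels),
    class = "painstrat_subdomain"
  )
}

#' @export
print.painstrat_subdomain <- function(x, ...) {
  if (x$skipped) {
    cat(sprintf("<subdomain %s> skipped: %s\n", x$domain, x$reason))
  } else {
    cat(sprintf("<subdomain %s> k = %d on %s\n", x$domain, x$model$k,
                paste(x$model$feature_names, collapse = ", ")))
    print(base::table(x$labels$label))
  }
  invisible(x)
}

#' Name clusters against the control profile
#'
#' Gives each hard cluster a human-readable label: the cluster whose
#' centroid lies closest (Euclidean, unit scale) to the mean control
#' profile on the model's variables is `"normal"`; every other cluster is
#' named by its deviating variables — those whose centroid departs from
#' the control mean by at least `dev_threshold` (unit scale) — prefixed
#' `low_`/`high_` by direction.
#'
#' @param model A `painstrat_fcm`.
#' @param ntable The [normalise_01()] table including controls.
#' @param dev_threshold Minimum unit-scale deviation for a variable to be
#'   named (default 0.15).
#' @return A tibble with `participant_id`, `cluster`, `label`, `normal`.
#' @export
label_clusters <- function(model, ntable, dev_threshold = 0.15) {
  controls <- filter_group(ntable, "control")
  if (nrow(controls) == 0) abort_contract("No control rows to compare with.")
  ctl_mean <- colMeans(ft_values(controls)[, model$feature_names,
                                           drop = FALSE], na.rm = TRUE)
  dev <- sweep(model$centroids, 2, ctl_mean)
  dist_to_ctl <- sqrt(rowSums(dev^2))
  normal_cluster <- which.min(dist_to_ctl)
  cluster_names <- vapply(seq_len(model$k), function(c) {
    if (c == normal_cluster) return("normal")
    d <- dev[c, ]
    named <- names(d)[abs(d) >= dev_threshold]
    if (length(named) == 0) named <- names(d)[which.max(abs(d))]
    paste(ifelse(d[named] < 0, paste0("low_", named),
                 paste0("high_", named)), collapse = "+")
  }, character(1))
  tibble::tibble(
    participant_id = model$participant_id,
    cluster = model$hard_labels,
    label = cluster_names[model$hard_labels],
    normal = model$hard_labels == normal_cluster
  )
}

#' Combine per-domain sub-group labels into an overall profile
#'
#' Concatenates each participant's non-`"normal"` domain labels in the
#' fixed order psychosocial, spinal, nervous into an overall classification
#' and records which domains contribute. A participant whose three labels
#' are all normal gets an empty combined label and zero contributing
#' domains.
#'
#' @param psychosocial,spinal,nervous Label tibbles with columns
#'   `participant_id`, `label`, `normal` (e.g. from [run_subdomain()]).
#'   Every participant must appear in all three.
#' @return A tibble with `participant_id`, the three domain labels,
#'   `combined_label` (`"; "`-separated), and `domains_contributing`
#'   (`"+"`-separated, `""` when none).
#' @export
combine_subdomain_labels <- function(psychosocial, spinal, nervous) {
  doms <- list(psychosocial = psychosocial, spinal = spinal,
               nervous = nervous)
  ids <- unique(unlist(lapply(doms, function(d) d$participant_id)))
  for (nm in names(doms)) {
    missing_ids <- setdiff(ids, doms[[nm]]$participant_id)
    if (length(missing_ids) > 0) {
      abort_contract(paste0(
        "Participant(s) missing a ", nm, " label: ",
        paste(missing_ids, collapse = ", ")
      ))
    }
  }
  purrr::map_dfr(ids, function(id) {
    lab <- vapply(doms, function(d) d$label[d$participant_id == id][1],
                  character(1))
    normal <- vapply(doms, function(d) d$normal[d$participant_id == id][1],
                     logical(1))
    contributing <- names(doms)[!normal]
    tibble::tibble(
      participant_id = id,
      psychosocial_label = lab[["psychosocial"]],
      spinal_label = lab[["spinal"]],
      nervous_label = lab[["nervous"]],
      combined_label = paste(lab[!normal], collapse = "; "),
      domains_contributing = paste(contributing, collapse = "+")
    )
  })
}
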