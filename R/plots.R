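#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the cluster-validity scan
#'
#' One panel per validity index showing its best-k value against the
#' number of ranked features entering the clustering; the dashed line
#' marks the selected feature count.
#'
#' @param object A `painstrat_validity`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.painstrat_validity <- function(object, ...) {
  best <- object$grid |>
    tidyr::pivot_longer(c("ch", "db", "silhouette"),
                        names_to = "index", values_to = "value") |>
    dplyr::group_by(.data$n_features, .data$index) |>
    dplyr::summarise(
      value = ifelse(.data$index[1] == "db", min(.data$value, na.rm = TRUE),
                     max(.data$value, na.rm = TRUE)),
      .groups = "drop"
    )
  ggplot2::ggplot(best, ggplot2::aes(.data$n_features, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$selected_n_features,
                        linetype = "dashed") +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = "features entered (ranking order)",
                  y = "index at its best k",
                  title = "Cluster-validity scan") +
    ggplot2::theme_minimal()
}

#' Plot per-cluster variable profiles
#'
#' Shows each participant's unit-scaled value on the clustering variables,
#' coloured by hard cluster, with cluster centroids overlaid — the profile
#' view used to interpret sub-groups.
#'
#' @param object A `painstrat_fcm`.
#' @param table The [normalise_01()] table the model was fitted on.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.painstrat_fcm <- function(object, table, ...) {
  if (any(table$group != "case")) table <- filter_group(table, "case")
  x <- ft_values(table)[, object$feature_names, drop = FALSE]
  x <- x[match(object$participant_id, table$participant_id), , drop = FALSE]
  pts <- tibble::as_tibble(x) |>
    dplyr::mutate(cluster = factor(object$hard_labels)) |>
    tidyr::pivot_longer(-"cluster", names_to = "variable",
                        values_to = "value")
  cents <- tibble::as_tibble(object$centroids) |>
    dplyr::mutate(cluster = factor(seq_len(object$k))) |>
    tidyr::pivot_longer(-"cluster", names_to = "variable",
                        values_to = "value")
  ggplot2::ggplot(pts, ggplot2::aes(.data$variable, .data$value,
                                    colour = .data$cluster)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.7) +
    ggplot2::geom_point(data = cents, shape = 4, size = 4, stroke = 1.5) +
    ggplot2::labs(x = NULL, y = "unit-scaled value",
                  title = "Sub-group profiles (x = centroid)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot classifier benchmark error rates
#'
#' Per-run holdout error rates by classifier with the mean and its 95%
#' confidence interval.
#'
#' @param object A `painstrat_benchmark`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.painstrat_benchmark <- function(object, ...) {
  ggplot2::ggplot(object$runs,
                  ggplot2::aes(.data$classifier, .data$error)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.5) +
    ggplot2::geom_pointrange(
      data = object$summary,
      ggplot2::aes(.data$classifier, .data$mean_error,
                   ymin = .data$ci_low, ymax = .data$ci_high),
      colour = "red"
    ) +
    ggplot2::labs(x = NULL, y = "holdout error rate",
                  title = sprintf("Classifier benchmark (%s)",
                                  object$setting)) +
    ggplot2::theme_minimal()
}
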