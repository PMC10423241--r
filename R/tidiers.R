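#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the screening result
#'
#' @param x A `painstrat_screening`.
#' @param ... Unused.
#' @return The per-variable test tibble (`variable`, group means/SDs, `t`,
#'   `df`, `p`, `q`, `selected`, `untestable`).
#' @export
tidy.painstrat_screening <- function(x, ...) x$tests

#' @rdname tidy.painstrat_screening
#' @return `glance()`: a one-row tibble with `n_tested`, `n_selected`,
#'   `n_fdr_significant`, `n_removed`, `n_surviving`.
#' @export
glance.painstrat_screening <- function(x, ...) {
  tibble::tibble(
    n_tested = nrow(x$tests),
    n_selected = sum(x$tests$selected, na.rm = TRUE),
    n_fdr_significant = sum(x$tests$q < x$alpha, na.rm = TRUE),
    n_removed = nrow(x$removed),
    n_surviving = length(x$surviving)
  )
}

#' Tidy a feature ranking
#'
#' @param x A `painstrat_ranking`.
#' @param ... Unused.
#' @return A tibble `variable`, `score`, `rank` ordered most important
#'   first.
#' @export
tidy.painstrat_ranking <- function(x, ...) {
  x$scores |>
    dplyr::mutate(rank = match(.data$variable, x$rank_order)) |>
    dplyr::arrange(.data$rank)
}

#' Tidy the cluster-validity scan
#'
#' @param x A `painstrat_validity`.
#' @param ... Unused.
#' @return The `(n_features, k)` index grid.
#' @export
tidy.painstrat_validity <- function(x, ...) x$grid

#' @rdname tidy.painstrat_validity
#' @export
glance.painstrat_validity <- function(x, ...) {
  tibble::tibble(
    selected_n_features = x$selected_n_features,
    selected_k = x$selected_k,
    confident = x$confident,
    stop_reason = x$stop_reason
  )
}

#' Tidy a fuzzy c-means model
#'
#' @param x A `painstrat_fcm`.
#' @param ... Unused.
#' @return A tibble with `participant_id`, `cluster` (hard label), and one
#'   membership column per cluster.
#' @export
tidy.painstrat_fcm <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(participant_id = x$participant_id,
                   cluster = x$hard_labels),
    tibble::as_tibble(x$membership)
  )
}

#' @rdname tidy.painstrat_fcm
#' @return `glance()`: one row with `k`, `m`, sizes, objective and the
#'   quality metrics (when filled).
#' @export
glance.painstrat_fcm <- function(x, ...) {
  tibble::tibble(
    k = x$k, m = x$m,
    sizes = paste(x$sizes, collapse = "/"),
    objective = x$objective,
    silhouette = x$silhouette_index %||% NA_real_,
    within_mean = if (is.null(x$within_cluster_distances)) NA_real_
                  else mean(x$within_cluster_distances),
    between = x$between_cluster_distance %||% NA_real_,
    discrimination = x$discrimination_value %||% NA_real_
  )
}

#' Tidy a classifier benchmark
#'
#' @param x A `painstrat_benchmark`.
#' @param ... Unused.
#' @return The per-run error tibble (`run`, `classifier`, `error`).
#' @export
tidy.painstrat_benchmark <- function(x, ...) x$runs

#' @rdname tidy.painstrat_benchmark
#' @return `glance()`: per-classifier mean errors with 95% CI and setting.
#' @export
glance.painstrat_benchmark <- function(x, ...) {
  dplyr::mutate(x$summary, setting = x$setting, n_runs = x$n_runs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
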