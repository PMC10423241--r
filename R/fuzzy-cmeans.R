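# One fuzzy c-means run from given initial centroids. Returns centroids,
# membership, objective trace. Standard alternating updates with fuzzifier
# m; points coinciding with a centroid get crisp membership there.
fcm_run <- function(x, centroids, m, tol, max_iter) {
  n <- nrow(x)
  k <- nrow(centroids)
  obj_trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    d2 <- pmax(outer(rowSums(x^2), rep(1, k)) -
                 2 * x %*% t(centroids) +
                 outer(rep(1, n), rowSums(centroids^2)), 0)
    u <- fcm_memberships(d2, m)
    um <- u^m
    new_centroids <- (t(um) %*% x) / colSums(um)
    # empty fuzzy cluster cannot occur (memberships positive), but guard NaN
    new_centroids[!is.finite(new_centroids)] <- centroids[!is.finite(new_centroids)]
    obj_trace <- c(obj_trace, sum(um * d2))
    shift <- max(abs(new_centroids - centroids))
    centroids <- new_centroids
    if (shift < tol) {
      converged <- TRUE
      break
    }
  }
  d2 <- pmax(outer(rowSums(x^2), rep(1, k)) -
               2 * x %*% t(centroids) +
               outer(rep(1, n), rowSums(centroids^2)), 0)
  u <- fcm_memberships(d2, m)
  list(centroids = centroids, membership = u,
       objective = sum(u^m * d2), objective_trace = obj_trace,
       iterations = iter, converged = converged)
}

fcm_memberships <- function(d2, m) {
  n <- nrow(d2)
  k <- ncol(d2)
  u <- matrix(0, n, k)
  zero <- d2 < 1e-300
  any_zero <- rowSums(zero) > 0
  if (any(any_zero)) {
    u[any_zero, ] <- zero[any_zero, , drop = FALSE] /
      rowSums(zero[any_zero, , drop = FALSE])
  }
  if (any(!any_zero)) {
    p <- d2[!any_zero, , drop = FALSE]^(-1 / (m - 1))
    u[!any_zero, ] <- p / rowSums(p)
  }
  u
}

#' Fuzzy c-means sub-grouping
#'
#' Derives graded sub-group memberships by fuzzy c-means: alternating
#' updates of the membership matrix and centroids minimising
#' `sum_ij u_ij^m ||x_i - c_j||^2` until the largest centroid shift falls
#' below `tol`. The best of `n_restarts` random initialisations (by final
#' objective) is kept, hard labels are the maximal membership, and cluster
#' ids are relabelled by descending size so results are deterministic under
#' a fixed seed.
#'
#' @param table A [normalise_01()] table restricted to cases.
#' @param features Variables to cluster on (e.g.
#'   `validity_scan()$selected_features`).
#' @param k Number of clusters, `>= 2`.
#' @param m Fuzzifier, `> 1` (default 2).
#' @param tol Centroid-shift convergence tolerance (default 1e-5).
#' @param max_iter Maximum alternating updates per restart (default 1000).
#' @param n_restarts Random restarts (default 20).
#' @param seed Integer seed.
#' @return A `painstrat_fcm` object with `centroids` (k x features, unit
#'   scale), `membership` (participants x k, rows sum to 1), `hard_labels`
#'   (named integer vector), `sizes`, `objective`, and — after
#'   [cluster_metrics()] — `within_cluster_distances`,
#'   `between_cluster_distance`, `silhouette_index`,
#'   `discrimination_value`.
#' @export
#' @examples
#' nt <- normalise_01(toy_feature_table())
#' fuzzy_cmeans(nt, c("depressive_symptoms", "lumbar_ppt"), k = 2, seed = 1)
fuzzy_cmeans <- function(table, features = ft_variables(table), k = 2,
                         m = 2, tol = 1e-5, max_iter = 1000,
                         n_restarts = 20, seed = 1) {
  if (k < 2) abort_contract("k must be >= 2.")
  if (m <= 1) abort_contract("Fuzzifier m must be > 1.")
  if (any(table$group != "case")) table <- filter_group(table, "case")
  x <- ft_values(table)[, features, drop = FALSE]
  complete <- stats::complete.cases(x)
  if (any(!complete)) {
    rlang::inform(sprintf("fuzzy_cmeans: dropping %d incomplete row(s).",
                          sum(!complete)))
    x <- x[complete, , drop = FALSE]
  }
  n <- nrow(x)
  if (k > n) abort_contract("k cannot exceed the number of rows.")
  degenerate <- nrow(unique(as.data.frame(x))) == 1
  if (degenerate) {
    rlang::warn("All rows identical: memberships are uniform 1/k.")
  }
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- x[sample(n, k), , drop = FALSE] +
      matrix(stats::rnorm(k * ncol(x), sd = 1e-4), k)
    run <- fcm_run(x, init, m = m, tol = tol, max_iter = max_iter)
    if (is.null(best) || run$objective < best$objective) best <- run
  }
  if (!best$converged) {
    rlang::warn(sprintf(
      "fuzzy_cmeans did not converge in %d iterations (objective %.6g).",
      max_iter, best$objective))
  }
  hard <- max.col(best$membership, ties.method = "first")
  # relabel by descending hard-cluster size (ties: original id)
  sizes <- tabulate(hard, nbins = k)
  relabel <- order(order(-sizes, seq_len(k)))
  hard <- relabel[hard]
  membership <- best$membership[, order(-sizes, seq_len(k)), drop = FALSE]
  centroids <- best$centroids[order(-sizes, seq_len(k)), , drop = FALSE]
  colnames(centroids) <- features
  rownames(centroids) <- paste0("cluster_", seq_len(k))
  colnames(membership) <- rownames(centroids)
  names(hard) <- table$participant_id[complete]
  structure(
    list(
      feature_names = features, k = k, m = m,
      centroids = centroids, membership = membership,
      hard_labels = hard, sizes = tabulate(hard, nbins = k),
      objective = best$objective, objective_trace = best$objective_trace,
      iterations = best$iterations, seed = seed,
      participant_id = table$participant_id[complete],
      within_cluster_distances = NULL, between_cluster_distance = NULL,
      silhouette_index = NULL, discrimination_value = NULL
    ),
    class = "painstrat_fcm"
  )
}

#' @export
print.painstrat_fcm <- function(x, ...) {
  cat(sprintf(
    "<fuzzy c-means> k = %d (sizes %s), m = %g, %d features, objective %.4g\n",
    x$k, paste(x$sizes, collapse = "/"), x$m, length(x$feature_names),
    x$objective
  ))
  if (!is.null(x$silhouette_index)) {
    cat(sprintf(
      "  silhouette %.2f; within %s; between %.2f; discrimination %.2f\n",
      x$silhouette_index,
      paste(sprintf("%.2f", x$within_cluster_distances), collapse = "/"),
      x$between_cluster_distance, x$discrimination_value
    ))
  }
  invisible(x)
}

#' Cluster-quality metrics for a fuzzy c-means model
#'
#' Fills the model's quality metrics on the unit scale: the mean Euclidean
#' distance of each cluster's members to its centroid (within-cluster
#' distance), the mean pairwise centroid distance (between-cluster
#' distance), the mean silhouette width over participants using hard
#' labels (singletons contribute 0), and a discrimination value measuring
#' cluster density: `log10(mean within-cluster squared distance / mean
#' squared centroid separation)` — more negative means denser, better
#' separated clusters.
#'
#' @param model A `painstrat_fcm` from [fuzzy_cmeans()].
#' @param table The same [normalise_01()] table the model was fitted on.
#' @return The model with metric fields filled.
#' @export
cluster_metrics <- function(model, table) {
  if (any(table$group != "case")) table <- filter_group(table, "case")
  x <- ft_values(table)[, model$feature_names, drop = FALSE]
  x <- x[match(model$participant_id, table$participant_id), , drop = FALSE]
  hard <- model$hard_labels
  k <- model$k
  if (length(unique(hard)) < 2) {
    abort_contract("Metrics need at least 2 non-empty hard clusters.")
  }
  within <- vapply(seq_len(k), function(c) {
    members <- x[hard == c, , drop = FALSE]
    if (nrow(members) == 0) return(NA_real_)
    mean(sqrt(rowSums(sweep(members, 2, model$centroids[c, ])^2)))
  }, numeric(1))
  centroid_d <- stats::dist(model$centroids)
  between <- mean(centroid_d)
  sil <- mean_silhouette(x, hard)
  within_var <- vapply(seq_len(k), function(c) {
    members <- x[hard == c, , drop = FALSE]
    if (nrow(members) == 0) return(NA_real_)
    mean(rowSums(sweep(members, 2, model$centroids[c, ])^2))
  }, numeric(1))
  discrimination <- log10(mean(within_var, na.rm = TRUE) / mean(centroid_d^2))
  model$within_cluster_distances <- within
  model$between_cluster_distance <- between
  model$silhouette_index <- sil
  model$discrimination_value <- discrimination
  model
}
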