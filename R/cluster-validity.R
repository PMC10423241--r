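# Internal cluster validity indices on a hard partition.
# labels: integer vector; x: numeric matrix.

calinski_harabasz <- function(x, labels) {
  n <- nrow(x)
  k <- length(unique(labels))
  if (k < 2 || k >= n) return(NA_real_)
  centre <- colMeans(x)
  ssb <- 0
  ssw <- 0
  for (c in unique(labels)) {
    xi <- x[labels == c, , drop = FALSE]
    ci <- colMeans(xi)
    ssb <- ssb + nrow(xi) * sum((ci - centre)^2)
    ssw <- ssw + sum(sweep(xi, 2, ci)^2)
  }
  if (ssw == 0) return(Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

davies_bouldin <- function(x, labels) {
  cl <- sort(unique(labels))
  k <- length(cl)
  if (k < 2) return(NA_real_)
  centroids <- do.call(rbind, lapply(cl, function(c) {
    colMeans(x[labels == c, , drop = FALSE])
  }))
  scatter <- vapply(seq_along(cl), function(i) {
    xi <- x[labels == cl[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xi, 2, centroids[i, ])^2)))
  }, numeric(1))
  r <- numeric(k)
  for (i in seq_len(k)) {
    ratios <- vapply(setdiff(seq_len(k), i), function(j) {
      d <- sqrt(sum((centroids[i, ] - centroids[j, ])^2))
      if (d == 0) return(Inf)
      (scatter[i] + scatter[j]) / d
    }, numeric(1))
    r[i] <- max(ratios)
  }
  mean(r)
}

mean_silhouette <- function(x, labels) {
  if (length(unique(labels)) < 2) return(NA_real_)
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(x))
  mean(sil[, "sil_width"])
}

#' Incremental cluster-validity scan over ranked features
#'
#' Decides how many of the ranked features to cluster on, and with how many
#' clusters, by adding features one at a time in ranking order. For every
#' feature count `j` and every `k` in `k_range`, a multi-restart k-means
#' partition is fitted on the first `j` features and then scored with the
#' Calinski-Harabasz (higher better), Davies-Bouldin (lower better) and
#' mean silhouette (higher better) indices.
#'
#' All three indices are evaluated on the *full* ranked-feature space, not
#' the `j`-feature subspace: index values are only comparable between
#' partitions when they are measured on a common metric space, whereas
#' raw subspace values are systematically inflated for few features (in one
#' dimension k-means can fragment any sample into tight intervals). Scoring
#' every candidate partition on the same space asks the meaningful
#' question — which feature subset yields the partition that best explains
#' the structure of the candidate data — and makes the scan's comparisons
#' well-defined.
#'
#' A feature count is accepted when all three indices improve at their own
#' best k over the previous accepted count; the scan stops at the first
#' count that is not an improvement, selecting the previous one. Requiring
#' consensus matters: a genuinely informative feature sharpens the
#' partition and moves all three indices together, while an appended
#' uninformative feature at best leaves the partition unchanged (tying
#' every index) or perturbs it so that single indices drift apart by
#' chance. The cluster number is the silhouette-maximising k at the
#' selected feature count (ties toward smaller k).
#'
#' @param table A [normalise_01()] table restricted to cases.
#' @param ranking A `painstrat_ranking` (typically from [laplacian_rank()]).
#' @param k_range Candidate cluster numbers, min >= 2, max < n (default
#'   `2:6`).
#' @param max_features Cap on scanned feature counts; default all ranked.
#' @param nstart k-means restarts per fit (default 20).
#' @param seed Integer seed.
#' @return A `painstrat_validity` object: `grid` (tibble `n_features`, `k`,
#'   `ch`, `db`, `silhouette`, full-space values), `selected_n_features`,
#'   `selected_k`, `selected_features`, `confident` (`FALSE` when even the
#'   best silhouette stays below 0.3, i.e. no convincing structure),
#'   `stop_reason`.
#' @export
validity_scan <- function(table, ranking, k_range = 2:6, max_features = NULL,
                          nstart = 20, seed = 1) {
  if (any(table$group != "case")) table <- filter_group(table, "case")
  features <- ranking$rank_order
  if (length(features) < 1) abort_contract("Ranking has no features.")
  if (is.null(max_features)) max_features <- length(features)
  max_features <- min(max_features, length(features))
  x_all <- ft_values(table)[, features, drop = FALSE]
  complete <- stats::complete.cases(x_all)
  x_all <- x_all[complete, , drop = FALSE]
  n <- nrow(x_all)
  if (min(k_range) < 2) abort_contract("k_range minimum must be >= 2.")
  k_range <- k_range[k_range < n]
  if (length(k_range) == 0) abort_contract("k_range has no k below n.")
  set.seed(seed)
  grid <- list()
  best <- NULL # per-index values at the last accepted count
  selected <- 1L
  stop_reason <- "scanned all features"
  for (j in seq_len(max_features)) {
    xj <- x_all[, seq_len(j), drop = FALSE]
    rows <- purrr::map_dfr(k_range, function(k) {
      km <- stats::kmeans(xj, centers = k, nstart = nstart, iter.max = 100)
      tibble::tibble(
        n_features = j, k = k,
        ch = calinski_harabasz(x_all, km$cluster),
        db = davies_bouldin(x_all, km$cluster),
        silhouette = mean_silhouette(x_all, km$cluster)
      )
    })
    grid[[j]] <- rows
    cur <- list(ch = max(rows$ch, na.rm = TRUE),
                db = min(rows$db, na.rm = TRUE),
                silhouette = max(rows$silhouette, na.rm = TRUE))
    if (j == 1) {
      best <- cur
      selected <- 1L
    } else {
      votes <- sum(cur$ch > best$ch, cur$db < best$db,
                   cur$silhouette > best$silhouette)
      if (votes == 3) {
        best <- cur
        selected <- j
      } else {
        stop_reason <- sprintf(
          "performance did not improve at %d features (%d/3 indices)",
          j, votes)
        break
      }
    }
  }
  grid <- dplyr::bind_rows(grid)
  sel_rows <- grid[grid$n_features == selected, ]
  sel_k <- sel_rows$k[which.max(sel_rows$silhouette)]
  low_sil <- max(sel_rows$silhouette, na.rm = TRUE) < 0.3
  structure(
    list(grid = grid,
         selected_n_features = selected,
         selected_k = as.integer(sel_k),
         selected_features = features[seq_len(selected)],
         confident = !low_sil,
         stop_reason = stop_reason),
    class = "painstrat_validity"
  )
}

#' @export
print.painstrat_validity <- function(x, ...) {
  cat(sprintf(
    "<validity scan> selected %d feature(s), k = %d (%s)%s\n",
    x$selected_n_features, x$selected_k, x$stop_reason,
    if (!x$confident) " [low silhouette: no confident structure]" else ""
  ))
  cat("  features:", paste(x$selected_features, collapse = ", "), "\n")
  invisible(x)
}
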