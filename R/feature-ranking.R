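new_ranking <- function(method, scores, rank_order) {
  structure(
    list(method = method,
         scores = tibble::tibble(variable = names(scores),
                                 score = unname(scores)),
         rank_order = rank_order),
    class = "painstrat_ranking"
  )
}

#' @export
print.painstrat_ranking <- function(x, ...) {
  cat(sprintf("<ranking: %s> %d variables\n", x$method, nrow(x$scores)))
  cat("  ", paste(utils::head(x$rank_order, 8), collapse = " > "),
      if (length(x$rank_order) > 8) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' Random-forest case/control feature weighting
#'
#' Fits a random-forest classifier of case vs control on the (unit-scaled)
#' candidate variables and ranks them by out-of-bag permutation importance
#' (mean decrease in accuracy), the step that weights how much each
#' variable helps separate cases from controls before the case-only
#' analyses.
#'
#' @param table A [normalise_01()] table containing both groups.
#' @param variables Candidate variables; default all.
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed; importances are reproducible under a fixed
#'   seed.
#' @return A `painstrat_ranking` (method `"rf_importance"`); `rank_order`
#'   sorts by descending importance.
#' @export
rf_feature_weighting <- function(table, variables = ft_variables(table),
                                 n_trees = 500, seed = 1) {
  vals <- ft_values(table)[, variables, drop = FALSE]
  y <- factor(table$group, levels = c("control", "case"))
  if (length(unique(table$group)) < 2) {
    abort_contract("Both case and control labels are required.")
  }
  complete <- stats::complete.cases(vals)
  if (sum(!complete) > 0) {
    rlang::inform(sprintf(
      "rf_feature_weighting: dropping %d incomplete row(s).", sum(!complete)
    ))
  }
  set.seed(seed)
  fit <- randomForest::randomForest(
    x = as.data.frame(vals[complete, , drop = FALSE]),
    y = y[complete], ntree = n_trees, importance = TRUE
  )
  imp <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
  ord <- names(sort(imp, decreasing = TRUE))
  new_ranking("rf_importance", imp[variables], ord)
}

# Laplacian score of each feature on a kNN heat-kernel graph.
# W_ij = exp(-||xi - xj||^2 / t) when i, j are mutual-or-either kNN,
# D = diag(W 1), L = D - W; for feature f demeaned with D-weights,
# score = (f' L f) / (f' D f). Smaller = the feature varies little between
# graph neighbours relative to its overall variance = more informative.
laplacian_scores <- function(x, k_neighbours = 5, bandwidth = NULL) {
  n <- nrow(x)
  if (k_neighbours >= n) {
    abort_contract("k_neighbours must be smaller than the number of rows.")
  }
  if (anyNA(x)) abort_contract("Laplacian scoring requires complete data.")
  d2 <- as.matrix(stats::dist(x))^2
  if (is.null(bandwidth)) {
    bandwidth <- mean(d2[upper.tri(d2)])
    if (bandwidth <= 0) bandwidth <- 1 # all points identical; weights all 1
  }
  W <- exp(-d2 / bandwidth)
  # keep only k-nearest-neighbour edges, symmetrised (edge if either end
  # lists the other as a neighbour)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[2:(k_neighbours + 1)]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  W[!adj] <- 0
  diag(W) <- 0
  deg <- rowSums(W)
  scores <- apply(x, 2, function(f) {
    fbar <- sum(f * deg) / sum(deg)
    ft <- f - fbar
    denom <- sum(deg * ft^2)
    if (denom < 1e-12) return(Inf) # constant feature: least informative
    num <- sum(deg * ft^2) - as.numeric(t(ft) %*% W %*% ft)
    num / denom
  })
  scores
}

#' Laplacian-score feature ranking within cases
#'
#' Ranks features by how well they preserve the local neighbourhood
#' structure of the case-only data: a symmetric k-nearest-neighbour graph
#' with heat-kernel weights is built over participants, and each demeaned
#' feature is scored by its graph-Laplacian quadratic form relative to its
#' degree-weighted variance. Smaller scores indicate features aligned with
#' the intrinsic structure; `rank_order` sorts ascending, most important
#' first. Constant features score `Inf` (least informative).
#'
#' @param table A [normalise_01()] table restricted to cases (rows with
#'   other groups are dropped with a message).
#' @param variables Variables to score; default all.
#' @param k_neighbours Neighbourhood size of the graph (default 5).
#' @param bandwidth Heat-kernel bandwidth; default (`NULL`) the mean
#'   pairwise squared Euclidean distance.
#' @return A `painstrat_ranking` (method `"laplacian"`).
#' @export
laplacian_rank <- function(table, variables = ft_variables(table),
                           k_neighbours = 5, bandwidth = NULL) {
  if (any(table$group != "case")) {
    rlang::inform("laplacian_rank: restricting to case rows.")
    table <- filter_group(table, "case")
  }
  x <- ft_values(table)[, variables, drop = FALSE]
  scores <- laplacian_scores(x, k_neighbours = k_neighbours,
                             bandwidth = bandwidth)
  ord <- names(sort(scores)) # ascending: smallest score most important
  new_ranking("laplacian", scores, ord)
}
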