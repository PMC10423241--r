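test_that("fuzzy c-means solves the two-point problem exactly", {
  d <- tibble::tibble(participant_id = c("a", "b"), group = "case",
                      x = c(0, 1), y = c(0, 1))
  tab <- feature_table(d, variable_meta(c("x", "y"), "other", -1, 2))
  m <- fuzzy_cmeans(tab, k = 2, n_restarts = 5, seed = 1)
  expect_equal(sort(m$centroids[, "x"]), c(0, 1), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(unname(apply(m$membership, 1, max)), c(1, 1),
               tolerance = 1e-6)
  expect_equal(sort(m$hard_labels), 1:2, ignore_attr = TRUE)
})

test_that("identical participants yield uniform memberships with a warning", {
  d <- tibble::tibble(participant_id = sprintf("i%02d", 1:6), group = "case",
                      x = 0.4, y = 0.6)
  tab <- feature_table(d, variable_meta(c("x", "y"), "other", 0, 1))
  expect_warning(m <- fuzzy_cmeans(tab, k = 3, n_restarts = 2, seed = 1),
                 "identical")
  expect_equal(unname(m$membership), matrix(1 / 3, 6, 3), tolerance = 1e-6)
})

test_that("memberships are a proper row-stochastic matrix and the objective non-increasing", {
  for (s in 1:5) {
    p <- make_planted_blobs(400 + s, n = 30)
    nt <- suppressWarnings(normalise_01(p$table))
    m <- fuzzy_cmeans(nt, k = 3, seed = s)
    expect_equal(unname(rowSums(m$membership)), rep(1, 30), tolerance = 1e-6)
    expect_true(all(m$membership >= 0 & m$membership <= 1))
    expect_true(all(diff(m$objective_trace) <= 1e-8))
    expect_equal(unname(m$hard_labels),
                 unname(max.col(m$membership, ties.method = "first")))
  }
})

test_that("fuzzy c-means agrees with an independent implementation", {
  p <- make_planted_blobs(41, n = 40)
  nt <- suppressWarnings(normalise_01(p$table))
  x <- ft_values(nt)[, c("f1", "f2")]
  ours <- fuzzy_cmeans(nt, c("f1", "f2"), k = 2, seed = 2)
  set.seed(2)
  ref <- e1071::cmeans(x, centers = 2, m = 2, iter.max = 200)
  # same partition (up to label switching) and same objective value
  agree <- mean((ours$hard_labels == 1) == (ref$cluster == ref$cluster[1]))
  expect_true(agree %in% c(0, 1))
  # centroids coincide up to label order
  ours_c <- ours$centroids[order(ours$centroids[, "f1"]), ]
  ref_c <- ref$centers[order(ref$centers[, "f1"]), ]
  expect_equal(unname(ours_c), unname(ref_c), tolerance = 1e-3)
})

test_that("with a near-crisp fuzzifier the partition matches k-means", {
  p <- make_planted_blobs(42, n = 40, sep = 5)
  nt <- suppressWarnings(normalise_01(p$table))
  x <- ft_values(nt)[, c("f1", "f2")]
  m <- fuzzy_cmeans(nt, c("f1", "f2"), k = 2, m = 1.05, seed = 3)
  set.seed(3)
  km <- stats::kmeans(x, 2, nstart = 10)
  agree <- mean((m$hard_labels == 1) == (km$cluster == km$cluster[1]))
  expect_true(agree %in% c(0, 1))
})

test_that("clusters are relabelled by descending size", {
  p <- make_planted_blobs(43, n = 40)
  # unbalance the blobs: drop half of blob 2
  keep <- c(which(p$labels == 1), which(p$labels == 2)[1:8])
  tab <- painstrat:::restore_ft(p$table[keep, ], p$table)
  nt <- suppressWarnings(normalise_01(tab))
  m <- fuzzy_cmeans(nt, c("f1", "f2"), k = 2, seed = 4)
  expect_true(m$sizes[1] >= m$sizes[2])
  expect_equal(sum(m$sizes), length(keep))
})

test_that("cluster metrics behave on a geometric two-blob construction", {
  p <- make_planted_blobs(44, n = 40, sep = 20)
  nt <- suppressWarnings(normalise_01(p$table))
  m <- fuzzy_cmeans(nt, c("f1", "f2"), k = 2, seed = 5)
  m <- cluster_metrics(m, nt)
  expect_gt(m$silhouette_index, 0.9)
  expect_lt(max(m$within_cluster_distances), m$between_cluster_distance)
  expect_lt(m$discrimination_value, 0) # dense, separated clusters
  g <- glance(m)
  expect_equal(g$silhouette, m$silhouette_index)
})

test_that("metrics require at least two non-empty hard clusters", {
  d <- tibble::tibble(participant_id = sprintf("i%02d", 1:8), group = "case",
                      x = c(rep(0, 7), 10), y = 0)
  tab <- feature_table(d, variable_meta(c("x", "y"), "other", -1, 11))
  m <- fuzzy_cmeans(tab, k = 2, seed = 1, n_restarts = 3)
  m$hard_labels[] <- 1L
  expect_error(cluster_metrics(m, tab), class = "painstrat_contract_error")
})

test_that("a singleton cluster contributes silhouette zero, logged not fatal", {
  d <- tibble::tibble(participant_id = sprintf("i%02d", 1:8), group = "case",
                      x = c(rep(0.1, 7), 0.9), y = c(rep(0.1, 7), 0.9))
  tab <- feature_table(d, variable_meta(c("x", "y"), "other", 0, 1))
  m <- fuzzy_cmeans(tab, k = 2, seed = 1, n_restarts = 5)
  m <- cluster_metrics(m, tab)
  expect_true(is.finite(m$silhouette_index))
  expect_equal(m$sizes, c(7L, 1L))
})

test_that("validity_scan recovers planted two-feature two-cluster structure", {
  res <- vapply(1:25, function(s) {
    p <- make_planted_blobs(s)
    nt <- suppressWarnings(normalise_01(p$table))
    v <- validity_scan(nt, p$ranking, seed = s)
    v$selected_n_features == 2 && v$selected_k == 2
  }, logical(1))
  expect_gte(mean(res), 0.8) # full 100-seed check in the acceptance suite
})

test_that("a structureless blob is flagged as no confident selection", {
  set.seed(77)
  n <- 40
  d <- tibble::tibble(participant_id = sprintf("i%02d", 1:n), group = "case")
  for (i in 1:4) d[[paste0("v", i)]] <- stats::rnorm(n)
  tab <- feature_table(d, variable_meta(paste0("v", 1:4), "other", -10, 10))
  nt <- normalise_01(tab)
  rk <- laplacian_rank(nt)
  v <- validity_scan(nt, rk, seed = 1)
  expect_false(v$confident)
  expect_true(all(v$grid$silhouette < 0.5))
})

test_that("validity_scan selections are invariant to participant order", {
  p <- make_planted_blobs(61)
  nt <- suppressWarnings(normalise_01(p$table))
  v1 <- validity_scan(nt, p$ranking, seed = 9)
  set.seed(123)
  perm <- painstrat:::restore_ft(nt[sample(nrow(nt)), ], nt)
  v2 <- validity_scan(perm, p$ranking, seed = 9)
  expect_equal(v1$selected_n_features, v2$selected_n_features)
  expect_equal(v1$selected_k, v2$selected_k)
})

test_that("validity_scan validates its contract", {
  p <- make_planted_blobs(62, n = 10)
  nt <- suppressWarnings(normalise_01(p$table))
  expect_error(validity_scan(nt, p$ranking, k_range = 1:3),
               class = "painstrat_contract_error")
  expect_error(validity_scan(nt, p$ranking, k_range = 30:40),
               class = "painstrat_contract_error")
})
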