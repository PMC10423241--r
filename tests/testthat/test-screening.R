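test_that("bh_fdr agrees with the brute-force step-up oracle", {
  set.seed(7)
  for (i in 1:40) {
    m <- sample(1:12, 1)
    p <- round(stats::runif(m), 3)
    expect_equal(bh_fdr(p), bh_brute_force(p), tolerance = 1e-7)
    # and with the reference implementation
    expect_equal(bh_fdr(p), stats::p.adjust(p, method = "BH"))
  }
})

test_that("bh_fdr handles ties, single values, missing and bad input", {
  expect_equal(bh_fdr(rep(0.01, 10)), rep(0.01, 10))
  expect_equal(bh_fdr(0.37), 0.37)
  q <- bh_fdr(c(0.01, NA, 0.5))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], stats::p.adjust(c(0.01, 0.5), "BH"))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "painstrat_domain_error")
  # q >= p always, monotone in p-rank
  set.seed(1)
  p <- stats::runif(30)
  q <- bh_fdr(p)
  expect_true(all(q >= p - 1e-12))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("identical groups give p near 1 and no selections", {
  half <- tibble::tibble(x = stats::rnorm(10), y = stats::rnorm(10))
  d <- tibble::tibble(
    participant_id = sprintf("i%02d", 1:20),
    group = rep(c("case", "control"), each = 10),
    x = rep(half$x, 2), y = rep(half$y, 2)
  )
  tab <- feature_table(d, variable_meta(c("x", "y"), "other", -10, 10))
  res <- group_t_tests(tab)
  expect_true(all(res$p > 0.999))
  expect_false(any(res$selected))
})

test_that("t-tests are invariant to row permutation and affine rescaling", {
  tab <- make_shifted_table(21)
  res <- group_t_tests(tab)
  # permute rows
  perm <- tab[sample(nrow(tab)), ]
  perm <- painstrat:::restore_ft(perm, tab)
  res_p <- group_t_tests(perm)
  expect_equal(res_p$t, res$t)
  expect_equal(res_p$p, res$p)
  # rescale one variable affinely
  resc <- tab
  resc$big <- 3.5 * resc$big - 100
  res_r <- group_t_tests(resc)
  expect_equal(res_r$t, res$t, tolerance = 1e-9)
  expect_equal(res_r$p, res$p, tolerance = 1e-9)
})

test_that("a variable with a too-small group is marked untestable", {
  tab <- make_shifted_table(22, n_per_group = 5)
  tab$big[tab$group == "case"][2:5] <- NA
  res <- group_t_tests(tab)
  expect_true(res$untestable[res$variable == "big"])
  expect_true(is.na(res$p[res$variable == "big"]))
  expect_false(any(res$untestable[res$variable != "big"]))
})

test_that("a duplicated column loses exactly one member to the collinearity filter", {
  tab <- make_shifted_table(23)
  tab$big_copy <- tab$big
  meta <- dplyr::bind_rows(ft_meta(make_shifted_table(23)),
                           variable_meta("big_copy", "other", -20, 20))
  tab2 <- feature_table(tibble::as_tibble(as.data.frame(tab)), meta)
  cf <- collinearity_filter(tab2, c("big", "big_copy", "noise1"))
  expect_length(intersect(cf$kept, c("big", "big_copy")), 1)
  expect_true("noise1" %in% cf$kept)
  expect_equal(nrow(cf$removed), 1)
  # a negated duplicate is equally collinear
  tab2$big_copy <- -tab2$big
  cf2 <- collinearity_filter(tab2, c("big", "big_copy"))
  expect_length(cf2$kept, 1)
})

test_that("independent columns are never removed at the 0.8 threshold", {
  removals <- vapply(1:50, function(s) {
    set.seed(s)
    d <- tibble::tibble(participant_id = sprintf("i%02d", 1:40),
                        group = rep(c("case", "control"), 20))
    for (i in 1:6) d[[paste0("v", i)]] <- stats::rnorm(40)
    tab <- feature_table(d, variable_meta(paste0("v", 1:6), "other", -10, 10))
    nrow(collinearity_filter(tab)$removed)
  }, numeric(1))
  expect_lte(sum(removals > 0), 1) # >= 98% of seeds clean
})

test_that("the tie rule drops the less significant member of a collinear pair", {
  tab <- make_shifted_table(24)
  tab$big_twin <- tab$big + stats::rnorm(nrow(tab), sd = 0.01)
  meta <- dplyr::bind_rows(ft_meta(make_shifted_table(24)),
                           variable_meta("big_twin", "other", -20, 20))
  tab2 <- feature_table(tibble::as_tibble(as.data.frame(tab)), meta)
  pv <- c(big = 0.001, big_twin = 0.04)
  cf <- collinearity_filter(tab2, c("big", "big_twin"), p_values = pv)
  expect_equal(cf$removed$variable, "big_twin")
  # with no p-values the later column goes
  cf2 <- collinearity_filter(tab2, c("big", "big_twin"))
  expect_equal(cf2$removed$variable, "big_twin")
})

test_that("zero-variance candidates are excluded with a reason", {
  tab <- make_shifted_table(25)
  tab$flat <- 1
  meta <- dplyr::bind_rows(ft_meta(make_shifted_table(25)),
                           variable_meta("flat", "other", 0, 10))
  tab2 <- feature_table(tibble::as_tibble(as.data.frame(tab)), meta)
  cf <- collinearity_filter(tab2, c("big", "flat"))
  expect_equal(cf$removed$variable, "flat")
  expect_match(cf$removed$reason, "variance")
})

test_that("screen_features composes tests, filtering and forced removal", {
  tab <- make_shifted_table(26, shifts = c(big = 2, med = 1.2))
  tab$big_copy <- tab$big
  meta <- dplyr::bind_rows(ft_meta(tab),
                           variable_meta("big_copy", "other", -20, 20))
  tab2 <- feature_table(tibble::as_tibble(as.data.frame(tab)), meta)
  scr <- screen_features(tab2, force_remove = "med")
  expect_s3_class(scr, "painstrat_screening")
  # the duplicated pair lost one member, the forced variable is gone
  expect_length(intersect(scr$surviving, c("big", "big_copy")), 1)
  expect_false("med" %in% scr$surviving)
  expect_true("forced removal" %in% scr$removed$reason)
  # surviving set has no collinear pair left
  if (length(scr$surviving) >= 2) {
    cm <- stats::cor(ft_values(tab2)[, scr$surviving],
                     use = "pairwise.complete.obs")
    expect_true(all(abs(cm[upper.tri(cm)]) <= 0.8))
  }
  g <- glance(scr)
  expect_equal(g$n_surviving, length(scr$surviving))
  expect_tibble(tidy(scr))
})
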