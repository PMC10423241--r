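test_that("the default cohort matches the published group structure", {
  cfg <- default_cohort_config()
  expect_equal(vapply(cfg$groups, `[[`, integer(1), "n"), c(21L, 16L, 5L))
  cf <- vapply(cfg$groups, function(g) g$means[["cognitive_function"]],
               numeric(1))
  expect_equal(cf, c(36.2, 35.8, 19.8))
  cf_sd <- vapply(cfg$groups, function(g) g$sds[["cognitive_function"]],
                  numeric(1))
  expect_equal(cf_sd, c(4.4, 4.1, 2.5))
  dep <- vapply(cfg$groups, function(g) g$means[["depressive_symptoms"]],
                numeric(1))
  expect_equal(dep, c(8.8, 9.4, 20.6))
  expect_equal(vapply(cfg$groups, function(g) g$sds[["depressive_symptoms"]],
                      numeric(1)), c(1.3, 1.8, 6.9))
  # 10 nuisance variables in each of the three biopsychosocial domains
  nuis <- cfg$meta[grepl("^nuis_", cfg$meta$name), ]
  expect_equal(unname(table(nuis$domain)[c("nervous", "psychosocial",
                                           "spinal")]),
               rep(10L, 3), ignore_attr = TRUE)
})

test_that("an identical seed reproduces the cohort exactly", {
  a <- suppressWarnings(generate_cohort(seed = 42))
  b <- suppressWarnings(generate_cohort(seed = 42))
  expect_identical(a$table, b$table)
  expect_identical(a$latent, b$latent)
  c <- suppressWarnings(generate_cohort(seed = 43))
  expect_false(identical(ft_values(a$table), ft_values(c$table)))
})

test_that("zero-SD groups collapse onto their means", {
  meta <- variable_meta(c("u", "v"), "other", 0, 50)
  grp <- function(lab, n, mu) {
    group_spec(lab, n, means = c(u = mu, v = mu + 1), sds = c(u = 0, v = 0))
  }
  cfg <- synthetic_config(list(grp("control", 4, 10), grp("subgroup_1", 3, 20),
                               grp("subgroup_2", 2, 30)), meta)
  co <- generate_cohort(cfg, seed = 1)
  vals <- ft_values(co$table)
  expect_equal(unname(vals[co$latent$subgroup == "subgroup_2", "u"]),
               rep(30, 2))
  expect_equal(unname(vals[co$latent$subgroup == "control", "v"]),
               rep(11, 4))
})

test_that("generated values respect the declared scale bounds", {
  for (s in 1:5) {
    co <- suppressWarnings(generate_cohort(seed = s))
    vals <- ft_values(co$table)
    meta <- ft_meta(co$table)
    for (i in seq_len(nrow(meta))) {
      expect_true(all(vals[, meta$name[i]] >= meta$scale_min[i]))
      expect_true(all(vals[, meta$name[i]] <= meta$scale_max[i]))
    }
  }
})

test_that("discrete pain-site counts come out as integers", {
  co <- suppressWarnings(generate_cohort(seed = 5))
  vals <- ft_values(co$table)
  expect_equal(vals[, "pain_sites_12m"], round(vals[, "pain_sites_12m"]))
  expect_equal(vals[, "pain_sites_7d"], round(vals[, "pain_sites_7d"]))
})

test_that("the sub-group #2 cognitive-function mean is recovered across replicates", {
  # Monte-Carlo check of the generator against its own parameters:
  # mean of 200 sub-group #2 cognitive-function draws (5 per cohort)
  # should sit within 3 standard errors of 19.8 (no clipping: the scale
  # bounds are > 4 SDs away).
  means <- vapply(1:40, function(s) {
    co <- suppressWarnings(generate_cohort(seed = 1000 + s))
    idx <- co$latent$subgroup == "subgroup_2"
    mean(ft_values(co$table)[idx, "cognitive_function"])
  }, numeric(1))
  n_draws <- 40 * 5
  se <- 2.5 / sqrt(n_draws)
  expect_lt(abs(mean(means) - 19.8), 3 * se)
})

test_that("declared correlations appear in the generated data", {
  cor_tbl <- tibble::tibble(var1 = "depressive_symptoms",
                            var2 = "anxiety_symptoms", rho = 0.6)
  cfg <- default_cohort_config(correlation = cor_tbl)
  # pool within-control-group sample correlations across replicates
  rs <- vapply(1:30, function(s) {
    co <- suppressWarnings(generate_cohort(cfg, seed = 2000 + s))
    ctl <- co$table$group == "control"
    stats::cor(co$table$depressive_symptoms[ctl],
               co$table$anxiety_symptoms[ctl])
  }, numeric(1))
  expect_gt(mean(rs), 0.4)
  expect_lt(mean(rs), 0.8)
})

test_that("an impossible correlation matrix is a configuration error", {
  bad <- tibble::tibble(
    var1 = c("depressive_symptoms", "depressive_symptoms",
             "anxiety_symptoms"),
    var2 = c("anxiety_symptoms", "cognitive_function",
             "cognitive_function"),
    rho = c(0.95, 0.95, -0.95)
  )
  expect_error(generate_cohort(default_cohort_config(correlation = bad)),
               class = "painstrat_contract_error")
})

test_that("with no group shifts the screening flags about alpha of variables", {
  # nuisance-only cohort: every variable shared mean/SD across groups, so
  # Step-1 selections are pure type-I errors at rate alpha
  n_sel <- vapply(1:25, function(s) {
    cfg <- default_cohort_config(n_nuisance = 20)
    # flatten the real variables too: give every group the control profile
    for (i in 2:3) {
      cfg$groups[[i]]$means <- cfg$groups[[1]]$means
      cfg$groups[[i]]$sds <- cfg$groups[[1]]$sds
    }
    co <- suppressWarnings(generate_cohort(cfg, seed = 3000 + s))
    sum(group_t_tests(co$table)$selected)
  }, numeric(1))
  m <- 71 * 25 # variables times replicates
  expect_lt(sum(n_sel), stats::qbinom(0.999, m, 0.05) + 1)
  expect_gt(sum(n_sel), stats::qbinom(0.001, m, 0.05) - 1)
})
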