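# Shared fixtures, generated in code.

# Two well-separated Gaussian blobs in two informative features (per-feature
# separation 3.2 within-blob SDs, so that neither feature alone separates
# perfectly but the pair does) plus six appended standard-normal noise
# features. Used for planted-structure recovery checks.
make_planted_blobs <- function(seed, n = 60, sep = 3.2, n_noise = 6) {
  set.seed(seed)
  lab <- rep(1:2, each = n / 2)
  d <- tibble::tibble(
    participant_id = sprintf("p%03d", seq_len(n)),
    group = "case",
    f1 = stats::rnorm(n, mean = ifelse(lab == 2, sep, 0)),
    f2 = stats::rnorm(n, mean = ifelse(lab == 2, sep, 0))
  )
  for (i in seq_len(n_noise)) {
    d[[paste0("noise", i)]] <- stats::rnorm(n)
  }
  vars <- setdiff(names(d), c("participant_id", "group"))
  meta <- variable_meta(vars, "psychosocial", -10, 10 + sep)
  list(table = feature_table(d, meta), labels = lab,
       informative = c("f1", "f2"),
       ranking = painstrat:::new_ranking(
         "manual", stats::setNames(seq_along(vars), vars), vars))
}

# A case/control table with planted case-control shifts on named variables.
make_shifted_table <- function(seed, n_per_group = 20, shifts = c(big = 2),
                               n_noise = 5) {
  set.seed(seed)
  n <- 2 * n_per_group
  group <- rep(c("case", "control"), each = n_per_group)
  d <- tibble::tibble(
    participant_id = sprintf("s%03d", seq_len(n)),
    group = group
  )
  for (v in names(shifts)) {
    d[[v]] <- stats::rnorm(n) + ifelse(group == "case", shifts[[v]], 0)
  }
  for (i in seq_len(n_noise)) {
    d[[paste0("noise", i)]] <- stats::rnorm(n)
  }
  vars <- setdiff(names(d), c("participant_id", "group"))
  meta <- variable_meta(vars, "other", -20, 20)
  feature_table(d, meta)
}

# Brute-force Benjamini-Hochberg step-up: find, for each i, the smallest
# level q at which hypothesis i would be rejected by the step-up rule.
# Independent of the implementation's cummin trick.
bh_brute_force <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    lo <- 0
    hi <- 1
    reject_at <- function(q) {
      ord <- order(p)
      thresh <- q * seq_len(m) / m
      kmax <- suppressWarnings(max(which(p[ord] <= thresh)))
      if (!is.finite(kmax)) return(rep(FALSE, m))
      rej <- rep(FALSE, m)
      rej[ord[seq_len(kmax)]] <- TRUE
      rej
    }
    for (iter in 1:40) {
      mid <- (lo + hi) / 2
      if (reject_at(mid)[i]) hi <- mid else lo <- mid
    }
    hi
  }, numeric(1))
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")
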