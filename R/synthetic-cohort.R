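#' Specify one latent group of a synthetic cohort
#'
#' @param label Group label (e.g. `"control"`, `"subgroup_1"`).
#' @param n Number of participants, `>= 1`.
#' @param means,sds Named numeric vectors of per-variable means and
#'   standard deviations (identical names across all groups of a config).
#' @return A `group_spec` list.
#' @export
group_spec <- function(label, n, means, sds) {
  if (n < 1) abort_contract("Group size must be >= 1.")
  if (!identical(sort(names(means)), sort(names(sds)))) {
    abort_contract("means and sds must cover the same variables.")
  }
  if (any(sds < 0)) abort_contract("Standard deviations must be >= 0.")
  structure(
    list(label = label, n = as.integer(n), means = means, sds = sds[names(means)]),
    class = "group_spec"
  )
}

#' Configure a synthetic cohort
#'
#' @param groups List of [group_spec()] objects (typically one control group
#'   and two latent case sub-groups). All must declare the same variables.
#' @param meta [variable_meta()] covering every declared variable.
#' @param correlation Optional within-group correlations: a tibble/data frame
#'   with columns `var1`, `var2`, `rho` (each in (-1, 1)). Applied to every
#'   group; the expanded correlation matrix must be positive definite.
#' @param discrete Character vector of variables drawn as rounded truncated
#'   normals (e.g. pain-site counts).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(groups, meta, correlation = NULL,
                             discrete = character()) {
  validate_meta(meta)
  vars <- meta$name
  for (g in groups) {
    if (!setequal(names(g$means), vars)) {
      abort_contract(paste0(
        "Group '", g$label, "' does not declare the same variables as meta."
      ))
    }
    low <- g$means < meta$scale_min[match(names(g$means), vars)]
    high <- g$means > meta$scale_max[match(names(g$means), vars)]
    if (any(low | high)) {
      abort_contract(paste0(
        "Group '", g$label, "' has mean(s) outside the declared scale: ",
        paste(names(g$means)[low | high], collapse = ", ")
      ))
    }
  }
  if (!is.null(correlation)) {
    correlation <- tibble::as_tibble(correlation)
    if (!all(c("var1", "var2", "rho") %in% names(correlation))) {
      abort_contract("correlation needs columns var1, var2, rho.")
    }
    if (any(abs(correlation$rho) >= 1)) {
      abort_contract("Correlations must lie strictly inside (-1, 1).")
    }
  }
  structure(
    list(groups = groups, meta = meta, correlation = correlation,
         discrete = discrete),
    class = "synthetic_config"
  )
}

# Published study conditions: group means (control, case sub-group 1 n=16,
# case sub-group 2 n=5) and SDs of the measured variables, plus the 7-day
# pain-site count from the cohort-characteristics statistics (shared across
# the two case sub-groups; it exists to exercise the collinearity /
# forced-removal path). Scale bounds are the instrument scales; unbounded
# physical measures get wide analysis bounds.
published_group_stats <- function() {
  tibble::tribble(
    ~name,                       ~domain,        ~lo,  ~hi, ~hib, ~m_ctl, ~s_ctl, ~m_s1, ~s_s1, ~m_s2, ~s_s2, ~discrete,
    "cognitive_function",        "psychosocial",    8,   40, TRUE,   36.2,    4.4,  35.8,   4.1,  19.8,   2.5, FALSE,
    "depressive_symptoms",       "psychosocial",    8,   40, FALSE,    8.8,    1.3,   9.4,   1.8,  20.6,   6.9, FALSE,
    "general_self_efficacy",     "psychosocial",   10,   50, TRUE,   44.1,    5.4,  43.1,   4.0,  27.2,   6.6, FALSE,
    "anxiety_symptoms",          "psychosocial",    8,   40, FALSE,   11.5,    4.4,  12.6,   4.8,  24.8,   5.5, FALSE,
    "social_roles_satisfaction", "psychosocial",    8,   40, TRUE,   38.0,    3.8,  34.8,   7.7,  24.8,   7.4, FALSE,
    "central_sensitisation",     "nervous",         0,  100, FALSE,   17.1,   10.3,  32.3,  11.8,  51.2,  11.1, FALSE,
    "lumbar_ppt",                "nervous",         0,   20, TRUE,    9.1,    2.2,   7.6,   2.7,   6.7,   2.4, FALSE,
    "max_extension_strength",    "spinal",          0,  200, TRUE,   68.7,   16.2,  53.7,  21.8,  49.2,  17.9, FALSE,
    "lumbar_t2",                 "spinal",          0,  250, TRUE,  103.4,   13.5,  95.1,   9.9,  96.9,  15.7, FALSE,
    "pain_sites_12m",            "other",           0,   10, FALSE,    1.4,    1.4,   5.2,   2.5,   6.6,   1.9, TRUE,
    "pain_sites_7d",             "other",           0,   10, FALSE,    0.3,    0.7,   2.8,   1.9,   2.8,   1.9, TRUE
  )
}

#' Default synthetic-cohort configuration
#'
#' The study conditions the generator emulates: 21 pain-free controls and 21
#' cases split into a latent sub-group of 16 (near-control psychosocial
#' profile) and one of 5 (impaired psychosocial profile), over ten measured
#' variables with the published group means/SDs, a 7-day pain-site count
#' that shadows the 12-month count, and `n_nuisance` non-discriminating
#' variables per domain (common mean 0.5, SD 0.15 on a unit scale) that the
#' screening step should reject.
#'
#' @param n_nuisance Nuisance variables per biopsychosocial domain
#'   (nervous, spinal, psychosocial); default 10.
#' @param correlation Optional correlation pairs, see [synthetic_config()].
#' @return A [synthetic_config()].
#' @export
#' @examples
#' cfg <- default_cohort_config()
#' sapply(cfg$groups, `[[`, "n")
default_cohort_config <- function(n_nuisance = 10, correlation = NULL) {
  t2 <- published_group_stats()
  nuis <- tidyr::expand_grid(
    domain = c("nervous", "spinal", "psychosocial"),
    i = seq_len(max(n_nuisance, 0))
  )
  if (n_nuisance > 0) {
    nuis$name <- sprintf("nuis_%s_%02d", substr(nuis$domain, 1, 4), nuis$i)
  } else {
    nuis <- nuis[0, ]
    nuis$name <- character()
  }
  meta <- variable_meta(
    name = c(t2$name, nuis$name),
    domain = c(t2$domain, nuis$domain),
    scale_min = c(t2$lo, rep(0, nrow(nuis))),
    scale_max = c(t2$hi, rep(1, nrow(nuis))),
    higher_is_better = c(t2$hib, rep(FALSE, nrow(nuis)))
  )
  mk_group <- function(label, n, m, s) {
    means <- stats::setNames(c(m, rep(0.5, nrow(nuis))), meta$name)
    sds <- stats::setNames(c(s, rep(0.15, nrow(nuis))), meta$name)
    group_spec(label, n, means, sds)
  }
  synthetic_config(
    groups = list(
      mk_group("control", 21, t2$m_ctl, t2$s_ctl),
      mk_group("subgroup_1", 16, t2$m_s1, t2$s_s1),
      mk_group("subgroup_2", 5, t2$m_s2, t2$s_s2)
    ),
    meta = meta,
    correlation = correlation,
    discrete = t2$name[t2$discrete]
  )
}

expand_correlation <- function(config) {
  vars <- config$meta$name
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  if (!is.null(config$correlation)) {
    for (i in seq_len(nrow(config$correlation))) {
      v1 <- config$correlation$var1[i]
      v2 <- config$correlation$var2[i]
      if (!v1 %in% vars || !v2 %in% vars) {
        abort_contract(paste0("Correlation names unknown variable: ", v1, "/", v2))
      }
      R[v1, v2] <- R[v2, v1] <- config$correlation$rho[i]
    }
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10) {
      abort_contract("Expanded correlation matrix is not positive definite.")
    }
  }
  R
}

#' Generate a synthetic cohort
#'
#' Draws per-group (truncated) multivariate normal values with the
#' configured means/SDs and optional within-group correlations, clips to
#' each variable's scale bounds (warning when more than 5% of a variable's
#' draws clip), rounds the declared discrete variables, and merges the case
#' sub-groups into a single `"case"` group. The hidden sub-group labels are
#' returned separately so recovery can be scored.
#'
#' @param config A [synthetic_config()]; default [default_cohort_config()].
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A list with `table` (a [feature_table()]) and `latent` (a tibble
#'   `participant_id`, `subgroup` over all participants, `"control"` for
#'   controls).
#' @export
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' table(cohort$latent$subgroup)
generate_cohort <- function(config = default_cohort_config(), seed = 1) {
  set.seed(seed)
  vars <- config$meta$name
  R <- expand_correlation(config)
  rows <- list()
  latent <- list()
  clipped <- stats::setNames(numeric(length(vars)), vars)
  total <- 0
  for (g in config$groups) {
    s <- g$sds[vars]
    mu <- g$means[vars]
    Sigma <- diag(s) %*% R %*% diag(s)
    draw <- MASS::mvrnorm(g$n, mu = mu, Sigma = Sigma)
    draw <- matrix(draw, nrow = g$n, dimnames = list(NULL, vars))
    lo <- matrix(config$meta$scale_min, g$n, length(vars), byrow = TRUE)
    hi <- matrix(config$meta$scale_max, g$n, length(vars), byrow = TRUE)
    clipped <- clipped + colSums(draw < lo | draw > hi)
    total <- total + g$n
    draw <- pmin(pmax(draw, lo), hi)
    for (v in intersect(config$discrete, vars)) draw[, v] <- round(draw[, v])
    rows[[g$label]] <- draw
    latent[[g$label]] <- rep(g$label, g$n)
  }
  frac <- clipped / total
  if (any(frac > 0.05)) {
    rlang::warn(paste0(
      "More than 5% of draws clipped at scale bounds for: ",
      paste(sprintf("%s (%.0f%%)", names(frac)[frac > 0.05],
                    100 * frac[frac > 0.05]), collapse = ", ")
    ))
  }
  values <- do.call(rbind, rows)
  subgroup <- unlist(latent, use.names = FALSE)
  group <- ifelse(subgroup == "control", "control", "case")
  id <- sprintf("%s%02d", ifelse(group == "control", "ctl", "case"),
                stats::ave(seq_along(group), group, FUN = seq_along))
  data <- tibble::as_tibble(as.data.frame(values))
  data <- dplyr::bind_cols(
    tibble::tibble(participant_id = id, group = group), data
  )
  list(
    table = feature_table(data, config$meta),
    latent = tibble::tibble(participant_id = id, subgroup = subgroup)
  )
}
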