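#' Variable metadata for a feature table
#'
#' Builds the per-variable metadata sidecar used throughout the pipeline:
#' which biopsychosocial domain a variable belongs to, the bounds of its
#' measurement scale, and whether higher values represent better health
#' (e.g. cognitive function) or worse (e.g. depressive symptoms).
#'
#' @param name Character vector of unique variable names.
#' @param domain Character vector, one of `"nervous"`, `"spinal"`,
#'   `"psychosocial"`, `"other"` per variable.
#' @param scale_min,scale_max Numeric scale bounds, `scale_min < scale_max`.
#' @param higher_is_better Logical; defaults to `FALSE`.
#' @return A tibble with one row per variable and columns `name`, `domain`,
#'   `scale_min`, `scale_max`, `higher_is_better`.
#' @export
#' @examples
#' variable_meta(
#'   name = c("depressive_symptoms", "lumbar_t2"),
#'   domain = c("psychosocial", "spinal"),
#'   scale_min = c(8, 0), scale_max = c(40, 250)
#' )
variable_meta <- function(name, domain, scale_min, scale_max,
                          higher_is_better = FALSE) {
  meta <- tibble::tibble(
    name = as.character(name),
    domain = as.character(domain),
    scale_min = as.numeric(scale_min),
    scale_max = as.numeric(scale_max),
    higher_is_better = rep_len(as.logical(higher_is_better), length(name))
  )
  validate_meta(meta)
  meta
}

painstrat_domains <- c("nervous", "spinal", "psychosocial", "other")

validate_meta <- function(meta) {
  required <- c("name", "domain", "scale_min", "scale_max", "higher_is_better")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    abort_schema(paste0(
      "Metadata is missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  if (anyDuplicated(meta$name)) {
    abort_schema(paste0(
      "Duplicate variable names in metadata: ",
      paste(unique(meta$name[duplicated(meta$name)]), collapse = ", ")
    ))
  }
  bad_domain <- setdiff(unique(meta$domain), painstrat_domains)
  if (length(bad_domain) > 0) {
    abort_schema(paste0(
      "Unknown domain(s): ", paste(bad_domain, collapse = ", "),
      ". Must be one of: ", paste(painstrat_domains, collapse = ", ")
    ))
  }
  if (any(meta$scale_min >= meta$scale_max)) {
    bad <- meta$name[meta$scale_min >= meta$scale_max]
    abort_schema(paste0(
      "scale_min must be < scale_max; violated for: ",
      paste(bad, collapse = ", ")
    ))
  }
  invisible(meta)
}

#' Construct a participant-by-variable feature table
#'
#' The central container of the package: a tibble with a `participant_id`
#' column, a `group` column (`"case"`/`"control"`) and one numeric column
#' per measured variable, carrying a metadata sidecar (see
#' [variable_meta()]) as an attribute. All pipeline stages accept and
#' return this shape, so calls chain with the pipe.
#'
#' @param data A data frame with columns `participant_id`, `group`, and one
#'   numeric column per variable. Missing values are `NA`, never zero.
#' @param meta A metadata tibble from [variable_meta()] covering every
#'   variable column.
#' @return A `feature_table`: a tibble subclass with a `meta` attribute.
#' @seealso [read_feature_table()], [normalise_01()], [select_domain()]
#' @export
feature_table <- function(data, meta) {
  data <- tibble::as_tibble(data)
  if (!all(c("participant_id", "group") %in% names(data))) {
    abort_schema("Data must have 'participant_id' and 'group' columns.")
  }
  data$participant_id <- as.character(data$participant_id)
  data$group <- as.character(data$group)
  bad_group <- setdiff(unique(data$group), c("case", "control"))
  if (length(bad_group) > 0) {
    abort_schema(paste0(
      "group must be 'case' or 'control'; found: ",
      paste(bad_group, collapse = ", ")
    ))
  }
  if (anyDuplicated(data$participant_id)) {
    abort_schema(paste0(
      "Duplicate participant_id: ",
      paste(unique(data$participant_id[duplicated(data$participant_id)]),
            collapse = ", ")
    ))
  }
  validate_meta(meta)
  vars <- setdiff(names(data), c("participant_id", "group"))
  not_described <- setdiff(vars, meta$name)
  if (length(not_described) > 0) {
    abort_schema(paste0(
      "Variable(s) without metadata: ", paste(not_described, collapse = ", ")
    ))
  }
  not_present <- setdiff(meta$name, vars)
  if (length(not_present) > 0) {
    abort_schema(paste0(
      "Metadata describes absent variable(s): ",
      paste(not_present, collapse = ", ")
    ))
  }
  for (v in vars) {
    if (!is.numeric(data[[v]])) {
      abort_parse(paste0("Variable '", v, "' is not numeric."))
    }
  }
  # align metadata to column order; rankings always reference names, but a
  # stable order keeps round-trips exact
  meta <- meta[match(vars, meta$name), , drop = FALSE]
  structure(
    data,
    meta = meta,
    class = c("feature_table", class(tibble::tibble()))
  )
}

#' @export
print.feature_table <- function(x, ...) {
  meta <- ft_meta(x)
  cat(sprintf(
    "<feature_table> %d participants (%d case, %d control) x %d variables\n",
    nrow(x), sum(x$group == "case"), sum(x$group == "control"), nrow(meta)
  ))
  tally <- table(factor(meta$domain, levels = painstrat_domains))
  cat("  domains:", paste(sprintf("%s=%d", names(tally), tally),
                          collapse = ", "), "\n")
  NextMethod()
}

#' Accessors for feature tables
#'
#' `ft_meta()` returns the metadata sidecar, `ft_variables()` the variable
#' names in column order, and `ft_values()` the numeric participant-by-
#' variable matrix (row names = participant ids).
#'
#' @param x A `feature_table`.
#' @return A tibble, character vector, or numeric matrix respectively.
#' @export
ft_meta <- function(x) {
  meta <- attr(x, "meta")
  if (is.null(meta)) abort_contract("Not a feature_table: no metadata.")
  meta
}

#' @rdname ft_meta
#' @export
ft_variables <- function(x) ft_meta(x)$name

#' @rdname ft_meta
#' @export
ft_values <- function(x) {
  m <- as.matrix(as.data.frame(x)[, ft_variables(x), drop = FALSE])
  rownames(m) <- x$participant_id
  m
}

#' Read and write feature tables with their metadata sidecar
#'
#' The on-disk format is two comma-separated text files: the data table
#' (header row; first column `participant_id`, second `group`, then one
#' numeric column per variable, `NA` or empty for missing) and a metadata
#' sidecar with columns `name`, `domain`, `scale_min`, `scale_max`,
#' `higher_is_better`.
#'
#' @param table_path,meta_path Paths to the data table and sidecar.
#' @return `read_feature_table()` returns a validated [feature_table()];
#'   `write_feature_table()` returns its input invisibly.
#' @export
read_feature_table <- function(table_path, meta_path) {
  if (!file.exists(table_path)) abort_schema(paste0("No such file: ", table_path))
  if (!file.exists(meta_path)) abort_schema(paste0("No such file: ", meta_path))
  data <- readr::read_csv(table_path, show_col_types = FALSE, progress = FALSE,
                          na = c("", "NA"))
  meta <- readr::read_csv(meta_path, show_col_types = FALSE, progress = FALSE,
                          na = c("", "NA"))
  vars <- setdiff(names(data), c("participant_id", "group"))
  for (v in vars) {
    if (is.character(data[[v]])) {
      bad <- data[[v]][!is.na(data[[v]]) &
                         is.na(suppressWarnings(as.numeric(data[[v]])))]
      abort_parse(paste0(
        "Non-numeric value(s) in variable '", v, "': ",
        paste(utils::head(unique(bad), 3), collapse = ", ")
      ))
    }
  }
  meta$higher_is_better <- as.logical(meta$higher_is_better)
  feature_table(data, meta)
}

#' @rdname read_feature_table
#' @param x A `feature_table` to write.
#' @export
write_feature_table <- function(x, table_path, meta_path) {
  readr::write_csv(tibble::as_tibble(as.data.frame(x)), table_path, na = "NA")
  readr::write_csv(ft_meta(x), meta_path, na = "NA")
  invisible(x)
}

#' Normalise variables to the unit interval
#'
#' Rescales every variable linearly so that the observed minimum and maximum
#' over a reference set of participants map to 0 and 1. The pipeline
#' normalises once with all participants as the reference and reuses the
#' stored parameters downstream, so case-only stages remain on a scale
#' comparable with controls.
#'
#' @param table A [feature_table()].
#' @param reference Which rows define the observed range: `"all"` (default),
#'   `"case"` or `"control"`, or a logical/integer row subset.
#' @return A `normalised_table` (a `feature_table` subclass) with attribute
#'   `norm_params`, a tibble of per-variable `(min, max)`. Values for rows
#'   outside the reference set may fall outside `[0, 1]`; their count is
#'   stored in attribute `n_outside_unit`.
#' @export
#' @examples
#' tab <- toy_feature_table()
#' nt <- normalise_01(tab)
#' range(ft_values(nt), na.rm = TRUE)
normalise_01 <- function(table, reference = "all") {
  vals <- ft_values(table)
  ref_idx <- resolve_reference(table, reference)
  if (length(ref_idx) == 0) abort_contract("Reference row set is empty.")
  mins <- apply(vals[ref_idx, , drop = FALSE], 2, min, na.rm = TRUE)
  maxs <- apply(vals[ref_idx, , drop = FALSE], 2, max, na.rm = TRUE)
  rng <- maxs - mins
  degenerate <- names(rng)[!is.finite(rng) | rng <= 0]
  if (length(degenerate) > 0) {
    abort_degenerate(
      paste0("Variable(s) constant over the reference rows: ",
             paste(degenerate, collapse = ", ")),
      variables = degenerate
    )
  }
  scaled <- sweep(sweep(vals, 2, mins, "-"), 2, rng, "/")
  out <- table
  for (v in colnames(scaled)) out[[v]] <- unname(scaled[, v])
  structure(
    out,
    norm_params = tibble::tibble(name = colnames(scaled), min = unname(mins),
                                 max = unname(maxs)),
    reference = reference,
    n_outside_unit = sum(scaled < 0 | scaled > 1, na.rm = TRUE),
    class = c("normalised_table", class(table))
  )
}

resolve_reference <- function(table, reference) {
  if (is.character(reference) && length(reference) == 1) {
    switch(reference,
      all = seq_len(nrow(table)),
      case = which(table$group == "case"),
      control = which(table$group == "control"),
      abort_contract(paste0("Unknown reference: ", reference))
    )
  } else if (is.logical(reference)) {
    which(reference)
  } else {
    as.integer(reference)
  }
}

#' Invert a unit-interval normalisation
#'
#' Applies the stored `(min, max)` parameters of a [normalise_01()] result
#' in reverse, reproducing the original measurement scale.
#'
#' @param table A `normalised_table`.
#' @return A `feature_table` on the original scale.
#' @export
denormalise <- function(table) {
  params <- attr(table, "norm_params")
  if (is.null(params)) abort_contract("Not a normalised_table: no norm_params.")
  out <- table
  for (i in seq_len(nrow(params))) {
    v <- params$name[i]
    out[[v]] <- out[[v]] * (params$max[i] - params$min[i]) + params$min[i]
  }
  attr(out, "norm_params") <- NULL
  attr(out, "n_outside_unit") <- NULL
  class(out) <- setdiff(class(out), "normalised_table")
  out
}

#' Select the variables of one biopsychosocial domain
#'
#' @param table A [feature_table()].
#' @param domain One of `"nervous"`, `"spinal"`, `"psychosocial"`, `"other"`.
#' @return A `feature_table` restricted to that domain's columns;
#'   participant rows unchanged.
#' @export
select_domain <- function(table, domain) {
  domain <- match.arg(domain, painstrat_domains)
  meta <- ft_meta(table)
  keep <- meta$name[meta$domain == domain]
  if (length(keep) == 0) {
    abort_empty_selection(paste0("No variables in domain '", domain, "'."))
  }
  select_variables(table, keep)
}

# Restrict a feature table to named variables, keeping metadata in step.
select_variables <- function(table, variables) {
  meta <- ft_meta(table)
  missing_vars <- setdiff(variables, meta$name)
  if (length(missing_vars) > 0) {
    abort_contract(paste0("Unknown variable(s): ",
                          paste(missing_vars, collapse = ", ")))
  }
  data <- tibble::as_tibble(as.data.frame(table))
  out <- data[, c("participant_id", "group", variables), drop = FALSE]
  norm_params <- attr(table, "norm_params")
  res <- feature_table(out, meta[match(variables, meta$name), , drop = FALSE])
  if (!is.null(norm_params)) {
    attr(res, "norm_params") <-
      norm_params[norm_params$name %in% variables, , drop = FALSE]
    class(res) <- c("normalised_table", class(res))
  }
  res
}

# Drop rows of a feature table by predicate on group, preserving class/meta.
filter_group <- function(table, group) {
  keep <- table$group %in% group
  out <- table[keep, , drop = FALSE]
  attrs <- attributes(table)
  for (a in c("meta", "norm_params", "reference")) {
    if (!is.null(attrs[[a]])) attr(out, a) <- attrs[[a]]
  }
  class(out) <- class(table)
  out
}

#' A tiny worked feature table
#'
#' Three cases and three controls over one variable per domain; handy for
#' examples and quick checks.
#'
#' @return A [feature_table()].
#' @export
toy_feature_table <- function() {
  data <- tibble::tibble(
    participant_id = c("p1", "p2", "p3", "c1", "c2", "c3"),
    group = c("case", "case", "case", "control", "control", "control"),
    depressive_symptoms = c(20, 24, 9, 8, 10, 9),
    lumbar_t2 = c(80, 95, 101, 110, 96, 104),
    lumbar_ppt = c(5.5, 6.8, 8.2, 9.6, 8.8, 9.9)
  )
  meta <- variable_meta(
    name = c("depressive_symptoms", "lumbar_t2", "lumbar_ppt"),
    domain = c("psychosocial", "spinal", "nervous"),
    scale_min = c(8, 0, 0),
    scale_max = c(40, 250, 15)
  )
  feature_table(data, meta)
}
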