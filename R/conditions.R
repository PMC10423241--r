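# Classed conditions used across the package so callers can distinguish
# malformed inputs (schema), impossible requests (contract), bad values
# (domain) and degenerate data (degenerate).

abort_schema <- function(message, ...) {
  rlang::abort(message, class = "painstrat_schema_error", ...)
}

abort_parse <- function(message, ...) {
  rlang::abort(message, class = "painstrat_parse_error", ...)
}

abort_contract <- function(message, ...) {
  rlang::abort(message, class = "painstrat_contract_error", ...)
}

abort_domain <- function(message, ...) {
  rlang::abort(message, class = "painstrat_domain_error", ...)
}

abort_degenerate <- function(message, ...) {
  rlang::abort(message, class = "painstrat_degenerate_error", ...)
}

abort_empty_selection <- function(message, ...) {
  rlang::abort(message, class = "painstrat_empty_selection_error", ...)
}
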