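# Preprocessing toolkit for the derived measurement variables. The pipeline
# itself consumes already-derived feature tables; these pure functions turn
# raw MRI and sensory-testing measurements into those features.

#' Disc T2 relaxation time from a multi-echo decay series
#'
#' Estimates the transverse relaxation time by an ordinary least-squares
#' linear fit of the natural logarithm of image intensity against echo time:
#' `ln(S) = a + b * TE`, `T2 = -1/b`. The signal must decay (negative
#' slope); lower disc T2 indicates dehydration/degeneration.
#'
#' @param echo_times Strictly increasing echo times in ms (>= 3 points).
#' @param intensities Positive signal intensities aligned to `echo_times`.
#' @return T2 in ms.
#' @export
#' @examples
#' te <- c(15.75, 36.75, 57.75, 78.75, 99.75, 120.75, 141.75, 162.75)
#' t2_from_echoes(te, 100 * exp(-te / 100)) # 100
t2_from_echoes <- function(echo_times, intensities) {
  if (length(echo_times) < 3 || length(intensities) != length(echo_times)) {
    abort_contract("Need >= 3 aligned (echo_time, intensity) points.")
  }
  if (any(diff(echo_times) <= 0)) {
    abort_contract("Echo times must be strictly increasing.")
  }
  if (any(intensities <= 0)) {
    abort_domain("Intensities must be positive to take logarithms.")
  }
  fit <- stats::lm.fit(cbind(1, echo_times), log(intensities))
  slope <- fit$coefficients[2]
  if (!is.finite(slope) || slope >= 0) {
    rlang::abort("Non-decaying signal: log-linear slope is not negative.",
                 class = "painstrat_fit_error")
  }
  unname(-1 / slope)
}

#' Dixon fat fraction
#'
#' `100 * fat / (fat + water)`, in percent.
#'
#' @param signal_fat,signal_water Non-negative signal intensities.
#' @return Fat fraction in `[0, 100]`.
#' @export
fat_fraction <- function(signal_fat, signal_water) {
  if (any(signal_fat < 0) || any(signal_water < 0)) {
    abort_domain("Signal intensities must be non-negative.")
  }
  if (any(signal_fat + signal_water == 0)) {
    abort_domain("fat + water signal must be positive.")
  }
  100 * signal_fat / (signal_fat + signal_water)
}

#' Change score (later minus earlier)
#'
#' Used for temporal summation (10th minus 1st pulse rating) and
#' exercise-induced hypoalgesia (post- minus pre-exercise pressure-pain
#' threshold, where positive means thresholds increased).
#'
#' @param later,earlier Numeric values.
#' @return `later - earlier`.
#' @export
change_score <- function(later, earlier) later - earlier

#' Volume from traced slice areas
#'
#' Sums per-slice areas (mm^2), scales by the slice pitch (mm, thickness
#' plus gap), and converts to cm^3.
#'
#' @param areas Non-negative slice areas in mm^2.
#' @param slice_pitch Slice thickness + inter-slice gap in mm (4.5 for
#'   discs, 3.5 for paraspinal muscles in the reference protocol).
#' @return Volume in cm^3.
#' @export
slice_volume <- function(areas, slice_pitch) {
  if (length(areas) == 0) abort_domain("areas must be non-empty.")
  if (any(areas < 0)) abort_domain("areas must be non-negative.")
  if (slice_pitch <= 0) abort_domain("slice_pitch must be positive.")
  sum(areas) * slice_pitch / 1000
}

#' Pool repeated or bilateral measurements
#'
#' @param values Non-empty numeric vector (e.g. two pressure-pain threshold
#'   trials, or per-level radiographic grades).
#' @param rule `"mean"` (trial/side averaging) or `"max"` (worst-level
#'   grading).
#' @return A single pooled value.
#' @export
pool_measurements <- function(values, rule = c("mean", "max")) {
  rule <- match.arg(rule)
  if (length(values) == 0) abort_domain("values must be non-empty.")
  switch(rule, mean = mean(values), max = max(values))
}
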