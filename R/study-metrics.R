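#' Novel-object discrimination index
#'
#' Interaction time with the novel object divided by total interaction time
#' with both objects. Defined on `[0, 1]`; 0.5 means no preference. When no
#' interaction occurred with either object the index is undefined and `NA`
#' is returned with a warning.
#'
#' @param novel_s,familiar_s Interaction durations in seconds (non-negative,
#'   vectorized).
#' @return Numeric vector in `[0, 1]` (or `NA` where undefined).
#' @examples
#' discrimination_index(45, 15) # 0.75
#' @export
discrimination_index <- function(novel_s, familiar_s) {
  assert_non_negative(novel_s, "novel_s")
  assert_non_negative(familiar_s, "familiar_s")
  total <- novel_s + familiar_s
  out <- ifelse(total > 0, novel_s / total, NA_real_)
  if (anyNA(out)) {
    warn("Zero total interaction time: discrimination index undefined.")
  }
  out
}

#' Social preference / social memory index
#'
#' Normalized contrast of interaction times,
#' `(preferred - other) / (preferred + other)`, bounded in `[-1, 1]` and
#' antisymmetric in its arguments. With the novel stranger as the preferred
#' target this is the social memory index; with the stranger vs empty cage
#' it is the sociability index.
#'
#' @param pref_s,other_s Interaction durations in seconds (non-negative,
#'   vectorized).
#' @return Numeric vector in `[-1, 1]` (`NA` where both durations are zero).
#' @examples
#' preference_index(60, 20) # 0.5
#' @export
preference_index <- function(pref_s, other_s) {
  assert_non_negative(pref_s, "pref_s")
  assert_non_negative(other_s, "other_s")
  total <- pref_s + other_s
  out <- ifelse(total > 0, (pref_s - other_s) / total, NA_real_)
  if (anyNA(out)) {
    warn("Zero total interaction time: preference index undefined.")
  }
  out
}

#' Marble burying score
#'
#' Each marble is scored 4 (completely buried), 3 (covered >50% with
#' bedding), 2 (covered 50%), 1 (covered <50%) or 0 (anything less); the
#' assay score is the sum over the cage's marbles (20 in the standard
#' layout).
#'
#' @param states Character vector of per-marble states, each one of
#'   `"completely_buried"`, `"covered_gt50"`, `"covered_eq50"`,
#'   `"covered_lt50"`, `"less"`.
#' @param n_marbles Expected number of marbles; defaults to
#'   `length(states)`, set to 20 to enforce the standard assay size.
#' @return Integer total score in `[0, 4 * n_marbles]`.
#' @examples
#' marble_score(rep("completely_buried", 20)) # 80
#' @export
marble_score <- function(states, n_marbles = length(states)) {
  point_map <- c(
    completely_buried = 4L, covered_gt50 = 3L, covered_eq50 = 2L,
    covered_lt50 = 1L, less = 0L
  )
  unknown <- setdiff(unique(states), names(point_map))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown marble state(s): %s.",
      paste(unknown, collapse = ", ")))
  }
  if (length(states) != n_marbles) {
    abort(sprintf("Expected %d marble states, got %d.",
      n_marbles, length(states)))
  }
  sum(point_map[states])
}

#' LTP magnitude from an fEPSP time series
#'
#' Percentage change of the mean fEPSP amplitude in a late post-induction
#' window relative to the mean baseline amplitude:
#' `100 * (mean(window) - mean(baseline)) / mean(baseline)`. Induction is at
#' time 0; the standard analysis window is 50-60 min after induction and
#' the baseline is the 30 min preceding it.
#'
#' @param time_min Numeric vector of time stamps in minutes relative to
#'   induction (baseline times are negative).
#' @param amplitude Positive fEPSP amplitudes, same length as `time_min`.
#' @param baseline_window Length-2 vector, baseline interval
#'   `[start, end)` in min (default `c(-30, 0)`).
#' @param response_window Length-2 vector, analysis interval
#'   `[start, end]` in min (default `c(50, 60)`).
#' @return LTP magnitude as a percentage (signed; negative = depression).
#' @examples
#' t <- c(-20, -10, 55, 58)
#' ltp_magnitude(t, c(1, 1, 1.5, 1.5)) # +50
#' @export
ltp_magnitude <- function(time_min, amplitude,
                          baseline_window = c(-30, 0),
                          response_window = c(50, 60)) {
  if (length(time_min) != length(amplitude)) {
    abort("`time_min` and `amplitude` must have the same length.")
  }
  assert_positive(amplitude, "amplitude")
  base <- amplitude[time_min >= baseline_window[1] & time_min < baseline_window[2]]
  resp <- amplitude[time_min >= response_window[1] & time_min <= response_window[2]]
  if (length(base) == 0) {
    abort("No sweeps in the baseline window.")
  }
  if (length(resp) == 0) {
    abort("No sweeps in the response window.")
  }
  100 * (mean(resp) - mean(base)) / mean(base)
}

#' Paired-pulse ratio per inter-stimulus interval
#'
#' For each sweep the ratio of the second evoked fEPSP amplitude over the
#' first is computed; sweeps are then averaged within each inter-stimulus
#' interval (mean of ratios, matching "the average ratio" convention).
#'
#' @param pulses Data frame with columns `interval_ms`, `amp1`, `amp2`
#'   (one row per sweep; `amp1` must be positive).
#' @return Tibble `interval_ms`, `n_sweeps`, `ppr` sorted by interval.
#' @examples
#' paired_pulse_ratio(
#'   tibble::tibble(interval_ms = 50, amp1 = c(1, 2), amp2 = c(2, 2))
#' ) # ppr 1.5
#' @export
paired_pulse_ratio <- function(pulses) {
  assert_columns(pulses, c("interval_ms", "amp1", "amp2"), "pulses")
  assert_positive(pulses$amp1, "amp1")
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(pulses), .data$interval_ms),
    n_sweeps = dplyr::n(),
    ppr = mean(.data$amp2 / .data$amp1),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$interval_ms)
}
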