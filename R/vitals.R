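#' Derived hemodynamic indices
#'
#' Vectorised formulas for the indices used throughout the analysis:
#' shock index (pulse over systolic pressure), mean arterial pressure
#' \eqn{(2 \cdot DBP + SBP)/3}, pulse pressure \eqn{SBP - DBP}, and the
#' severe-shock indicator (MAP strictly below 60 mmHg). All functions
#' propagate missing values and return `NA` rather than erroring on
#' physiologically impossible inputs (non-positive pressures, DBP above SBP).
#'
#' @param pulse pulse rate, beats per minute.
#' @param sbp systolic blood pressure, mmHg.
#' @param dbp diastolic blood pressure, mmHg.
#' @param map mean arterial pressure, mmHg.
#' @return numeric vector (`severe_shock_flag()`: logical vector).
#' @examples
#' shock_index(112, 80)            # 1.4
#' mean_arterial_pressure(90, 60)  # 70
#' pulse_pressure(120, 80)         # 40
#' severe_shock_flag(59.9)         # TRUE (strict inequality)
#' @name vital_indices
NULL

#' @rdname vital_indices
#' @export
shock_index <- function(pulse, sbp) {
  out <- pulse / sbp
  out[is.na(pulse) | is.na(sbp) | pulse <= 0 | sbp <= 0] <- NA_real_
  out
}

#' @rdname vital_indices
#' @export
mean_arterial_pressure <- function(sbp, dbp) {
  out <- (2 * dbp + sbp) / 3
  out[is.na(sbp) | is.na(dbp) | sbp <= 0 | dbp <= 0 | dbp > sbp] <- NA_real_
  out
}

#' @rdname vital_indices
#' @export
pulse_pressure <- function(sbp, dbp) {
  out <- sbp - dbp
  out[is.na(sbp) | is.na(dbp) | dbp > sbp] <- NA_real_
  out
}

#' @rdname vital_indices
#' @export
severe_shock_flag <- function(map) {
  map < 60
}

.selection_rules <- c("max_si", "max_pulse", "min_sbp", "min_map")

# per-observation statistic maximised by each worst-point rule
.rule_stat <- function(rule, pulse, sbp, dbp) {
  switch(rule,
         max_si    = shock_index(pulse, sbp),
         max_pulse = ifelse(!is.na(pulse) & pulse > 0, pulse, NA_real_),
         min_sbp   = ifelse(!is.na(sbp) & sbp > 0, -sbp, NA_real_),
         min_map   = -mean_arterial_pressure(sbp, dbp),
         stopf("unknown selection rule '%s'", rule))
}

#' Select the worst measurement point of each first-hour series
#'
#' For every patient, picks the observation inside the analysis window that
#' is extremal under the chosen rule and computes all derivable indices at
#' that single time point. The primary rule is the interval with the highest
#' shock index; the three alternatives (highest pulse, lowest SBP, lowest
#' MAP) support a sensitivity analysis of the worst-point convention.
#' Observations missing a field the rule needs are skipped; ties are broken
#' by the earliest time point (earlier detection is the clinical framing).
#'
#' @param cohort a `shock_cohort` (long) data frame, see [read_cohort()].
#' @param window_minutes closed analysis window `[0, window_minutes]` from
#'   study entry; default 60 (the first hour, 15-minute grid).
#' @param rule one of `"max_si"`, `"max_pulse"`, `"min_sbp"`, `"min_map"`.
#' @return data frame with one row per patient: the selected observation,
#'   `si`, `map`, `pulse_pressure`, `severe_shock` and `selection_rule`.
#'   Patients with no eligible observation get an all-`NA` row (they drop out
#'   of analyses that need this rule).
#' @seealso [select_worst_point()] for a single record.
#' @export
derive_worst_points <- function(cohort, window_minutes = 60, rule = "max_si") {
  rule <- match.arg(rule, .selection_rules)
  ids <- unique(cohort$patient_id)
  obs <- cohort[!is.na(cohort$minutes_from_entry) &
                  cohort$minutes_from_entry >= 0 &
                  cohort$minutes_from_entry <= window_minutes, , drop = FALSE]
  obs$._stat <- .rule_stat(rule, obs$pulse, obs$sbp, obs$dbp)
  obs <- obs[!is.na(obs$._stat), , drop = FALSE]
  # extremal statistic first, earliest time on ties
  obs <- obs[order(obs$patient_id, -obs$._stat, obs$minutes_from_entry), , drop = FALSE]
  sel <- obs[!duplicated(obs$patient_id), , drop = FALSE]

  out <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  m <- match(ids, sel$patient_id)
  out$selection_rule <- rule
  out$minutes_from_entry <- sel$minutes_from_entry[m]
  out$pulse <- sel$pulse[m]
  out$sbp <- sel$sbp[m]
  out$dbp <- sel$dbp[m]
  out$si <- shock_index(out$pulse, out$sbp)
  out$map <- mean_arterial_pressure(out$sbp, out$dbp)
  out$pulse_pressure <- pulse_pressure(out$sbp, out$dbp)
  out$severe_shock <- severe_shock_flag(out$map)
  class(out) <- c("shock_derived", "data.frame")
  out
}

#' Worst-point selection for a single patient record
#'
#' @param record data frame of one patient's rows (long cohort schema).
#' @inheritParams derive_worst_points
#' @return one-row data frame as in [derive_worst_points()].
#' @export
select_worst_point <- function(record, window_minutes = 60, rule = "max_si") {
  if (length(unique(record$patient_id)) != 1L)
    stopf("select_worst_point() expects rows of a single patient")
  derive_worst_points(record, window_minutes = window_minutes, rule = rule)
}
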