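#' Build the three analysis outcomes
#'
#' Constructs the WHO near-miss style outcome hierarchy from the raw
#' per-patient fields:
#' \describe{
#'   \item{death}{maternal death.}
#'   \item{smo}{severe maternal outcome: death or severe end-organ failure
#'     morbidity.}
#'   \item{smo_ci}{SMO or a critical intervention: ICU admission, blood
#'     transfusion of five or more units (inclusive), or emergency
#'     hysterectomy — the latter counting only for uterine-atony diagnoses.}
#' }
#' The composites are nested by construction: `death` implies `smo` implies
#' `smo_ci`. Missing component fields (end-organ failure, ICU, transfusion
#' units, hysterectomy) are treated as `FALSE` with a single summary warning,
#' matching an all-available-data rather than complete-case analysis. A
#' missing death flag is a contract violation — such records must already
#' have been removed by [apply_exclusions()].
#'
#' @param cohort a `shock_cohort` data frame (long format); patient-level
#'   fields must be constant within patient.
#' @return data frame with one row per patient: `patient_id`, `death`,
#'   `smo`, `smo_ci` (logical).
#' @export
build_outcomes <- function(cohort) {
  first <- cohort[!duplicated(cohort$patient_id), , drop = FALSE]
  if (anyNA(first$died))
    stopf("contract violation: %d record(s) with missing death outcome; run apply_exclusions() first",
          sum(is.na(first$died)))

  comp <- c("end_organ_failure", "icu_admission", "transfusion_units",
            "emergency_hysterectomy")
  n_miss <- vapply(first[comp], function(x) sum(is.na(x)), integer(1))
  if (any(n_miss > 0))
    warnf("missing outcome components treated as FALSE/0: %s",
          paste(names(n_miss)[n_miss > 0], n_miss[n_miss > 0],
                sep = "=", collapse = ", "))
  eof <- !is.na(first$end_organ_failure) & first$end_organ_failure
  icu <- !is.na(first$icu_admission) & first$icu_admission
  txn <- !is.na(first$transfusion_units) & first$transfusion_units >= 5
  hyst <- !is.na(first$emergency_hysterectomy) & first$emergency_hysterectomy &
    first$diagnosis == "uterine_atony"

  death <- first$died
  smo <- death | eof
  smo_ci <- smo | icu | txn | hyst
  data.frame(patient_id = first$patient_id,
             death = death, smo = smo, smo_ci = smo_ci,
             stringsAsFactors = FALSE)
}

#' Outcome prevalences
#'
#' @param outcomes data frame from [build_outcomes()].
#' @return data frame of outcome, count, n and prevalence in percent
#'   (unrounded; use [round_half_up()] for presentation).
#' @export
outcome_prevalence <- function(outcomes) {
  nm <- setdiff(names(outcomes), "patient_id")
  data.frame(outcome = nm,
             count = vapply(outcomes[nm], function(x) sum(x, na.rm = TRUE), numeric(1)),
             n = vapply(outcomes[nm], function(x) sum(!is.na(x)), numeric(1)),
             prevalence = vapply(outcomes[nm],
                                 function(x) 100 * mean(x, na.rm = TRUE), numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-patient analysis table
#'
#' Convenience constructor for the matrix every downstream analysis consumes:
#' worst-point predictors ([derive_worst_points()]) joined with the outcome
#' flags ([build_outcomes()]).
#'
#' @inheritParams derive_worst_points
#' @return data frame with one row per patient: the derived point, `si`,
#'   `map`, `pulse_pressure`, plus `death`, `smo`, `smo_ci`.
#' @export
analysis_table <- function(cohort, window_minutes = 60, rule = "max_si") {
  der <- derive_worst_points(cohort, window_minutes = window_minutes, rule = rule)
  out <- build_outcomes(cohort)
  merge(der, out, by = "patient_id", sort = FALSE)
}
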