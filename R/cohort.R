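#' @title Cohort tables: schema, reading, writing, exclusions
#'
#' @description The package works on a long-format cohort table: one row per
#' timed vital-sign observation, with patient-level fields (eligibility,
#' diagnosis, outcomes, demographics) repeated on every row of that patient.
#' This mirrors how the underlying study data were captured (vitals recorded
#' on a 15-minute grid until stabilisation) and is what the worst-point rule
#' needs.
#'
#' @name cohort_schema
NULL

.cohort_columns <- c(
  "patient_id", "entry_context", "ebl_ml", "diagnosis",
  "minutes_from_entry", "pulse", "sbp", "dbp",
  "died", "end_organ_failure", "icu_admission", "transfusion_units",
  "emergency_hysterectomy", "age_years", "parity"
)

.diagnosis_levels <- c(
  "uterine_atony", "abortion_complications", "retained_placenta", "ectopic",
  "abruption", "ruptured_uterus", "previa", "lacerations", "other", "molar",
  "accreta", "missing"
)

.vital_cols <- c("pulse", "sbp", "dbp")
.numeric_cols <- c("ebl_ml", "minutes_from_entry", "pulse", "sbp", "dbp",
                   "transfusion_units", "age_years", "parity")
.logical_cols <- c("died", "end_organ_failure", "icu_admission",
                   "emergency_hysterectomy")

# parse a character column to numeric; the token "NP" (non-palpable vitals)
# becomes NA but is counted separately because the study excluded such records
.parse_numeric <- function(x, field, np_allowed = FALSE) {
  x <- trimws(x)
  x[x == ""] <- NA_character_
  np <- np_allowed & !is.na(x) & toupper(x) == "NP"
  val <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & !np & is.na(val)
  if (any(bad))
    warnf("%d unparseable value(s) in column '%s' set to missing", sum(bad), field)
  if (any(np))
    warnf("%d non-palpable ('NP') value(s) in column '%s' set to missing", sum(np), field)
  list(value = val, np = np)
}

.parse_logical <- function(x, field) {
  x <- toupper(trimws(x))
  x[x == ""] <- NA_character_
  val <- rep(NA, length(x))
  val[x %in% c("TRUE", "T", "1", "YES")] <- TRUE
  val[x %in% c("FALSE", "F", "0", "NO")] <- FALSE
  bad <- !is.na(x) & is.na(val)
  if (any(bad))
    warnf("%d unparseable value(s) in column '%s' set to missing", sum(bad), field)
  val
}

.validate_cohort <- function(df) {
  dup <- duplicated(df[, c("patient_id", "minutes_from_entry")]) &
    !is.na(df$minutes_from_entry)
  if (any(dup))
    stopf("validation error: duplicate (patient_id, minutes_from_entry) pairs: %s",
          paste(utils::head(unique(df$patient_id[dup]), 5), collapse = ", "))
  for (v in .vital_cols) {
    nonpos <- !is.na(df[[v]]) & df[[v]] <= 0
    if (any(nonpos)) {
      warnf("%d non-positive value(s) in '%s' set to missing", sum(nonpos), v)
      df[[v]][nonpos] <- NA_real_
    }
  }
  inv <- !is.na(df$dbp) & !is.na(df$sbp) & df$dbp > df$sbp
  if (any(inv)) {
    warnf("%d observation(s) with DBP > SBP: DBP set to missing", sum(inv))
    df$dbp[inv] <- NA_real_
  }
  # observations sorted by time within patient
  df <- df[order(match(df$patient_id, unique(df$patient_id)),
                 df$minutes_from_entry), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.as_shock_cohort <- function(df, provenance = list()) {
  df <- .validate_cohort(df)
  attr(df, "provenance") <- provenance
  class(df) <- c("shock_cohort", "data.frame")
  df
}

#' Read a cohort CSV
#'
#' Reads and validates a long-format cohort table. Missing values are empty
#' cells; the literal token `NP` in a vital-sign column (vitals recorded as
#' non-palpable) parses to missing with a warning, and the affected rows are
#' flagged so the exclusion step can count them. Unparseable numerics become
#' missing with a warning; a missing mandatory column or a duplicated
#' `(patient_id, minutes_from_entry)` pair is an error.
#'
#' @param path path to a CSV file with columns `patient_id`, `entry_context`,
#'   `ebl_ml`, `diagnosis`, `minutes_from_entry`, `pulse`, `sbp`, `dbp`,
#'   `died`, `end_organ_failure`, `icu_admission`, `transfusion_units`,
#'   `emergency_hysterectomy`, `age_years`, `parity`.
#' @param schema_version schema identifier; only `"1"` is defined.
#' @return a `shock_cohort` data frame; attribute `"np_rows"` marks rows that
#'   contained non-palpable vitals, attribute `"provenance"` records the
#'   source file.
#' @seealso [write_cohort()], [apply_exclusions()], [generate_cohort()]
#' @export
read_cohort <- function(path, schema_version = "1") {
  if (!identical(schema_version, "1"))
    stopf("unknown schema_version '%s'", schema_version)
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(.cohort_columns, names(raw))
  if (length(missing_cols))
    stopf("schema error: missing mandatory column(s): %s",
          paste(missing_cols, collapse = ", "))
  df <- data.frame(patient_id = trimws(raw$patient_id),
                   stringsAsFactors = FALSE)
  df$entry_context <- trimws(raw$entry_context)
  np_any <- rep(FALSE, nrow(raw))
  for (v in .numeric_cols) {
    p <- .parse_numeric(raw[[v]], v, np_allowed = v %in% .vital_cols)
    df[[v]] <- p$value
    np_any <- np_any | p$np
  }
  for (v in .logical_cols) df[[v]] <- .parse_logical(raw[[v]], v)
  df$diagnosis <- trimws(raw$diagnosis)
  df$diagnosis[df$diagnosis == ""] <- "missing"
  unknown <- !df$diagnosis %in% .diagnosis_levels
  if (any(unknown)) {
    warnf("%d unknown diagnosis value(s) set to 'other'", sum(unknown))
    df$diagnosis[unknown] <- "other"
  }
  df <- df[, .cohort_columns]
  out <- .as_shock_cohort(df, provenance = list(source = path,
                                                schema_version = schema_version))
  attr(out, "np_rows") <- which(np_any)
  out
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: writes the documented schema with missing
#' values as empty cells, so `read_cohort(write_cohort(x))` is the identity
#' on validated cohorts.
#'
#' @param cohort a `shock_cohort` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)[, .cohort_columns]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Apply the study exclusion rules
#'
#' Drops records lost to follow-up (no outcome data for death) and records
#' with no usable vital-sign observation — no non-missing pulse or SBP —
#' inside the first-hour window; this includes records whose vitals were all
#' recorded as non-palpable. The per-patient exclusion log is attached as an
#' attribute. The operation is idempotent.
#'
#' @param cohort a `shock_cohort` data frame.
#' @param window_minutes window used to judge "usable vitals"; default 60.
#' @param verbose print a one-line summary.
#' @return the retained cohort, with attributes `"exclusion_log"` (data frame
#'   of `patient_id`, `reason`) and `"n_input"`/`"n_retained"` patient counts.
#' @export
apply_exclusions <- function(cohort, window_minutes = 60, verbose = FALSE) {
  ids <- unique(cohort$patient_id)
  died_by_id <- tapply(cohort$died, cohort$patient_id, function(x) any(!is.na(x)))
  usable <- !is.na(cohort$minutes_from_entry) &
    cohort$minutes_from_entry >= 0 & cohort$minutes_from_entry <= window_minutes &
    (!is.na(cohort$pulse) | !is.na(cohort$sbp))
  usable_by_id <- tapply(usable, cohort$patient_id, any)

  reason <- rep(NA_character_, length(ids))
  reason[!died_by_id[ids]] <- "no_outcome"
  reason[is.na(reason) & !usable_by_id[ids]] <- "no_vitals"

  keep_ids <- ids[is.na(reason)]
  out <- cohort[cohort$patient_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  log <- data.frame(patient_id = ids[!is.na(reason)],
                    reason = reason[!is.na(reason)],
                    stringsAsFactors = FALSE)
  attr(out, "provenance") <- attr(cohort, "provenance")
  class(out) <- c("shock_cohort", "data.frame")
  attr(out, "exclusion_log") <- log
  attr(out, "n_input") <- length(ids)
  attr(out, "n_retained") <- length(keep_ids)
  if (verbose)
    message(sprintf("retained %d of %d records (%s)",
                    length(keep_ids), length(ids),
                    if (nrow(log)) paste(names(table(log$reason)),
                                         table(log$reason),
                                         sep = "=", collapse = ", ")
                    else "no exclusions"))
  out
}

#' Exclusion log of a filtered cohort
#'
#' @param cohort result of [apply_exclusions()].
#' @return data frame of `patient_id`, `reason`.
#' @export
exclusion_log <- function(cohort) {
  attr(cohort, "exclusion_log") %||%
    data.frame(patient_id = character(), reason = character(),
               stringsAsFactors = FALSE)
}

#' Study eligibility at entry
#'
#' Eligibility in the parent studies required a threshold estimated blood
#' loss together with at least one vital-sign criterion at study entry:
#' SBP at or below 100 mmHg and/or pulse at or above 100 BPM. "Study entry"
#' vitals are the earliest observation of the record. The EBL threshold
#' depends on entry context: above 750 mL in the tertiary-facility studies,
#' above 500 mL in the primary-health-clinic study; the default reproduces
#' the lower (PHC) bar.
#'
#' @param record data frame of one patient's rows, or a full cohort (in which
#'   case a named per-patient logical vector is returned).
#' @param ebl_threshold_ml estimated-blood-loss threshold in mL (exclusive);
#'   default 500.
#' @return logical (`NA` when EBL or all entry vitals are missing —
#'   indeterminate, never an error).
#' @export
eligibility_check <- function(record, ebl_threshold_ml = 500) {
  ids <- unique(record$patient_id)
  res <- vapply(ids, function(id) {
    r <- record[record$patient_id == id, , drop = FALSE]
    entry <- r[which.min(r$minutes_from_entry), , drop = FALSE]
    ebl <- entry$ebl_ml
    sbp_ok <- if (is.na(entry$sbp)) NA else entry$sbp <= 100
    pulse_ok <- if (is.na(entry$pulse)) NA else entry$pulse >= 100
    vital_ok <- if (isTRUE(sbp_ok) || isTRUE(pulse_ok)) TRUE
                else if (is.na(sbp_ok) || is.na(pulse_ok)) NA
                else FALSE
    if (is.na(ebl)) return(NA)          # indeterminate, not an exception
    if (ebl <= ebl_threshold_ml) return(FALSE)
    vital_ok
  }, logical(1))
  names(res) <- ids
  if (length(ids) == 1L) unname(res) else res
}

#' @export
print.shock_cohort <- function(x, ...) {
  n_pat <- length(unique(x$patient_id))
  cat(sprintf("<shock_cohort> %d patients, %d observations\n", n_pat, nrow(x)))
  prov <- attr(x, "provenance")
  if (!is.null(prov$source)) cat("  source:", prov$source, "\n")
  if (!is.null(prov$seed)) cat("  generator seed:", prov$seed, "\n")
  log <- attr(x, "exclusion_log")
  if (!is.null(log) && nrow(log))
    cat(sprintf("  exclusions applied: %s\n",
                paste(names(table(log$reason)), table(log$reason),
                      sep = "=", collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}
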