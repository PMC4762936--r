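#' Confusion counts at a threshold
#'
#' Cross-classifies a higher-is-worse score against an outcome at a cut
#' point. Test-positive means score at or above the threshold (`direction =
#' "ge"`, the convention used for all shock-index cuts) or strictly above
#' (`"gt"`). Subjects missing the score or the outcome are excluded from all
#' four cells; the excluded count is attached as attribute `"n_missing"`.
#'
#' @param scores numeric scores, oriented higher-is-worse.
#' @param labels logical outcome indicator.
#' @param threshold finite cut point.
#' @param direction `"ge"` (default) or `"gt"`.
#' @return list of class `confusion_counts`: `tp`, `fp`, `fn`, `tn`,
#'   `threshold`, `direction`.
#' @export
confusion_at_threshold <- function(scores, labels, threshold, direction = c("ge", "gt")) {
  direction <- match.arg(direction)
  if (!is.finite(threshold)) stopf("threshold must be finite")
  keep <- !is.na(scores) & !is.na(labels)
  s <- scores[keep]; y <- as.logical(labels[keep])
  pos <- if (direction == "ge") s >= threshold else s > threshold
  out <- list(tp = sum(pos & y), fp = sum(pos & !y),
              fn = sum(!pos & y), tn = sum(!pos & !y),
              threshold = threshold, direction = direction)
  attr(out, "n_missing") <- sum(!keep)
  class(out) <- "confusion_counts"
  out
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile exact interval for a binomial proportion, on the percentage
#' scale. The lower bound is exactly 0 when no successes are observed and the
#' upper bound exactly 100 when all trials succeed; for the all-successes
#' case the lower bound has the closed form \eqn{100\,(\alpha/2)^{1/n}}.
#'
#' @param successes number of successes, `0 <= successes <= trials`.
#' @param trials number of trials, at least 1.
#' @param level confidence level, default 0.95.
#' @return numeric `c(lo, hi)` in percent.
#' @export
#' @examples
#' clopper_pearson_ci(38, 38)  # lower bound 90.7 after rounding
clopper_pearson_ci <- function(successes, trials, level = 0.95) {
  if (trials < 1) stopf("Clopper-Pearson interval undefined for zero trials")
  if (successes < 0 || successes > trials)
    stopf("successes must be between 0 and trials")
  a <- 1 - level
  lo <- if (successes == 0) 0 else stats::qbeta(a / 2, successes, trials - successes + 1)
  hi <- if (successes == trials) 1 else stats::qbeta(1 - a / 2, successes + 1, trials - successes)
  100 * c(lo, hi)
}

#' Operating characteristics from a 2x2 table
#'
#' Sensitivity, specificity, positive and negative predictive value and
#' prevalence, each as a percentage with an exact Clopper-Pearson interval on
#' its own denominator. A metric whose denominator is empty (e.g. NPV when
#' nothing tests negative) is reported as `NA`, not 0. Values are unrounded;
#' the print method rounds half-up to one decimal.
#'
#' @param counts a `confusion_counts` object (or list with `tp`, `fp`, `fn`,
#'   `tn`).
#' @param level confidence level for the intervals.
#' @return one-row data frame with `est`, `lo`, `hi` columns for
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `prevalence`, plus the four
#'   counts.
#' @export
diagnostic_metrics <- function(counts, level = 0.95) {
  with_ci <- function(x, n) {
    if (n == 0) return(c(NA_real_, NA_real_, NA_real_))
    c(100 * x / n, clopper_pearson_ci(x, n, level))
  }
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  sens <- with_ci(tp, tp + fn)
  spec <- with_ci(tn, tn + fp)
  ppv <- with_ci(tp, tp + fp)
  npv <- with_ci(tn, tn + fn)
  prev <- with_ci(tp + fn, tp + fp + fn + tn)
  data.frame(tp = tp, fp = fp, fn = fn, tn = tn,
             sensitivity = sens[1], sensitivity_lo = sens[2], sensitivity_hi = sens[3],
             specificity = spec[1], specificity_lo = spec[2], specificity_hi = spec[3],
             ppv = ppv[1], ppv_lo = ppv[2], ppv_hi = ppv[3],
             npv = npv[1], npv_lo = npv[2], npv_hi = npv[3],
             prevalence = prev[1], prevalence_lo = prev[2], prevalence_hi = prev[3],
             stringsAsFactors = FALSE)
}

#' Threshold performance table
#'
#' Operating characteristics of a predictor at a set of cut points for each
#' outcome: the machinery behind rule-out (high sensitivity / NPV) versus
#' rule-in (high specificity / PPV) threshold selection. Patients missing the
#' predictor or the outcome are dropped per cell and counted in `n_used`.
#'
#' @param tab per-patient data frame from [analysis_table()].
#' @param predictor predictor column, oriented higher-is-worse (default
#'   `"si"`).
#' @param thresholds numeric cut points (inclusive, score >= cut is
#'   positive); default the four shock-index candidates 0.7, 0.9, 1.4, 1.7.
#' @param outcomes outcome columns.
#' @param level confidence level.
#' @return data frame of class `shock_threshold_table`, one row per outcome x
#'   threshold.
#' @export
threshold_table <- function(tab, predictor = "si",
                            thresholds = c(0.7, 0.9, 1.4, 1.7),
                            outcomes = c("death", "smo", "smo_ci"),
                            level = 0.95) {
  if (!predictor %in% names(tab)) stopf("predictor column '%s' not found", predictor)
  rows <- list()
  for (oc in outcomes) {
    for (th in thresholds) {
      cc <- confusion_at_threshold(tab[[predictor]], tab[[oc]], th)
      met <- diagnostic_metrics(cc, level = level)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(outcome = oc, predictor = predictor, threshold = th,
                         n_used = with(cc, tp + fp + fn + tn),
                         n_missing = attr(cc, "n_missing"),
                         stringsAsFactors = FALSE),
              met)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "level") <- level
  class(out) <- c("shock_threshold_table", "data.frame")
  out
}

#' @export
print.shock_threshold_table <- function(x, ...) {
  cat(sprintf("Operating characteristics of %s at %s (%% with exact %.0f%% CI)\n",
              x$predictor[1],
              paste(">=", unique(x$threshold), collapse = ", "),
              100 * attr(x, "level")))
  show <- data.frame(outcome = x$outcome,
                     threshold = sprintf(">=%.1f", x$threshold),
                     sensitivity = fmt_ci(x$sensitivity, x$sensitivity_lo, x$sensitivity_hi),
                     specificity = fmt_ci(x$specificity, x$specificity_lo, x$specificity_hi),
                     ppv = fmt_ci(x$ppv, x$ppv_lo, x$ppv_hi),
                     npv = fmt_ci(x$npv, x$npv_lo, x$npv_hi),
                     prevalence = sprintf("%s (%d)", fmt1(x$prevalence), x$tp + x$fn),
                     stringsAsFactors = FALSE)
  print.data.frame(show, row.names = FALSE)
  invisible(x)
}

#' Fraction of scores at or above each threshold
#'
#' @param scores numeric scores (missing values ignored).
#' @param thresholds numeric vector of cut points.
#' @return named numeric vector of fractions, nonincreasing in the
#'   threshold.
#' @export
proportion_above <- function(scores, thresholds) {
  s <- scores[!is.na(scores)]
  out <- vapply(thresholds, function(t) mean(s >= t), numeric(1))
  names(out) <- paste0(">=", thresholds)
  out
}
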