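#' Predictor value at a target specificity
#'
#' The specificity-p centile of a predictor: the p-quantile of its values
#' among outcome-negative patients, so that a threshold placed there (with
#' score >= threshold counting test-positive) yields specificity of
#' approximately p. The point estimate is the type-7 empirical quantile
#' (linear interpolation); when heavy ties leave the achieved specificity
#' more than one order statistic short of the target, the estimate is moved
#' up to the next distinct negative value (ties resolved toward higher
#' specificity). The confidence interval is distribution-free, from binomial
#' bounds on the order statistics bracketing the quantile.
#'
#' @param scores numeric predictor values, oriented higher-is-worse.
#' @param labels logical outcome indicator.
#' @param level target specificity as a percentage in (0, 100); 0 and 100
#'   return the minimum and maximum of the negatives.
#' @param conf confidence level of the interval, default 0.95.
#' @param min_neg minimum number of outcome negatives required for a CI;
#'   below it the point estimate is returned with missing bounds and a
#'   warning.
#' @return one-row data frame: `level`, `value`, `lo`, `hi`, `n_neg`.
#' @export
value_at_specificity <- function(scores, labels, level, conf = 0.95, min_neg = 20) {
  if (level < 0 || level > 100) stopf("specificity level must be in [0, 100]")
  keep <- !is.na(scores) & !is.na(labels)
  neg <- sort(scores[keep & !labels])
  n <- length(neg)
  if (n < 1L) stopf("no outcome-negative subjects with a score")
  p <- level / 100
  q <- unname(stats::quantile(neg, p, type = 7))
  # ties straddling the quantile: specificity at q must not fall more than
  # one order statistic below target
  ach <- mean(neg < q)
  if (ach < p - 1 / n) {
    above <- neg[neg > q]
    if (length(above)) q <- min(above)
  }
  lo <- hi <- NA_real_
  if (n >= min_neg && level > 0 && level < 100) {
    a <- 1 - conf
    l_rank <- stats::qbinom(a / 2, n, p)
    u_rank <- stats::qbinom(1 - a / 2, n, p) + 1L
    lo <- neg[max(1L, l_rank)]
    hi <- neg[min(n, u_rank)]
  } else if (n < min_neg) {
    warnf("only %d outcome negatives: quantile CI omitted", n)
  }
  data.frame(level = level, value = q, lo = lo, hi = hi, n_neg = n)
}

#' Specificity-centile table
#'
#' Predictor values at several specificity levels for each outcome — the
#' basis of rule-in threshold derivation. Centiles depend only on the
#' outcome-negative patients, so a row is computable even for an outcome
#' with no positives.
#'
#' @param tab per-patient data frame from [analysis_table()].
#' @param predictor predictor column, oriented higher-is-worse.
#' @param outcomes outcome columns.
#' @param levels specificity percentages; default `c(60, 80, 95, 98, 99)`.
#' @param conf confidence level for the distribution-free intervals.
#' @return data frame of class `shock_centile_table`, one row per outcome x
#'   level.
#' @export
centile_table <- function(tab, predictor = "si",
                          outcomes = c("death", "smo", "smo_ci"),
                          levels = c(60, 80, 95, 98, 99),
                          conf = 0.95) {
  if (!predictor %in% names(tab)) stopf("predictor column '%s' not found", predictor)
  rows <- list()
  for (oc in outcomes) {
    for (lv in levels) {
      est <- value_at_specificity(tab[[predictor]], tab[[oc]], lv, conf = conf)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(outcome = oc, predictor = predictor,
                         stringsAsFactors = FALSE), est)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "conf") <- conf
  class(out) <- c("shock_centile_table", "data.frame")
  out
}

#' @export
print.shock_centile_table <- function(x, ...) {
  cat(sprintf("%s values at target specificity levels (%.0f%% distribution-free CI)\n",
              x$predictor[1], 100 * attr(x, "conf")))
  show <- data.frame(outcome = x$outcome,
                     specificity = paste0(x$level, "%"),
                     value = fmt_ci(x$value, x$lo, x$hi, digits = 2),
                     n_neg = x$n_neg,
                     stringsAsFactors = FALSE)
  print.data.frame(show, row.names = FALSE)
  invisible(x)
}
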