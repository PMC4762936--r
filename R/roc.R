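#' Predictor orientations
#'
#' Direction in which each vital-sign predictor signals risk. Shock index and
#' pulse rise with hemodynamic compromise; systolic/diastolic pressure and
#' MAP fall, so they are negated before ROC analysis. Pulse pressure is kept
#' on the higher-is-worse side: falling pulse pressure in shock then shows up
#' as an AUC below 0.5 rather than being silently re-oriented, which is how
#' the discrimination of an unoriented marker is conventionally reported.
#'
#' @return named character vector over the six predictors with values
#'   `"higher_is_worse"` or `"lower_is_worse"`.
#' @export
predictor_orientations <- function() {
  c(si = "higher_is_worse",
    pulse = "higher_is_worse",
    sbp = "lower_is_worse",
    dbp = "lower_is_worse",
    map = "lower_is_worse",
    pulse_pressure = "higher_is_worse")
}

.orient <- function(scores, orientation) {
  orientation <- match.arg(orientation, c("higher_is_worse", "lower_is_worse"))
  if (orientation == "lower_is_worse") -scores else scores
}

.complete_pairs <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  list(s = scores[keep], y = as.logical(labels[keep]))
}

#' Nonparametric (Mann-Whitney) AUC
#'
#' Empirical area under the ROC curve as the two-sample U-statistic: the
#' probability that a random outcome-positive patient scores above a random
#' outcome-negative one, ties counting one half. Computed via midranks, so it
#' is exactly the trapezoidal area under the empirical ROC curve with
#' tied-value plateaus.
#'
#' @param scores numeric predictor values (missing values dropped pairwise
#'   with the labels).
#' @param labels logical (or 0/1) outcome indicator.
#' @param orientation `"higher_is_worse"` (default) or `"lower_is_worse"`;
#'   lower-is-worse scores are negated before ranking.
#' @return the AUC, a number in \[0, 1\].
#' @export
auc_mann_whitney <- function(scores, labels, orientation = "higher_is_worse") {
  cp <- .complete_pairs(.orient(scores, orientation), labels)
  n1 <- sum(cp$y); n0 <- sum(!cp$y)
  if (n1 < 1L || n0 < 1L)
    stopf("AUC undefined: need at least one positive and one negative (got %d/%d)", n1, n0)
  r <- rank(cp$s)                       # midranks handle ties
  (sum(r[cp$y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-subject structural components of the AUC
#'
#' The placement values underlying the DeLong variance machinery: for each
#' positive subject, the fraction of negatives it outranks (`v10`, ties one
#' half); for each negative, the fraction of positives ranking above it
#' (`v01`). Both component sets average exactly to the AUC.
#'
#' @inheritParams auc_mann_whitney
#' @return list with `v10` (length = number of positives), `v01` (length =
#'   number of negatives) and `auc`.
#' @export
delong_components <- function(scores, labels, orientation = "higher_is_worse") {
  cp <- .complete_pairs(.orient(scores, orientation), labels)
  n1 <- sum(cp$y); n0 <- sum(!cp$y)
  if (n1 < 1L || n0 < 1L)
    stopf("components undefined: need at least one positive and one negative")
  r_all <- rank(cp$s)
  r_pos <- rank(cp$s[cp$y])
  r_neg <- rank(cp$s[!cp$y])
  # midrank identity: (overall rank - within-class rank)/n_other counts the
  # other class strictly below, plus half of the ties
  v10 <- (r_all[cp$y] - r_pos) / n0
  v01 <- 1 - (r_all[!cp$y] - r_neg) / n1
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong covariance matrix of correlated AUC estimates
#'
#' For several predictors measured on the same subjects, estimates the
#' covariance matrix of their empirical AUCs as
#' `S10 / n_pos + S01 / n_neg`, where `S10` and `S01` are the sample
#' covariance matrices of the per-positive and per-negative structural
#' components. Rows with any missing value are dropped (complete-pairs
#' analysis), since paired comparison requires common subjects.
#'
#' @param score_set numeric matrix or data frame, one column per predictor,
#'   already oriented higher-is-worse (use `orientations` otherwise).
#' @param labels logical outcome indicator.
#' @param orientations optional character vector (recycled) of per-column
#'   orientations.
#' @return list with `cov` (k x k symmetric PSD matrix), `auc` (length k),
#'   `n_pos`, `n_neg`, `n_common`.
#' @export
delong_cov <- function(score_set, labels, orientations = "higher_is_worse") {
  score_set <- as.matrix(score_set)
  k <- ncol(score_set)
  orientations <- rep_len(orientations, k)
  for (j in seq_len(k)) score_set[, j] <- .orient(score_set[, j], orientations[j])
  keep <- stats::complete.cases(score_set) & !is.na(labels)
  s <- score_set[keep, , drop = FALSE]
  y <- as.logical(labels[keep])
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 < 2L || n0 < 2L)
    stopf("DeLong covariance needs at least two positives and two negatives (got %d/%d)",
          n1, n0)
  V10 <- matrix(0, n1, k)
  V01 <- matrix(0, n0, k)
  auc <- numeric(k)
  for (j in seq_len(k)) {
    comp <- delong_components(s[, j], y)
    V10[, j] <- comp$v10
    V01[, j] <- comp$v01
    auc[j] <- comp$auc
  }
  S <- stats::cov(V10) / n1 + stats::cov(V01) / n0
  list(cov = S, auc = auc, n_pos = n1, n_neg = n0, n_common = n1 + n0)
}

#' Confidence interval for an AUC
#'
#' Default is the Wald interval on the AUC scale truncated to \[0, 1\]; a
#' logit-scale interval (back-transformed, never needs truncation) is
#' available for AUCs near the boundary.
#'
#' @param auc point estimate.
#' @param var_auc its (DeLong) variance, nonnegative.
#' @param level confidence level, default 0.95.
#' @param method `"wald"` or `"logit"`.
#' @return numeric `c(lo, hi)`.
#' @export
auc_ci <- function(auc, var_auc, level = 0.95, method = c("wald", "logit")) {
  method <- match.arg(method)
  if (is.na(var_auc) || var_auc < 0) stopf("var_auc must be nonnegative")
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(var_auc)
  if (method == "wald") {
    lo <- max(0, auc - z * se)
    hi <- min(1, auc + z * se)
  } else {
    if (auc <= 0 || auc >= 1 || se == 0) return(c(auc, auc))
    lg <- stats::qlogis(auc)
    se_lg <- se / (auc * (1 - auc))
    lo <- stats::plogis(lg - z * se_lg)
    hi <- stats::plogis(lg + z * se_lg)
  }
  c(lo, hi)
}

#' Paired test of AUC equality for two correlated predictors
#'
#' Chi-square test (1 df) of equal discrimination for two predictors measured
#' on the same subjects: the squared AUC difference over the DeLong variance
#' of the difference, with a Bonferroni-adjusted p-value. Computed on the
#' subset of subjects where both predictors and the outcome are non-missing.
#'
#' @param ref,other numeric score vectors on the same subjects.
#' @param labels logical outcome indicator.
#' @param orientation_ref,orientation_other per-predictor orientation.
#' @param m number of comparisons for the Bonferroni correction (default 1).
#' @return list of class `auc_comparison`: `auc_ref`, `auc_other`, `chi2`,
#'   `df`, `p_raw`, `p_bonferroni`, `m`, `n_common`.
#' @export
compare_auc_paired <- function(ref, other, labels,
                               orientation_ref = "higher_is_worse",
                               orientation_other = "higher_is_worse",
                               m = 1) {
  dl <- delong_cov(cbind(ref = ref, other = other), labels,
                   orientations = c(orientation_ref, orientation_other))
  d <- dl$auc[1] - dl$auc[2]
  v <- dl$cov[1, 1] + dl$cov[2, 2] - 2 * dl$cov[1, 2]
  if (v <= .Machine$double.eps^0.5) {
    # zero variance of the difference: identical placements
    chi2 <- if (abs(d) < .Machine$double.eps^0.5) 0 else Inf
  } else {
    chi2 <- d^2 / v
  }
  p <- if (is.infinite(chi2)) 0 else stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  structure(list(auc_ref = dl$auc[1], auc_other = dl$auc[2],
                 diff = d, var_diff = v, chi2 = chi2, df = 1L,
                 p_raw = p, p_bonferroni = min(1, m * p), m = m,
                 n_common = dl$n_common, n_pos = dl$n_pos, n_neg = dl$n_neg),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("Paired AUC equality test (DeLong): %.3f vs %.3f on %d subjects\n",
              x$auc_ref, x$auc_other, x$n_common))
  cat(sprintf("  chi2 = %.3f (1 df), p = %.4g, Bonferroni (m=%d) p = %.4g\n",
              x$chi2, x$p_raw, x$m, x$p_bonferroni))
  invisible(x)
}

#' Empirical ROC curve
#'
#' Operating points of the test "score >= threshold is positive" at every
#' distinct score value, plus the two trivial endpoints. The curve starts at
#' (0, 0), ends at (1, 1) and is monotone nondecreasing in both coordinates;
#' tied scores produce diagonal segments whose trapezoidal area equals the
#' midrank U-statistic AUC exactly.
#'
#' @inheritParams auc_mann_whitney
#' @return data frame with `threshold` (on the oriented scale; `Inf` for the
#'   (0,0) corner), `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels, orientation = "higher_is_worse") {
  cp <- .complete_pairs(.orient(scores, orientation), labels)
  n1 <- sum(cp$y); n0 <- sum(!cp$y)
  if (n1 < 1L || n0 < 1L) stopf("ROC curve undefined without both classes")
  ord <- order(cp$s, decreasing = TRUE)
  s <- cp$s[ord]; y <- cp$y[ord]
  idx <- which(!duplicated(s, fromLast = TRUE)) # last index of each tied run
  tpr <- cumsum(y)[idx] / n1
  fpr <- cumsum(!y)[idx] / n0
  data.frame(threshold = c(Inf, s[idx]),
             fpr = c(0, fpr),
             tpr = c(0, tpr))
}

# trapezoidal area under a roc_curve() data frame
auc_trapezoid <- function(curve) {
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
}

#' AUC table with paired comparisons against a reference predictor
#'
#' For every predictor x outcome cell of the per-patient analysis table,
#' computes the sample size, empirical AUC and DeLong confidence interval;
#' each non-reference predictor is then compared with the reference by the
#' paired chi-square test on their complete-pairs subset, with Bonferroni
#' correction over the non-reference predictors within each outcome.
#'
#' @param tab per-patient data frame from [analysis_table()].
#' @param predictors character vector of predictor columns; defaults to the
#'   six vital-sign predictors.
#' @param outcomes character vector of outcome columns.
#' @param reference predictor against which the others are tested.
#' @param bonferroni_m correction multiplier; default is the number of
#'   non-reference predictors (per outcome).
#' @param level confidence level for the AUC intervals.
#' @param ci_method `"wald"` or `"logit"`, see [auc_ci()].
#' @return data frame of class `shock_roc_table`: one row per predictor x
#'   outcome with `n`, `n_pos`, `auc`, `lo`, `hi`, `chi2`, `p_raw`,
#'   `p_bonferroni`, `sig` (`""`, `"*"` p<0.05, `"**"` p<0.01, Bonferroni
#'   adjusted, only where the predictor is worse than the reference).
#' @export
roc_table <- function(tab,
                      predictors = names(predictor_orientations()),
                      outcomes = c("death", "smo", "smo_ci"),
                      reference = "si",
                      bonferroni_m = NULL,
                      level = 0.95,
                      ci_method = "wald") {
  orient <- predictor_orientations()
  unknown <- setdiff(predictors, names(orient))
  if (length(unknown))
    stopf("unknown predictor(s): %s", paste(unknown, collapse = ", "))
  if (!all(outcomes %in% names(tab)))
    stopf("outcome column(s) missing from table: %s",
          paste(setdiff(outcomes, names(tab)), collapse = ", "))
  if (length(predictors) > 1L && !reference %in% predictors)
    stopf("reference predictor '%s' not among predictors", reference)
  m <- bonferroni_m %||% max(1L, length(predictors) - 1L)

  rows <- list()
  for (oc in outcomes) {
    for (pr in predictors) {
      scores <- tab[[pr]]
      labels <- tab[[oc]]
      keep <- !is.na(scores) & !is.na(labels)
      row <- data.frame(predictor = pr, outcome = oc,
                        n = sum(keep), n_pos = sum(labels[keep]),
                        auc = NA_real_, lo = NA_real_, hi = NA_real_,
                        chi2 = NA_real_, p_raw = NA_real_,
                        p_bonferroni = NA_real_, sig = "",
                        stringsAsFactors = FALSE)
      ok <- sum(labels[keep]) >= 2 && sum(!labels[keep]) >= 2
      if (ok) {
        dl <- delong_cov(matrix(scores, ncol = 1), labels,
                         orientations = orient[[pr]])
        ci <- auc_ci(dl$auc, dl$cov[1, 1], level = level, method = ci_method)
        row$auc <- dl$auc
        row$lo <- ci[1]
        row$hi <- ci[2]
        if (pr != reference && length(predictors) > 1L) {
          cmp <- compare_auc_paired(tab[[reference]], scores, labels,
                                    orientation_ref = orient[[reference]],
                                    orientation_other = orient[[pr]], m = m)
          row$chi2 <- cmp$chi2
          row$p_raw <- cmp$p_raw
          row$p_bonferroni <- cmp$p_bonferroni
          worse <- cmp$auc_other < cmp$auc_ref
          row$sig <- if (worse && cmp$p_bonferroni < 0.01) "**"
                     else if (worse && cmp$p_bonferroni < 0.05) "*"
                     else ""
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "reference") <- reference
  attr(out, "bonferroni_m") <- m
  attr(out, "level") <- level
  class(out) <- c("shock_roc_table", "data.frame")
  out
}

#' @export
print.shock_roc_table <- function(x, ...) {
  cat(sprintf("AUC (%.0f%% CI) by predictor and outcome; reference = %s, Bonferroni m = %d\n",
              100 * attr(x, "level"), attr(x, "reference"), attr(x, "bonferroni_m")))
  wide <- unique(x$predictor)
  for (oc in unique(x$outcome)) {
    cat("\n ", oc, "\n")
    sub <- x[x$outcome == oc, , drop = FALSE]
    cell <- sprintf("%5.2f (%4.2f-%4.2f)%-2s [n=%d]",
                    sub$auc, sub$lo, sub$hi, sub$sig, sub$n)
    cell[is.na(sub$auc)] <- "  --"
    for (i in seq_len(nrow(sub)))
      cat(sprintf("  %-15s %s\n", sub$predictor[i], cell[i]))
  }
  cat("\n  *, ** : worse than reference at Bonferroni-adjusted p<0.05, p<0.01\n")
  invisible(x)
}
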