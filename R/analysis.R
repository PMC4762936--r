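#' Full vital-sign threshold analysis of a cohort
#'
#' Runs the whole analysis on one cohort: exclusions, worst-point selection,
#' outcome construction, the AUC table with paired comparisons against the
#' reference predictor, threshold operating characteristics, and
#' specificity-centile derivation. This is the programmatic core that
#' [run_pipeline()] wraps with file output.
#'
#' @param cohort a `shock_cohort` (long) data frame.
#' @param window_minutes first-hour analysis window, default 60.
#' @param rule worst-point selection rule, see [derive_worst_points()].
#' @param predictors,outcomes,reference,bonferroni_m,ci_method passed to
#'   [roc_table()].
#' @param thresholds,threshold_predictor passed to [threshold_table()].
#' @param centile_levels passed to [centile_table()].
#' @param level confidence level used throughout.
#' @return object of class `shock_analysis`: list with the filtered cohort's
#'   exclusion log, the per-patient `table`, `vitals_summary` (median/IQR per
#'   predictor), `prevalence`, `roc`, `thresholds`, `proportion_above`,
#'   `centiles` and the call.
#' @export
shock_analysis <- function(cohort,
                           window_minutes = 60,
                           rule = "max_si",
                           predictors = names(predictor_orientations()),
                           outcomes = c("death", "smo", "smo_ci"),
                           reference = "si",
                           bonferroni_m = NULL,
                           thresholds = c(0.7, 0.9, 1.4, 1.7),
                           threshold_predictor = "si",
                           centile_levels = c(60, 80, 95, 98, 99),
                           level = 0.95,
                           ci_method = "wald") {
  unknown <- setdiff(c(predictors, threshold_predictor), names(predictor_orientations()))
  if (length(unknown))
    stopf("config error: unknown predictor(s): %s", paste(unknown, collapse = ", "))
  unknown_oc <- setdiff(outcomes, c("death", "smo", "smo_ci"))
  if (length(unknown_oc))
    stopf("config error: unknown outcome(s): %s", paste(unknown_oc, collapse = ", "))

  kept <- apply_exclusions(cohort, window_minutes = window_minutes)
  tab <- analysis_table(kept, window_minutes = window_minutes, rule = rule)

  vs <- do.call(rbind, lapply(predictors, function(pr) {
    x <- tab[[pr]][!is.na(tab[[pr]])]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7)
    data.frame(predictor = pr, n = length(x),
               median = unname(q[2]), q1 = unname(q[1]), q3 = unname(q[3]),
               stringsAsFactors = FALSE)
  }))

  out <- list(
    call = match.call(),
    n_input = attr(kept, "n_input"),
    n_retained = attr(kept, "n_retained"),
    exclusions = exclusion_log(kept),
    rule = rule,
    window_minutes = window_minutes,
    table = tab,
    vitals_summary = vs,
    prevalence = outcome_prevalence(tab[, c("patient_id", outcomes)]),
    roc = roc_table(tab, predictors = predictors, outcomes = outcomes,
                    reference = reference, bonferroni_m = bonferroni_m,
                    level = level, ci_method = ci_method),
    thresholds = threshold_table(tab, predictor = threshold_predictor,
                                 thresholds = thresholds, outcomes = outcomes,
                                 level = level),
    proportion_above = proportion_above(tab[[threshold_predictor]], thresholds),
    centiles = centile_table(tab, predictor = threshold_predictor,
                             outcomes = outcomes, levels = centile_levels,
                             conf = level),
    reference = reference,
    threshold_predictor = threshold_predictor
  )
  class(out) <- "shock_analysis"
  out
}

#' @export
print.shock_analysis <- function(x, ...) {
  cat(sprintf("Vital-sign threshold analysis: %d of %d records retained (rule = %s, window = [0, %d] min)\n",
              x$n_retained, x$n_input, x$rule, x$window_minutes))
  cat("\nOutcome prevalence:\n")
  pv <- x$prevalence
  for (i in seq_len(nrow(pv)))
    cat(sprintf("  %-8s %3d/%d (%s%%)\n", pv$outcome[i], pv$count[i], pv$n[i],
                fmt1(pv$prevalence[i])))
  cat(sprintf("\nProportion of patients at or above each %s threshold:\n",
              x$threshold_predictor))
  cat(sprintf("  %s\n", paste(names(x$proportion_above),
                              fmt1(100 * x$proportion_above), collapse = "  ")))
  cat("\nUse summary() for the AUC, threshold and centile tables; plot() for ROC curves.\n")
  invisible(x)
}

#' @export
summary.shock_analysis <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$roc)
  cat("\n")
  print(object$thresholds)
  cat("\n")
  print(object$centiles)
  invisible(object)
}

#' ROC curves of the reference predictor for each outcome
#'
#' @param x a `shock_analysis` object.
#' @param predictor predictor to plot; defaults to the analysis reference.
#' @param ... passed to [graphics::plot()].
#' @export
plot.shock_analysis <- function(x, predictor = x$reference, ...) {
  orient <- predictor_orientations()[[predictor]]
  ocs <- unique(x$roc$outcome)
  graphics::plot(c(0, 1), c(0, 1), type = "n",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("ROC curves: %s", predictor), ...)
  graphics::abline(0, 1, col = "grey70", lty = 2)
  for (i in seq_along(ocs)) {
    cv <- roc_curve(x$table[[predictor]], x$table[[ocs[i]]], orientation = orient)
    graphics::lines(cv$fpr, cv$tpr, col = i + 1, lwd = 2)
  }
  graphics::legend("bottomright", legend = ocs, col = seq_along(ocs) + 1,
                   lwd = 2, bty = "n")
  invisible(x)
}

#' Pipeline configuration
#'
#' Bundles and validates every knob of [run_pipeline()]. Either `input` (a
#' cohort CSV path) or simulation settings (`n`, `seed`, `params`) must be
#' given; validation happens before any computation.
#'
#' @param input optional path to a cohort CSV; when `NULL` a cohort is
#'   simulated.
#' @param n,seed,params simulation settings, see [generate_cohort()].
#' @param output_dir directory for the report bundle.
#' @inheritParams shock_analysis
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, n = 958, seed = 1L,
                            params = NULL,
                            output_dir = tempfile("shockindex_report_"),
                            window_minutes = 60, rule = "max_si",
                            predictors = names(predictor_orientations()),
                            outcomes = c("death", "smo", "smo_ci"),
                            reference = "si", bonferroni_m = NULL,
                            thresholds = c(0.7, 0.9, 1.4, 1.7),
                            threshold_predictor = "si",
                            centile_levels = c(60, 80, 95, 98, 99),
                            level = 0.95) {
  rule <- match.arg(rule, .selection_rules)
  unknown <- setdiff(c(predictors, reference, threshold_predictor),
                     names(predictor_orientations()))
  if (length(unknown))
    stopf("config error: unknown predictor(s): %s", paste(unknown, collapse = ", "))
  unknown_oc <- setdiff(outcomes, c("death", "smo", "smo_ci"))
  if (length(unknown_oc))
    stopf("config error: unknown outcome(s): %s", paste(unknown_oc, collapse = ", "))
  if (!is.null(input) && !file.exists(input))
    stopf("config error: input file not found: %s", input)
  structure(list(input = input, n = n, seed = seed, params = params,
                 output_dir = output_dir, window_minutes = window_minutes,
                 rule = rule, predictors = predictors, outcomes = outcomes,
                 reference = reference, bonferroni_m = bonferroni_m,
                 thresholds = thresholds,
                 threshold_predictor = threshold_predictor,
                 centile_levels = centile_levels, level = level),
            class = "pipeline_config")
}

#' Run the end-to-end pipeline and write the report bundle
#'
#' Simulates or reads a cohort, applies exclusions, derives worst-point
#' vitals and outcomes, and writes the full set of report files to
#' `config$output_dir`: `cohort.csv`, `derived.csv`, `vitals_summary.csv`,
#' `roc_auc.csv`, `roc_curves.csv`, `thresholds.csv`, `centiles.csv`,
#' `exclusions.jsonl` and `run_log.json`. Reports are deterministic given
#' the seed and configuration. On error, partially written outputs are
#' removed and the error is re-thrown tagged with the failing stage.
#'
#' @param config a [pipeline_config()] object.
#' @return the `shock_analysis` object, invisibly; the file paths are in
#'   attribute `"files"`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stopf("config error: expected a pipeline_config object")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  ok <- FALSE
  on.exit(if (!ok && length(written)) unlink(written), add = TRUE)
  emit <- function(name, writer) {
    path <- file.path(config$output_dir, name)
    writer(path)
    written <<- c(written, path)
    path
  }
  stage <- "load"
  res <- tryCatch({
    cohort <- if (is.null(config$input)) {
      generate_cohort(n = config$n, seed = config$seed,
                      params = config$params %||% default_cohort_params())
    } else {
      read_cohort(config$input)
    }
    emit("cohort.csv", function(p) write_cohort(cohort, p))

    stage <- "analysis"
    an <- shock_analysis(cohort,
                         window_minutes = config$window_minutes,
                         rule = config$rule,
                         predictors = config$predictors,
                         outcomes = config$outcomes,
                         reference = config$reference,
                         bonferroni_m = config$bonferroni_m,
                         thresholds = config$thresholds,
                         threshold_predictor = config$threshold_predictor,
                         centile_levels = config$centile_levels,
                         level = config$level)

    stage <- "write"
    emit("derived.csv", function(p)
      utils::write.csv(an$table, p, row.names = FALSE, na = ""))
    emit("vitals_summary.csv", function(p)
      utils::write.csv(an$vitals_summary, p, row.names = FALSE, na = ""))
    emit("roc_auc.csv", function(p)
      utils::write.csv(as.data.frame(an$roc), p, row.names = FALSE, na = ""))
    emit("roc_curves.csv", function(p) {
      curves <- do.call(rbind, lapply(config$outcomes, function(oc) {
        cv <- roc_curve(an$table[[config$reference]], an$table[[oc]],
                        predictor_orientations()[[config$reference]])
        cbind(data.frame(predictor = config$reference, outcome = oc,
                         stringsAsFactors = FALSE), cv)
      }))
      utils::write.csv(curves, p, row.names = FALSE, na = "")
    })
    emit("thresholds.csv", function(p)
      utils::write.csv(as.data.frame(an$thresholds), p, row.names = FALSE, na = ""))
    emit("centiles.csv", function(p)
      utils::write.csv(as.data.frame(an$centiles), p, row.names = FALSE, na = ""))
    emit("exclusions.jsonl", function(p) {
      con <- file(p, open = "wt")
      on.exit(close(con))
      if (nrow(an$exclusions))
        for (i in seq_len(nrow(an$exclusions)))
          writeLines(jsonlite::toJSON(as.list(an$exclusions[i, ]),
                                      auto_unbox = TRUE), con)
    })
    emit("run_log.json", function(p) {
      log <- list(
        seed = config$seed,
        input = config$input %||% "simulated",
        n_input = an$n_input, n_retained = an$n_retained,
        exclusion_reasons = as.list(table(an$exclusions$reason)),
        rule = an$rule, window_minutes = an$window_minutes,
        cell_n = stats::setNames(as.list(an$roc$n),
                                 paste(an$roc$predictor, an$roc$outcome, sep = ".")),
        threshold_n = stats::setNames(as.list(an$thresholds$n_used),
                                      paste(an$thresholds$outcome,
                                            an$thresholds$threshold, sep = ".")))
      jsonlite::write_json(log, p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    })
    ok <- TRUE
    an
  }, error = function(e) {
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  attr(res, "files") <- written
  invisible(res)
}

#' Sensitivity of the AUC table to the worst-point convention
#'
#' Recomputes every predictor x outcome AUC under each of the four
#' worst-point selection rules and reports the per-cell spread (maximum
#' minus minimum AUC across rules), flagging cells where the choice of rule
#' moves the AUC by more than `flag_above`.
#'
#' @param cohort a `shock_cohort` data frame.
#' @inheritParams shock_analysis
#' @param flag_above spread above which a cell is flagged, default 0.05.
#' @return data frame with one row per predictor x outcome: the AUC under
#'   each rule, `spread`, and `flagged`.
#' @export
worst_point_sensitivity <- function(cohort,
                                    window_minutes = 60,
                                    predictors = names(predictor_orientations()),
                                    outcomes = c("death", "smo", "smo_ci"),
                                    flag_above = 0.05) {
  kept <- apply_exclusions(cohort, window_minutes = window_minutes)
  orient <- predictor_orientations()
  aucs <- lapply(.selection_rules, function(rule) {
    tab <- analysis_table(kept, window_minutes = window_minutes, rule = rule)
    cells <- vapply(outcomes, function(oc) {
      vapply(predictors, function(pr) {
        keep <- !is.na(tab[[pr]]) & !is.na(tab[[oc]])
        if (sum(tab[[oc]][keep]) < 1 || sum(!tab[[oc]][keep]) < 1) return(NA_real_)
        auc_mann_whitney(tab[[pr]], tab[[oc]], orient[[pr]])
      }, numeric(1))
    }, numeric(length(predictors)))
    matrix(cells, nrow = length(predictors),
           dimnames = list(predictors, outcomes))
  })
  names(aucs) <- .selection_rules
  grid <- expand.grid(predictor = predictors, outcome = outcomes,
                      stringsAsFactors = FALSE)
  for (rule in .selection_rules)
    grid[[rule]] <- mapply(function(pr, oc) aucs[[rule]][pr, oc],
                           grid$predictor, grid$outcome)
  vals <- as.matrix(grid[, .selection_rules])
  grid$spread <- apply(vals, 1, function(v) diff(range(v, na.rm = TRUE)))
  grid$flagged <- grid$spread > flag_above
  grid
}
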