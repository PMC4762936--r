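test_that("confusion counts enumerate correctly with inclusive thresholds", {
  cc <- confusion_at_threshold(c(1.5, 1.3, 0.8), c(TRUE, FALSE, FALSE), 1.4)
  expect_equal(with(cc, c(tp, fp, fn, tn)), c(1, 0, 0, 2))
  # threshold below all scores: nothing tests negative
  cc <- confusion_at_threshold(c(1.5, 1.3), c(TRUE, FALSE), 0.5)
  expect_equal(cc$fn + cc$tn, 0)
  # boundary value is test-positive under >=
  cc <- confusion_at_threshold(c(0.9), TRUE, 0.9)
  expect_equal(cc$tp, 1)
  cc <- confusion_at_threshold(c(0.9), TRUE, 0.9, direction = "gt")
  expect_equal(cc$fn, 1)
  # missing scores leave all four cells
  cc <- confusion_at_threshold(c(1.5, NA, 0.8), c(TRUE, TRUE, FALSE), 1.0)
  expect_equal(with(cc, tp + fp + fn + tn), 2)
  expect_equal(attr(cc, "n_missing"), 1)
})

test_that("Clopper-Pearson bounds match closed forms and binom.test", {
  # all-successes lower bound: 100 * (alpha/2)^(1/n)
  for (n in c(4, 10, 38, 48))
    expect_equal(clopper_pearson_ci(n, n)[1], 100 * 0.025^(1 / n), tolerance = 1e-10)
  expect_equal(clopper_pearson_ci(0, 10)[1], 0)
  expect_equal(clopper_pearson_ci(10, 10)[2], 100)
  # independent oracle across a grid
  for (x in c(0, 1, 5, 17, 33)) {
    bt <- 100 * binom.test(x, 38)$conf.int
    expect_equal(clopper_pearson_ci(x, 38), as.numeric(bt), tolerance = 1e-10)
  }
  expect_error(clopper_pearson_ci(1, 0), "zero trials")
})

test_that("metrics from a reconstructed 2x2 table match the printed row", {
  # Died at SI >= 1.4: TP=33, FN=5, FP=274, TN=640
  met <- diagnostic_metrics(list(tp = 33, fp = 274, fn = 5, tn = 640))
  expect_equal(round_half_up(met$sensitivity, 1), 86.8)
  expect_equal(round_half_up(met$specificity, 1), 70.0)
  expect_equal(round_half_up(met$ppv, 1), 10.7)
  expect_equal(round_half_up(met$npv, 1), 99.2)
  expect_equal(round_half_up(c(met$sensitivity_lo, met$sensitivity_hi), 1),
               c(71.9, 95.6))
  # symmetric table: everything 50
  met <- diagnostic_metrics(list(tp = 1, fp = 1, fn = 1, tn = 1))
  expect_equal(unlist(met[c("sensitivity", "specificity", "ppv", "npv")]),
               c(sensitivity = 50, specificity = 50, ppv = 50, npv = 50))
})

test_that("empty denominators report NA rather than zero", {
  met <- diagnostic_metrics(list(tp = 3, fp = 2, fn = 0, tn = 0))
  expect_true(is.na(met$npv))
  expect_true(is.na(met$npv_lo))
  expect_equal(met$sensitivity, 100)
})

test_that("PPV is Bayes-consistent with sensitivity, specificity and prevalence", {
  co <- generate_cohort(600, seed = 71)
  tab <- analysis_table(apply_exclusions(co))
  tt <- threshold_table(tab)
  for (i in seq_len(nrow(tt))) {
    se <- tt$sensitivity[i] / 100; sp <- tt$specificity[i] / 100
    pr <- tt$prevalence[i] / 100
    bayes <- 100 * se * pr / (se * pr + (1 - sp) * (1 - pr))
    expect_equal(tt$ppv[i], bayes, tolerance = 1e-9)
  }
})

test_that("sensitivity falls and specificity rises along a threshold sweep", {
  co <- generate_cohort(500, seed = 73)
  tab <- analysis_table(apply_exclusions(co))
  tt <- threshold_table(tab, thresholds = seq(0.6, 2.2, by = 0.2),
                        outcomes = "smo_ci")
  expect_true(all(diff(tt$sensitivity) <= 1e-12))
  expect_true(all(diff(tt$specificity) >= -1e-12))
})

test_that("proportion above thresholds is a nonincreasing fraction", {
  expect_equal(unname(proportion_above(c(0.8, 1.0, 1.5, 2.0), 1.4)), 0.5)
  expect_equal(unname(proportion_above(c(1.0, 1.2), 0.9)), 1.0)
  p <- proportion_above(rnorm(200, 1.3, 0.3), c(0.7, 0.9, 1.4, 1.7))
  expect_true(all(diff(p) <= 0))
})
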