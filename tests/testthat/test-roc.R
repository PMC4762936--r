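test_that("the worked placement example reproduces by hand", {
  s <- c(3, 2, 1, 2); y <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(auc_mann_whitney(s, y), 0.875) # (1 + 1 + 1 + 0.5) / 4
  comp <- delong_components(s, y)
  expect_equal(comp$v10, c(1, 0.75))
  expect_equal(comp$v01, c(1, 0.75))
  expect_equal(comp$auc, 0.875)
})

test_that("degenerate and boundary AUC cases", {
  expect_equal(auc_mann_whitney(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc_mann_whitney(rep(2, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_error(auc_mann_whitney(1:4, rep(TRUE, 4)), "at least one")
  one <- delong_components(c(2, 1), c(TRUE, FALSE))
  expect_equal(one$v10, 1)
  expect_equal(one$v01, 1)
})

test_that("U-statistic, components mean, and trapezoidal ROC area agree exactly", {
  set.seed(101)
  for (i in 1:300) {
    inst <- random_tied_instance()
    a_brute <- brute_auc(inst$s, inst$y)
    a_mw <- auc_mann_whitney(inst$s, inst$y)
    comp <- delong_components(inst$s, inst$y)
    curve <- roc_curve(inst$s, inst$y)
    a_trap <- shockindex:::auc_trapezoid(curve)
    expect_equal(a_mw, a_brute, tolerance = 1e-12)
    expect_equal(mean(comp$v10), a_brute, tolerance = 1e-12)
    expect_equal(mean(comp$v01), a_brute, tolerance = 1e-12)
    expect_equal(a_trap, a_brute, tolerance = 1e-12)
  }
})

test_that("AUC is invariant to monotone transforms, antisymmetric to label swap", {
  set.seed(7)
  s <- rnorm(50); y <- runif(50) < 0.4
  a <- auc_mann_whitney(s, y)
  expect_equal(auc_mann_whitney(exp(s), y), a)
  expect_equal(auc_mann_whitney(s, !y), 1 - a)
  expect_equal(auc_mann_whitney(-s, y, orientation = "lower_is_worse"), a)
})

test_that("ROC curve is a monotone path from (0,0) to (1,1)", {
  set.seed(13)
  cv <- roc_curve(sample(0:5, 40, TRUE), runif(40) < 0.5)
  expect_equal(cv$fpr[1], 0); expect_equal(cv$tpr[1], 0)
  expect_equal(cv$fpr[nrow(cv)], 1); expect_equal(cv$tpr[nrow(cv)], 1)
  expect_true(all(diff(cv$fpr) >= 0))
  expect_true(all(diff(cv$tpr) >= 0))
})

test_that("DeLong covariance is consistent and PSD", {
  set.seed(23)
  z <- rnorm(60); y <- runif(60) < 0.4
  s1 <- z + rnorm(60); s2 <- z + rnorm(60)
  dl <- delong_cov(cbind(s1, s2), y)
  expect_equal(dl$cov, t(dl$cov))
  expect_true(all(eigen(dl$cov, only.values = TRUE)$values > -1e-12))
  # duplicated predictor: perfectly correlated AUC estimates
  dup <- delong_cov(cbind(s1, s1), y)
  expect_equal(dup$cov[1, 1], dup$cov[1, 2])
  # diagonal equals the single-predictor DeLong variance
  single <- delong_cov(cbind(s1), y)
  expect_equal(dl$cov[1, 1], single$cov[1, 1])
  expect_error(delong_cov(cbind(s1), c(TRUE, rep(FALSE, 59))), "two positives")
})

test_that("DeLong covariance matches a jackknife oracle", {
  set.seed(31)
  z <- rnorm(60); y <- runif(60) < 0.45
  S <- cbind(z + rnorm(60), z + rnorm(60, sd = 1.5))
  dl <- delong_cov(S, y)
  jk <- jackknife_auc_cov(S, y)
  expect_equal(dl$cov[1, 1], jk[1, 1], tolerance = 0.1)
  expect_equal(dl$cov[2, 2], jk[2, 2], tolerance = 0.1)
  expect_equal(dl$cov[1, 2], jk[1, 2], tolerance = 0.15)
})

test_that("variance and covariance agree with an independent implementation", {
  set.seed(41)
  z <- rnorm(80); y <- runif(80) < 0.4
  s1 <- z + rnorm(80); s2 <- z + rnorm(80)
  dl <- delong_cov(cbind(s1, s2), y)
  r1 <- pROC::roc(y, s1, direction = "<", quiet = TRUE)
  r2 <- pROC::roc(y, s2, direction = "<", quiet = TRUE)
  expect_equal(dl$auc[1], as.numeric(pROC::auc(r1)))
  expect_equal(dl$cov[1, 1], pROC::var(r1, method = "delong"))
  expect_equal(dl$cov[2, 2], pROC::var(r2, method = "delong"))
  expect_equal(dl$cov[1, 2], pROC::cov(r1, r2, method = "delong"))
})

test_that("AUC confidence intervals truncate and round-trip a printed interval", {
  expect_equal(auc_ci(0.5, 0), c(0.5, 0.5))
  expect_equal(auc_ci(0.99, 0.01)[2], 1)
  expect_gte(auc_ci(0.01, 0.01)[1], 0)
  # SI vs death: 0.87 with the SE implied by the printed 0.80-0.94 interval
  ci <- auc_ci(0.87, 0.0357^2)
  expect_equal(round_half_up(ci, 2), c(0.80, 0.94))
  lg <- auc_ci(0.87, 0.0357^2, method = "logit")
  expect_true(lg[1] > 0 && lg[2] < 1)
})

test_that("paired AUC comparison: identity, Bonferroni and variance identity", {
  set.seed(53)
  z <- rnorm(100); y <- runif(100) < 0.4
  s1 <- z + rnorm(100)
  self <- compare_auc_paired(s1, s1, y)
  expect_equal(self$chi2, 0)
  expect_equal(self$p_raw, 1)
  s2 <- z + rnorm(100)
  cmp <- compare_auc_paired(s1, s2, y, m = 5)
  expect_equal(cmp$chi2, cmp$diff^2 / cmp$var_diff)
  expect_equal(cmp$p_bonferroni, min(1, 5 * cmp$p_raw))
  expect_equal(stats::pchisq(cmp$chi2, 1, lower.tail = FALSE), cmp$p_raw)
})

test_that("roc_table shapes, null coverage, and config validation", {
  co <- generate_cohort(400, seed = 61)
  tab <- analysis_table(apply_exclusions(co))
  # outcome-independent scores: CIs should cover 0.5
  set.seed(62)
  tab$si <- rnorm(nrow(tab))
  rt <- roc_table(tab, predictors = "si", outcomes = "death")
  expect_true(rt$lo <= 0.5 && rt$hi >= 0.5)
  expect_true(is.na(rt$chi2))            # single predictor: no comparison
  expect_error(roc_table(tab, predictors = c("si", "temp")), "unknown predictor")

  tab2 <- analysis_table(apply_exclusions(generate_cohort(500, seed = 63)))
  rt2 <- roc_table(tab2)
  expect_equal(nrow(rt2), 18)
  expect_true(all(rt2$lo <= rt2$auc & rt2$auc <= rt2$hi, na.rm = TRUE))
  # DBP-involving cells run on the reduced complete-pairs subset
  expect_lt(rt2$n[rt2$predictor == "dbp" & rt2$outcome == "death"],
            rt2$n[rt2$predictor == "si" & rt2$outcome == "death"])
})
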