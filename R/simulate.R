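#' Closed-form AUC of a binormal score
#'
#' Exact AUC when scores are normal within outcome classes:
#' \eqn{\Phi(\mathrm{effect}/\sqrt{sd_{pos}^2 + sd_{neg}^2})}, where `effect`
#' is the separation of the class means. This is the calibration oracle for
#' the generator's latent-severity model; inverting it gives the latent
#' loading needed for a target AUC (`sqrt(2) * qnorm(target)` at unit
#' standard deviations).
#'
#' @param effect mean score difference, positives minus negatives.
#' @param sd_pos,sd_neg within-class standard deviations, positive.
#' @return the AUC.
#' @export
binormal_auc <- function(effect, sd_pos = 1, sd_neg = 1) {
  if (any(sd_pos <= 0) || any(sd_neg <= 0)) stopf("standard deviations must be positive")
  stats::pnorm(effect / sqrt(sd_pos^2 + sd_neg^2))
}

# quadrature grid over the latent severity scale
.z_grid <- function(m = 641, lim = 8) {
  z <- seq(-lim, lim, length.out = m)
  w <- stats::dnorm(z)
  list(z = z, w = w / sum(w))
}

# intercept a with E[plogis(a + b z)] = target, z ~ N(0,1)
.solve_intercept <- function(b, target) {
  g <- .z_grid()
  f <- function(a) sum(g$w * stats::plogis(a + b * g$z)) - target
  stats::uniroot(f, c(-40, 20), tol = 1e-10)$root
}

# mean and sd of the maximum of k iid standard normals (numeric integration)
.max_normal_moments <- function(k) {
  g <- .z_grid(2001, 10)
  dens <- k * g$w * stats::pnorm(g$z)^(k - 1)
  m1 <- sum(dens * g$z)
  m2 <- sum(dens * g$z^2)
  c(mean = m1, sd = sqrt(max(0, m2 - m1^2)))
}

# Expected worst-point-SI AUC for the death outcome under the generator's
# latent model, by quadrature. log SI is approximately linear in z with
# loading a_z = beta_pulse/mu_pulse + beta_sbp/mu_sbp; worst-point selection
# over k intervals leaves a residual of sd(max of k normals) * per-interval
# noise sd. AUC = P(S1 > S2 | Y1=1, Y2=0) integrates the normal kernel over
# the outcome-weighted latent distribution.
.expected_si_auc <- function(b, a_death, vitals) {
  a_z <- vitals$beta_pulse / vitals$mu_pulse + vitals$beta_sbp / vitals$mu_sbp
  sig_n <- sqrt((vitals$sd_within / vitals$mu_pulse)^2 +
                  (vitals$sd_within / vitals$mu_sbp)^2)
  s_eta <- .max_normal_moments(vitals$n_intervals)["sd"] * sig_n
  g <- .z_grid()
  p <- stats::plogis(a_death + b * g$z)
  prev <- sum(g$w * p)
  kern <- stats::pnorm(a_z * outer(g$z, g$z, "-") / (sqrt(2) * s_eta))
  num <- as.numeric((g$w * p) %*% kern %*% (g$w * (1 - p)))
  num / (prev * (1 - prev))
}

.default_vitals <- function() {
  list(mu_pulse = 112.5, beta_pulse = 6,
       mu_sbp = 96, beta_sbp = 12,
       sd_within = 7,
       mu_pp = 33, beta_pp = 2, sd_pp = 7, sd_pp_within = 2,
       n_intervals = 4, interval_minutes = 15)
}

# Table 1 hemorrhage-etiology frequencies (counts / 958)
.diagnosis_freq <- c(
  uterine_atony = 315, abortion_complications = 148, retained_placenta = 115,
  ectopic = 104, abruption = 84, ruptured_uterus = 51, previa = 49,
  lacerations = 40, other = 28, molar = 12, missing = 6, accreta = 6
)

#' Calibrate generator parameters to target discrimination and prevalences
#'
#' Chooses the latent-severity slope of the outcome model and the three
#' nested logistic intercepts so that, under the generator's single-factor
#' model, the expected worst-point shock-index AUC for death equals
#' `auc_target` and the marginal outcome prevalences equal
#' `prevalence_targets` in expectation. The slope is found by root-finding on
#' a quadrature approximation of the expected AUC (log-linearised shock
#' index, extreme-value residual for the worst-point selection); the
#' binormal inversion `sqrt(2) * qnorm(auc_target)` is recorded as the
#' latent-scale reference effect.
#'
#' @param auc_target expected AUC of worst-point SI for death, in (0.5, 1);
#'   0.5 returns a zero slope (no severity signal). Default 0.87.
#' @param prevalence_targets named numeric: marginal probabilities of
#'   `death`, `smo`, `smo_ci` (nested, nondecreasing). Defaults 0.041,
#'   0.066, 0.157.
#' @param vitals list of vital-sign generator settings (means, latent
#'   loadings, noise SDs, intervals); see the methods vignette.
#' @return a `generator_params` list accepted by [generate_cohort()].
#' @export
calibrate_cohort_params <- function(auc_target = 0.87,
                                    prevalence_targets = c(death = 0.041,
                                                           smo = 0.066,
                                                           smo_ci = 0.157),
                                    vitals = .default_vitals()) {
  if (auc_target < 0.5 || auc_target >= 1)
    stopf("unattainable AUC target %.3f: must be in [0.5, 1)", auc_target)
  if (is.unsorted(prevalence_targets))
    stopf("prevalence targets must be nondecreasing (nested outcomes)")
  if (any(prevalence_targets <= 0 | prevalence_targets >= 1))
    stopf("prevalence targets must be in (0, 1)")
  if (auc_target == 0.5) {
    slope <- 0
  } else {
    f <- function(b) .expected_si_auc(b, .solve_intercept(b, prevalence_targets[[1]]),
                                      vitals) - auc_target
    slope <- stats::uniroot(f, c(0.05, 8), tol = 1e-7)$root
  }
  intercepts <- vapply(prevalence_targets, function(p) .solve_intercept(slope, p),
                       numeric(1))
  names(intercepts) <- names(prevalence_targets)
  structure(list(
    vitals = vitals,
    outcome_slope = slope,
    outcome_intercepts = intercepts,
    latent_effect = sqrt(2) * stats::qnorm(auc_target),
    auc_target = auc_target,
    prevalence_targets = prevalence_targets,
    dbp_missing_rate = 0.10,
    pulse_missing_rate = 2 / 958,
    sbp_missing_rate = 4 / 958,
    context_phc_frac = 0.20,
    ebl_meanlog = log(1000), ebl_sdlog = 0.51,
    ebl_thresholds = c(phc = 500, tertiary = 750),
    age_mean = 28.3, age_sd = 6.4,
    diagnosis_freq = .diagnosis_freq,
    note = "calibrated by quadrature to the target SI-death AUC and outcome prevalences"
  ), class = "generator_params")
}

.pkg_cache <- new.env(parent = emptyenv())

#' Default generator parameters
#'
#' The calibrated defaults used throughout: expected SI-death AUC 0.87 and
#' outcome prevalences 4.1, 6.6 and 15.7 percent at the study's population
#' structure. Computed once per session by [calibrate_cohort_params()] and
#' cached.
#'
#' @return a `generator_params` list.
#' @export
default_cohort_params <- function() {
  if (is.null(.pkg_cache$default_params))
    .pkg_cache$default_params <- calibrate_cohort_params()
  .pkg_cache$default_params
}

#' Simulate a synthetic hypovolemic-shock cohort
#'
#' Seeded generator of cohorts with the statistical structure the analysis
#' assumes. Each patient carries a latent severity `z ~ N(0, 1)`; vitals on a
#' 15-minute grid load on `z` (pulse up, systolic pressure down) with
#' within-patient noise, diastolic pressure is coupled to systolic through a
#' nearly severity-independent pulse pressure, and the three nested outcomes
#' are drawn by thresholding a single uniform against nested logistic
#' probabilities in `z` — so death implies SMO implies SMO-CI by
#' construction. The study eligibility rule (entry SBP <= 100 and/or pulse
#' >= 100, EBL above the context threshold) is enforced by resampling
#' ineligible draws. DBP is set missing at random per patient. Fully
#' reproducible from `seed`.
#'
#' @param n number of patients, default 958 (the analytic sample size).
#' @param seed integer RNG seed; if `NULL` the current RNG stream is used.
#' @param params a `generator_params` list, see [default_cohort_params()]
#'   and [calibrate_cohort_params()].
#' @return a `shock_cohort` data frame (long format) with provenance
#'   attribute recording the seed and parameters.
#' @export
generate_cohort <- function(n = 958, seed = NULL, params = default_cohort_params()) {
  if (n < 1) stopf("n must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  vp <- params$vitals
  ni <- vp$n_intervals
  minutes <- (seq_len(ni) - 1L) * vp$interval_minutes

  z <- stats::rnorm(n)

  ## outcomes: one uniform against nested probabilities
  u <- stats::runif(n)
  pr <- vapply(params$outcome_intercepts,
               function(a) stats::plogis(a + params$outcome_slope * z),
               numeric(n))
  if (n == 1L) pr <- matrix(pr, nrow = 1)
  died <- u < pr[, 1]
  smo <- u < pr[, 2]
  smo_ci <- u < pr[, 3]

  diagnosis <- sample(names(params$diagnosis_freq), n, replace = TRUE,
                      prob = params$diagnosis_freq)
  eof <- smo & !died
  icu <- logical(n)
  hyst <- logical(n)
  units <- stats::rbinom(n, 4, 0.30)          # routine transfusions, 0-4 units

  ci_only <- which(smo_ci & !smo)
  if (length(ci_only)) {
    comp <- sample(c("icu", "txn", "hyst"), length(ci_only), replace = TRUE,
                   prob = c(0.50, 0.35, 0.15))
    icu[ci_only[comp == "icu"]] <- TRUE
    units[ci_only[comp == "txn"]] <- 5L + stats::rpois(sum(comp == "txn"), 1.5)
    hy <- ci_only[comp == "hyst"]
    hyst[hy] <- TRUE
    diagnosis[hy] <- "uterine_atony"          # hysterectomy counts for atony only
  }
  in_smo <- which(smo)
  if (length(in_smo)) {
    icu[in_smo] <- stats::runif(length(in_smo)) < 0.5
    big <- stats::runif(length(in_smo)) < 0.4
    units[in_smo[big]] <- 5L + stats::rpois(sum(big), 1.5)
  }
  # hysterectomies outside atony occur but do not enter the composite
  non_atony <- which(!hyst & diagnosis != "uterine_atony")
  hyst[non_atony] <- stats::runif(length(non_atony)) < 0.03

  ## context and eligibility-consistent blood loss (truncated lognormal)
  context <- ifelse(stats::runif(n) < params$context_phc_frac, "phc", "tertiary")
  thr <- params$ebl_thresholds[context]
  lo_q <- stats::plnorm(thr, params$ebl_meanlog, params$ebl_sdlog)
  ebl <- round(stats::qlnorm(stats::runif(n, lo_q, 1),
                             params$ebl_meanlog, params$ebl_sdlog))

  ## vitals: n x ni matrices; resample noise of entry-ineligible patients
  draw_block <- function(idx) {
    m <- length(idx)
    list(pulse = vp$mu_pulse + vp$beta_pulse * z[idx] +
           matrix(stats::rnorm(m * ni, 0, vp$sd_within), m, ni),
         sbp = vp$mu_sbp - vp$beta_sbp * z[idx] +
           matrix(stats::rnorm(m * ni, 0, vp$sd_within), m, ni))
  }
  blk <- draw_block(seq_len(n))
  pulse <- blk$pulse
  sbp <- blk$sbp
  for (iter in seq_len(100)) {
    bad <- which(!(sbp[, 1] <= 100 | pulse[, 1] >= 100))
    if (!length(bad)) break
    nb <- draw_block(bad)
    pulse[bad, ] <- nb$pulse
    sbp[bad, ] <- nb$sbp
  }
  still <- !(sbp[, 1] <= 100 | pulse[, 1] >= 100)
  sbp[still, 1] <- 100                         # vanishing-probability fallback

  pp_pat <- vp$mu_pp - vp$beta_pp * z + stats::rnorm(n, 0, vp$sd_pp)
  pp <- pp_pat + matrix(stats::rnorm(n * ni, 0, vp$sd_pp_within), n, ni)

  pulse <- pmax(round(pulse), 40)   # matrix first: pmax keeps its dim
  sbp <- pmax(round(sbp), 40)
  dbp <- pmax(pmin(round(sbp - pp), sbp - 5), 15)

  ## missingness: per-patient, disjoint for pulse/sbp so every record keeps
  ## a usable vital
  miss_dbp <- stats::runif(n) < params$dbp_missing_rate
  miss_pulse <- stats::runif(n) < params$pulse_missing_rate
  miss_sbp <- !miss_pulse & stats::runif(n) < params$sbp_missing_rate
  pulse[miss_pulse, ] <- NA_real_
  sbp[miss_sbp, ] <- NA_real_
  dbp[miss_dbp, ] <- NA_real_

  age <- pmin(49, pmax(15, round(stats::rnorm(n, params$age_mean, params$age_sd))))
  parity <- as.numeric(stats::rnbinom(n, size = 2, mu = 2.4))
  units <- as.numeric(units)          # CSV round-trip stores numerics as double

  id <- sprintf(paste0("P%0", max(4L, nchar(n)), "d"), seq_len(n))
  df <- data.frame(
    patient_id = rep(id, each = ni),
    entry_context = rep(context, each = ni),
    ebl_ml = rep(ebl, each = ni),
    diagnosis = rep(diagnosis, each = ni),
    minutes_from_entry = rep(minutes, times = n),
    pulse = as.vector(t(pulse)),
    sbp = as.vector(t(sbp)),
    dbp = as.vector(t(dbp)),
    died = rep(died, each = ni),
    end_organ_failure = rep(eof, each = ni),
    icu_admission = rep(icu, each = ni),
    transfusion_units = rep(units, each = ni),
    emergency_hysterectomy = rep(hyst, each = ni),
    age_years = rep(age, each = ni),
    parity = rep(parity, each = ni),
    stringsAsFactors = FALSE
  )
  .as_shock_cohort(df, provenance = list(
    generator = "shockindex::generate_cohort",
    seed = if (is.null(seed)) NA_integer_ else seed,
    n = n,
    auc_target = params$auc_target,
    prevalence_targets = params$prevalence_targets
  ))
}

#' @export
print.generator_params <- function(x, ...) {
  cat("<generator_params>\n")
  cat(sprintf("  outcome slope %.4f on latent severity; intercepts %s\n",
              x$outcome_slope,
              paste(sprintf("%s=%.3f", names(x$outcome_intercepts),
                            x$outcome_intercepts), collapse = ", ")))
  cat(sprintf("  targets: SI-death AUC %.2f; prevalences %s\n", x$auc_target,
              paste(sprintf("%.1f%%", 100 * x$prevalence_targets), collapse = ", ")))
  cat(sprintf("  vitals: pulse ~ %g + %g z, SBP ~ %g - %g z, noise sd %g, %d intervals\n",
              x$vitals$mu_pulse, x$vitals$beta_pulse, x$vitals$mu_sbp,
              x$vitals$beta_sbp, x$vitals$sd_within, x$vitals$n_intervals))
  invisible(x)
}
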