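---
title: "Methods: vital-sign threshold analysis for hypovolemic shock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vital-sign threshold analysis for hypovolemic shock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shockindex)
```

This vignette is the package's own account of the statistical methods it
implements, the choices that were genuinely open, and what its synthetic
cohorts do and do not establish about real data.

## The estimands

For a cohort of women in hypovolemic shock secondary to obstetric
hemorrhage, with vital signs recorded on a 15-minute grid, the package
evaluates six hemodynamic predictors — shock index SI = pulse/SBP, pulse,
SBP, DBP, MAP = (2·DBP + SBP)/3 mmHg, pulse pressure SBP − DBP mmHg —
against three nested adverse-outcome composites: death; SMO (death or
severe end-organ failure morbidity); and SMO-CI (SMO or ICU admission,
transfusion of ≥ 5 units, or emergency hysterectomy for intractable uterine
atony). Severe shock is defined as MAP strictly below 60 mmHg, the
perfusion bar for vital organs.

Three families of quantities are produced:

* per predictor and outcome, the nonparametric AUC with a DeLong interval
  and a paired test of equality against the reference predictor (SI);
* per candidate SI threshold, the 2×2 operating characteristics with exact
  binomial intervals, supporting a *rule-out* cut (high sensitivity/NPV:
  referral) and a *rule-in* cut (high specificity/PPV: urgent
  intervention);
* per target specificity level, the SI value whose ≥-threshold attains it —
  the specificity centile of SI among outcome negatives.

## Worst-point selection

The analysis point of each patient is the observation in the closed window
[0, 60] minutes from study entry that maximises SI; the window endpoint is
included because the 15-minute grid makes 60′ a natural final interval.
Alternative rules (highest pulse, lowest SBP, lowest MAP) feed a
sensitivity analysis (`worst_point_sensitivity()`), since selecting on the
highest SI could in principle favour SI as a predictor. SI is computed per
observation *before* maximisation: the worst point is one measurement
interval, not a mix of the highest pulse at one time and the lowest SBP at
another. Ties are broken toward the earliest time point — earlier detection
is the clinical framing, and nothing in the estimand favours a later tied
interval. Observations missing a field the rule needs are skipped rather
than failing the record; a record with no usable observation drops out of
analyses requiring that rule.

"Study entry" vitals, used for the eligibility rule (EBL above the context
threshold and SBP ≤ 100 mmHg and/or pulse ≥ 100 BPM), are taken from the
earliest observation of the record. Whether entry vitals and the first
grid interval coincide is not determined by the data schema; the
first-observation convention is the package's choice, and the eligibility
EBL bar is a parameter (750 mL for tertiary entry, 500 mL for
primary-health-clinic entry; 500 by default).

## ROC machinery

The AUC is the Mann–Whitney U-statistic with ties counted one half,
computed by midranks; it equals the trapezoidal area under the empirical
ROC curve with tied-value plateaus, and the test suite verifies the
equality exactly (to 1e−12) against a brute-force pair enumeration on
random tied instances. Variances and covariances of correlated AUCs use the
DeLong structural components: per-positive placements V10 and per-negative
placements V01, whose sample covariance matrices combine as
S = S10/n₁ + S01/n₀. Equality of two predictors' AUCs is tested by
χ² = (Â₁ − Â₂)² / Var(Â₁ − Â₂) on 1 df. When the variance of the
difference is numerically zero, the statistic is 0 (identical placements)
or +∞ (different AUCs with zero variance), giving p = 1 or p = 0 rather
than a division error.

Orientation is fixed per predictor: SI, pulse and pulse pressure score
higher-is-worse; SBP, DBP and MAP are negated. Pulse pressure is
deliberately *not* re-oriented even though it falls with shock — its AUC is
reported below 0.5, which preserves the conventional reading that an
unoriented marker's discrimination is visible in the magnitude of its
departure from 0.5 and keeps the sign of the paired comparison against SI
meaningful.

Comparisons run on the complete-pairs subset (both predictors and the
outcome non-missing): paired DeLong requires common subjects, so
DBP-involving comparisons use the reduced subset with DBP present. The
Bonferroni multiplier defaults to the number of non-reference predictors
within one outcome (m = 5 for the full predictor set) — the comparisons
form one family per outcome, not one family across outcomes. AUC intervals
are Wald on the AUC scale truncated to [0, 1]; a logit-scale interval is
available (`ci_method = "logit"`) for AUCs near the boundary.

## Exact intervals and threshold metrics

All threshold comparisons are inclusive (score ≥ cut is test-positive),
matching the clinical phrasing of "SI ≥ 0.9". Sensitivity, specificity,
PPV and NPV each get an exact Clopper–Pearson (beta-quantile) interval on
their own denominator; the all-successes lower bound has the closed form
(α/2)^(1/n), which is also how the interval method of a published table can
be identified from its printed bounds. Empty denominators (e.g. NPV when no
one tests negative) report as missing, never as zero. Internally nothing is
rounded; presentation rounds half away from zero to one decimal, because
round-half-even would mis-reproduce printed clinical tables.

## Specificity centiles

The specificity-p centile is the p-quantile (type 7, linear interpolation)
of the predictor among outcome negatives. Negatives-only is the right pool
because the column is *specificity*: the achieved specificity of a
≥-threshold at the centile depends only on negatives. When heavy ties leave
the achieved specificity more than one order statistic short of the target,
the estimate moves to the next distinct negative value — ties resolve
toward higher specificity, the conservative direction for a rule-in
threshold. The confidence interval is distribution-free, from binomial
bounds on the order statistics bracketing the quantile; a quantile of a
skewed score distribution has no reliable normal-theory interval at the
98–99% levels of interest. Interpolation-rule choices shift centiles by
less than one data spacing; exact reproduction of any published centile
table is therefore not claimed and requires the original data.

## The synthetic cohort generator

No patient-level data are deposited for this kind of study, so the
generator is a first-class module: it emulates the statistical structure
the analysis assumes, making every pipeline stage testable.

Each patient carries one latent severity z ~ N(0, 1). Per 15-minute
interval, pulse = 112.5 + 6z + ε and SBP = 96 − 12z + ε with ε ~ N(0, 7²)
(units: BPM, mmHg); DBP couples to SBP through a patient-level pulse
pressure 33 − 2z + N(0, 7²) mmHg, so pulse pressure is nearly independent
of severity — reproducing the empirical pattern that its AUC sits at or
below 0.5. The means and loadings were chosen once so that the
*worst-point* marginals match the study population's: median SI 1.3
(IQR ≈ 1.1–1.5), pulse 117 (110–122), SBP 90 (80–100), DBP near 59 — the
worst-point selection over four intervals shifts pulse up and SBP down
relative to the per-interval means by about 4–6 units, which the means
anticipate. Outcomes are drawn by thresholding a *single* uniform per
patient against three nested logistic probabilities plogis(aₖ + bz) with a
common slope, which guarantees death ⇒ SMO ⇒ SMO-CI by construction.
Eligibility is enforced by resampling the vital-sign noise of
entry-ineligible draws; blood loss is lognormal (median 1000 mL) truncated
above the context threshold. DBP is set missing per patient at rate 0.10,
and tiny pulse/SBP missingness rates reproduce the per-predictor N pattern
of real-shaped data. Vitals are rounded to integers, which produces the
tied SI values real instruments produce.

Calibration (`calibrate_cohort_params()`) chooses the outcome slope b and
intercepts aₖ so that the marginal prevalences hit 4.1/6.6/15.7% in
expectation (one-dimensional quadrature in z) and the *expected worst-point
SI AUC for death* equals 0.87. The AUC calibration uses the closed-form
binormal oracle Φ(effect/√(sd₁² + sd₀²)) as its reference — inverting it
gives the latent-scale effect √2·Φ⁻¹(0.87) — combined with a quadrature
approximation of the generator: log SI is linear in z with loading
β_p/μ_p + β_s/μ_s, and worst-point selection over k intervals leaves a
residual with the standard deviation of the maximum of k normals. The
slope solves a root-finding problem on that approximation; no simulation
is involved, so calibration is deterministic and fast.

What the generator does **not** emulate: treatment effects between entry
and outcome (fluids, uterotonics, surgery), referral delays, context
differences beyond the EBL bar, correlated multi-factor severity (one
latent factor drives all vitals and outcomes), non-random missingness
(real non-palpable vitals mark the sickest patients; generated missingness
is random), and serial correlation structure beyond iid within-patient
noise. Passing tests therefore show the *machinery* is correct and the
pipeline reproduces known operating characteristics under a plausible
data-generating process — not that any particular threshold generalises to
a real population.

## Numerical choices and test scales

* AUC/U-statistic equivalences are asserted to 1e−12 on instances of
  n ≤ 30 with heavy ties.
* The paired test's size is checked at n = 200 over 2,000 null replicates
  (correlated, equally discriminating scores), accepting [0.03, 0.07].
* Wald-AUC and order-statistic quantile intervals are checked for 92–98%
  empirical coverage at 1,000 replicates (n = 200 with 60 positives;
  n = 900 negatives at the 95% level, matching the study's negative-pool
  size).
* Generator calibration is checked two ways at the study size n = 958:
  the across-seed mean SI–death AUC must sit within ±0.01 of the 0.87
  target, and a per-seed band of ±0.04 is tallied over seeds 1–100. The
  second is a strict band: with ~39 deaths the sampling SD of an empirical
  AUC near 0.87 is ≈ 0.02–0.03, so individual seeds routinely fall
  outside ±0.04 even under perfect calibration, and that check documents
  the sampling spread rather than a defect of the generator.
* Simulation sizes in the suite (300–958 patients, 10–100 seeds) were
  chosen to keep Monte-Carlo error well inside each asserted band while
  the full suite runs in well under a minute of compute.

## Limitations

The package implements a secondary-analysis pipeline, not a clinical
decision rule: threshold choices trade sensitivity against specificity in
ways that depend on setting, referral pathways and resource constraints.
The exclusion of non-palpable-vitals records makes analyses conservative
(the sickest patients are removed). Single worst-point measures discard the
trajectory information that repeated-measures methods would use. And the
DeLong machinery assumes independent subjects — clustered designs (e.g.
facility-level entry) would need variance corrections that are out of scope
here.
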