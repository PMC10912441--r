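---
title: "Pseudo-observation relative risks for time-updated parental disease exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-observation relative risks for time-updated parental disease exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

`regpseudo` implements an inference pipeline for a question that arises in
register-based child-welfare epidemiology: does a parent's physical illness,
classified into clinically defined disease categories and updated month by
month, predict the first documented incident of physical child abuse?  The
real analyses of this kind run on national administrative registers that
cannot be redistributed, so the package pairs the estimation machinery with
a synthetic multi-register generator whose ground truth is known, making
every stage testable end to end.

The pipeline has four stages:

1. **Exposure classification** (`load_taxonomy()`,
   `build_exposure_timeline()`): dated ICD-10 diagnoses and ATC
   prescription redemptions are matched by longest code prefix to disease
   categories, each with a look-back window (*ever*, or the last 1/2/3/5
   years) and, for drug-defined categories, a minimum number of
   redemptions in the trailing 365 days (two by default; four for the
   analgesic-defined painful-condition category).  A family is exposed in
   a month if any linked parent qualifies at that month's first day.
2. **Incidence-density matched sampling** (`find_exposed()`,
   `draw_matched_controls()`): each newly exposed child (index date = the
   later of exposure onset and birth) is matched to five children
   unexposed at that same date, on calendar time, reconstituted-family
   level, birth date within a year, family-size level, and mean parental
   age within five years.  Follow-up runs from one month after the index
   date to the first of abuse, death, censoring, the 18th birthday, or 18
   years after the index.
3. **Pseudo-observation regression** (`pseudo_values()`,
   `fit_gee_log()`): the cause-specific cumulative incidence of abuse,
   with non-abuse death as a competing risk, is estimated by the
   Aalen–Johansen estimator; jackknife pseudo-values
   \(\theta_i(\tau) = n\hat F_1(\tau) - (n-1)\hat F_1^{(-i)}(\tau)\)
   become per-child responses in a log-link GEE, so that
   \(\exp(\beta_{\text{exposed}})\) is an adjusted relative risk.
   Standard errors are Eicker–Huber–White, clustered on family.
4. **Multiplicity** (`bonferroni_ci()`): with 33 categories tested, a
   Bonferroni-corrected interval uses the \(1 - 0.05/(2\cdot 33)\) normal
   quantile (3.1718), computed at run time.

## Model assumptions and numerical choices

**Pseudo-values and censoring.**  Pseudo-observation regression assumes
censoring is marginally independent of covariates.  Emigration intensity in
the emulated registers varies by calendar period, so pseudo-values are
generated *within* calendar-time strata and pooled for regression, with the
stratum also entering the model as a covariate (it is listed among the
adjustment variables).  Strata with fewer than two records or no events are
skipped with a warning.

**Evaluation times.**  The default grid is the 0.2/0.4/0.6/0.8/1.0
quantiles of the observed exit times, with one intercept per time and
working independence across a child's time points; `n_tau = 1` gives the
single-time mode at the end of follow-up.  Both modes are tested; the
exposure coefficient is insensitive to the choice in the simulated worlds.

**The jackknife.**  Leave-one-out cumulative incidences are computed
exactly but incrementally: removing subject *i* rescales product-limit
factors only over the event times where *i* was at risk, so each
\(\hat F_1^{(-i)}(\tau)\) decomposes into an unchanged head, a rescaled
middle, and a proportionally shifted tail, evaluated from prefix sums in
\(O((n+m)\log m)\).  Zero factors (a risk set of two with one event) are
tracked by zero-counts so ratios remain exact.  Equality with naive n-fold
recomputation to 1e-10 — and with a `survival::survfit`-based oracle — is
part of the test contract.

**Estimating equations.**  The quasi-score
\(\sum_i x_i \mu_i (y_i - \mu_i)\) with \(\mu = \exp(X\beta)\) is solved by
Fisher scoring with step halving; continuous design columns are
standardised internally (coefficients are mapped back) because register
covariates such as income arrive on scales of hundreds.  Convergence is a
relative coefficient change below 1e-8 within 100 iterations;
non-convergence is *reported*, not raised, mirroring how such models are
published (a dash in the results table).  This estimating equation has a
degenerate root at \(\mu \to 0\); specifications whose cells cannot
support a log-link coefficient are the usual cause of drifting there, so
`run_category()` reduces a model's covariate set before fitting: a
categorical covariate is kept only when every level carries at least five
outcome events.  This mirrors the published practice of reducing models
"to avoid collinearity and small cells" (the original analysis likewise
fitted a reduced specification for its sparsest category).

**Left truncation.**  Entry one month after the index date is handled in
the risk sets, \(n(s) = \#\{i: L_i < s \le T_i\}\); in matched cohorts all
subjects share the same entry time on the time-since-index scale, but the
estimator supports staggered entry generally.

**Window boundaries.**  "Within the last *k* years" is evaluated at month
starts, inclusive of the boundary day (`last_2y` means
`date >= month_start - 730` days); the prescription year is a rolling 365
days ending at the month start.  These conventions are fixed for
reproducibility where the published description is silent between rolling
and calendar readings; rolling matches monthly updating.

## The synthetic registry: what it emulates, and what it does not

`sim_config()` encodes the stated world: a 1997–2018 study window with a
3-year burn-in of parental health data; one or two parents (85% two) and a
family-size distribution of 46/37/16/0.4% for one/two/three-to-five/six or
more children; children mostly born during the study window; a baseline
abuse hazard of 0.002 per child-year and a competing non-abuse death
hazard of 6e-5 per child-year, both derived from the population tables of
the emulated study; covariate marginals (income and neighborhood-resource
means and spreads, education, psychiatric disease, inter-parental
violence, substance abuse, parental maltreatment, immigration background,
refugee status, reconstituted family) matching the same tables, with
missing-completely-at-random gaps at the reported rates (13–23%) on
exactly the five fields that carry missingness in register extracts.
Diagnosis streams are homogeneous Poisson per parent; their default
intensities were chosen once so the family-level exposed fractions
reproduce the coarse published shape — a few percent for most named
categories, two broad residual streams (unspecific symptoms, other
diagnoses) covering most of the population across a childhood.  Emigration
hazards per calendar group (0.005/0.010/0.020 per child-year) are not
published anywhere and were fixed a priori as plausible intensities whose
ratios the generator tests recover.

Deliberate simplifications: event streams are homogeneous within parent
(no disease progression or comorbidity correlation unless the latent
adversity loading is switched on); income is Gaussian rather than
right-skewed; parents neither die nor divorce by default (guardianship
changes are supported through link start/end dates but not generated);
the outcome is a single abstract first-incidence indicator rather than a
merge of hospital and police codes.  A green pipeline test therefore
establishes that the *machinery* recovers known effects under the stated
world, not that the world reproduces any particular published estimate.

Two validation designs are provided.  `simulate_cohort()` emulates the
post-matching world directly (matched sets sharing calendar strata,
family clusters, competing exponential hazards) and is used for parameter
recovery — 200 cohorts of 2,000 exposed children at a true RR of 1.5
recover the truth within Monte-Carlo error with 95% CI coverage near
nominal — and for null calibration across 33 categories, where the
family-wise rejection rate under Bonferroni correction stays below 0.08.
The full registry route (`simulate_registry()` + `run_category()`) is
validated separately for effect direction and audit properties; note that
its estimand is attenuated relative to the generative hazard ratio for
windowed categories, because exposure is classified at the index date
while the generative hazard follows the time-varying state (controls may
also become exposed later — they are kept, matching the
unexposed-at-index design).

## Design choices where the published description was open

* **Index date at month resolution.**  Exposure is defined monthly, so the
  index date is the first day of the first qualifying month (or the birth
  date, if later), not the raw diagnosis date.
* **Calendar matching window** is symmetric (±3 months).  Controls inherit
  the exposed child's index date, the standard risk-set-sampling reading,
  which satisfies the window by construction; the audit still checks it.
* **Controls born after the index date** are ineligible (not yet at risk),
  over and above the ±1-year birth matching.
* **Exposed children with fewer than five eligible controls are dropped**
  rather than matched to fewer (consistent with the published cohort
  bookkeeping); configurable via `ratio`.
* **A matched child whose terminal event precedes follow-up entry** (index
  + 1 month) is dropped individually; the set survives.
* **Controls that become exposed after the index date** remain, uncensored
  (unexposed-at-index design).
* **Drug-only categories qualify without a concurrent diagnosis** (the
  painful-condition category is analgesic-defined by construction).
* **τ grid**: quantile-based multi-time default with per-time intercepts;
  single-time mode available.  Link is log (relative risks); the working
  variance is identity.

## Known limitations

* The shipped taxonomy is a representative fixture (3–10 ICD prefixes per
  category plus the complete ATC lists); the full many-thousand-code
  classification can replace it without code changes, and classification
  results will differ accordingly.
* Relative risks from the registry route are attenuated for short-window
  categories, as discussed above — a property of the design, not a bug.
* The robust Wald tests run slightly hot at moderate cluster counts
  (per-test type-I error near 0.06 at 500 exposed per cohort in the null
  calibration); no small-sample correction (e.g. KC-type) is applied, as
  none was applied in the emulated analysis.
* No population finite-sampling correction and no mutual adjustment among
  disease categories, by design.
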