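Package: regpseudo
Title: Pseudo-Observation Relative Risks for Time-Updated Parental
    Disease Exposure in Simulated Health Registries
Version: 0.1.0
Authors@R:
    person("Registry", "Methods", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating adjusted relative risks of a rare
    childhood outcome under time-updated, rule-based parental disease
    exposure, using registry-style longitudinal data.  Provides a
    synthetic multi-register simulator with known ground truth,
    ICD-10/ATC longest-prefix classification of diagnosis and
    prescription streams into monthly family-level exposure states,
    incidence-density (risk-set) matched cohort sampling with a 1:5
    ratio, Aalen-Johansen cumulative incidence under a competing risk
    of death, jackknife pseudo-observations generated within
    calendar-time strata, log-link generalized estimating equations
    with family-clustered Eicker-Huber-White covariance, and
    Bonferroni-corrected confidence intervals for multiplicity over
    disease categories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
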