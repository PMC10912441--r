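## Configuration of the synthetic multi-register world.  Defaults encode the
## source population the generator emulates: a ~22-year national study window
## (1997-2018) with a 3-year burn-in of parental health data, monthly exposure
## updating, a rare first-incidence outcome (~2 events per 1000 child-years),
## a much rarer competing death, and emigration censoring whose intensity
## differs across three calendar-time groups.

#' Simulation configuration for the synthetic registry generator
#'
#' @param n_families number of families to simulate.
#' @param study_start,study_end study window (coerced to `Date`).
#' @param burn_in_years years of pre-study health data read in so that
#'   prevalent disease is classified correctly at study entry (default 3).
#' @param category_diagnosis_rates named numeric vector of diagnosis
#'   intensities (events per parent-year).  Names must be disease categories
#'   of `taxonomy`, or the reserved streams `UNSPECIFIC`, `OTHER`,
#'   `EXCLUDED`, `PSYCH`.  Unnamed categories default to 0.
#' @param prescription_rates named numeric vector of prescription intensities
#'   (redemptions per parent-year) keyed by ATC pattern of the taxonomy.
#' @param true_log_rr named numeric vector: ground-truth log relative risk of
#'   abuse while the family is exposed in a category; unnamed categories
#'   default to 0.
#' @param baseline_abuse_hazard abuse hazard for an unexposed child, per
#'   child-year.
#' @param death_hazard competing (non-abuse) death hazard per child-year.
#' @param censoring_hazards_by_period length-3 numeric: emigration hazard per
#'   child-year in each calendar-time group, in order.
#' @param calendar_breaks length-2 `Date` vector splitting the study window
#'   into the three calendar-time groups.
#' @param covariate_distributions list of marginal-law parameters, see
#'   [default_covariate_distributions()].
#' @param confounding list with `diag` and `abuse`: log-scale loadings of a
#'   latent per-family adversity score on diagnosis rates and on the abuse
#'   hazard (defaults 0 = no confounding, so recovered effects are unbiased
#'   for `true_log_rr`).
#' @param family_frailty_sd standard deviation of a log-normal family frailty
#'   on the abuse hazard (default 0; used to exercise clustered inference).
#' @param taxonomy taxonomy the generated codes are drawn from.
#' @param seed integer RNG seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_families = 500,
                       study_start = "1997-01-01",
                       study_end = "2018-12-31",
                       burn_in_years = 3L,
                       category_diagnosis_rates = NULL,
                       prescription_rates = NULL,
                       true_log_rr = NULL,
                       baseline_abuse_hazard = 0.002,
                       death_hazard = 6e-5,
                       censoring_hazards_by_period = c(0.005, 0.010, 0.020),
                       calendar_breaks = c("2003-01-01", "2010-01-01"),
                       covariate_distributions = default_covariate_distributions(),
                       confounding = list(diag = 0, abuse = 0),
                       family_frailty_sd = 0,
                       taxonomy = default_taxonomy(),
                       seed = 1L) {
  n_families <- as.integer(n_families)
  if (is.na(n_families) || n_families < 0)
    stopf("n_families must be a non-negative integer")
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  if (!(study_end > study_start)) stopf("study_end must be after study_start")
  burn_in_years <- as.integer(burn_in_years)

  cats <- taxonomy$categories$category
  rate_keys <- c(setdiff(cats, c(UNSPECIFIC_2Y, UNSPECIFIC_EVER, OTHER_CATEGORY)),
                 "UNSPECIFIC", "OTHER", "EXCLUDED", "PSYCH")
  dr <- default_diagnosis_rates(rate_keys)
  if (!is.null(category_diagnosis_rates)) {
    unknown <- setdiff(names(category_diagnosis_rates), rate_keys)
    if (length(unknown))
      stopf("unknown category key(s) in diagnosis rates: %s",
            paste(unknown, collapse = ", "))
    dr[names(category_diagnosis_rates)] <- category_diagnosis_rates
  }
  atc_pat <- taxonomy$patterns$pattern[taxonomy$patterns$kind == "atc"]
  pr <- default_prescription_rates(atc_pat)
  if (!is.null(prescription_rates)) {
    unknown <- setdiff(names(prescription_rates), atc_pat)
    if (length(unknown))
      stopf("unknown ATC key(s) in prescription rates: %s",
            paste(unknown, collapse = ", "))
    pr[names(prescription_rates)] <- prescription_rates
  }
  beta <- setNames(numeric(length(cats)), cats)
  if (!is.null(true_log_rr)) {
    unknown <- setdiff(names(true_log_rr), cats)
    if (length(unknown))
      stopf("unknown category key(s) in true_log_rr: %s",
            paste(unknown, collapse = ", "))
    beta[names(true_log_rr)] <- true_log_rr
  }
  if (any(!is.finite(beta))) stopf("true_log_rr must be finite")
  if (any(dr < 0) || any(pr < 0) || baseline_abuse_hazard < 0 ||
      death_hazard < 0 || any(censoring_hazards_by_period < 0))
    stopf("all rates must be non-negative")
  if (length(censoring_hazards_by_period) != 3)
    stopf("censoring_hazards_by_period must have length 3")
  calendar_breaks <- as.Date(calendar_breaks)
  if (length(calendar_breaks) != 2 || any(calendar_breaks <= study_start) ||
      any(calendar_breaks >= study_end))
    stopf("calendar_breaks must be two dates inside the study window")

  structure(list(
    n_families = n_families, study_start = study_start, study_end = study_end,
    burn_in_years = burn_in_years,
    category_diagnosis_rates = dr, prescription_rates = pr,
    true_log_rr = beta,
    baseline_abuse_hazard = baseline_abuse_hazard,
    death_hazard = death_hazard,
    censoring_hazards_by_period = censoring_hazards_by_period,
    calendar_breaks = calendar_breaks,
    covariate_distributions = covariate_distributions,
    confounding = confounding, family_frailty_sd = family_frailty_sd,
    taxonomy = taxonomy, seed = as.integer(seed)), class = "sim_config")
}

## per-parent-year diagnosis intensities, chosen so that the family-level
## exposed fractions roughly reproduce the coarse shape of a national
## registry: a few percent ever-exposed for most named categories, with the
## two broad residual streams (unspecific symptoms, other diagnoses)
## covering most of the population over a childhood
default_diagnosis_rates <- function(keys) {
  r <- setNames(rep(0.0015, length(keys)), keys)
  r[intersect(c("UNSPECIFIC", "OTHER"), keys)] <- c(0.05, 0.04)
  r[intersect(c("EXCLUDED", "PSYCH"), keys)] <- c(0.10, 0.02)
  r
}

default_prescription_rates <- function(atc_patterns) {
  r <- setNames(rep(0.02, length(atc_patterns)), atc_patterns)
  # analgesics are redeemed far more often than speciality drugs
  r[intersect(c("N02BE", "M01A", "M02A", "N02BA51"), atc_patterns)] <- 0.3
  r
}

#' Default marginal covariate laws
#'
#' Means, dispersions, level probabilities and missingness rates of the
#' family-level covariate set.  Missingness is missing-completely-at-random
#' and only on the five fields that carry it in real register extracts
#' (neighborhood resources, reconstituted family, education, income,
#' immigration background).
#'
#' @return a named list of parameters consumed by [generate_population()].
#' @export
default_covariate_distributions <- function() {
  list(
    income_mean = 123, income_sd = 80, income_miss = 0.13,
    neighborhood_mean = 107, neighborhood_sd = 38, neighborhood_miss = 0.20,
    education_tertiary_p = 0.39, education_miss = 0.11,
    psychiatric_p = 0.036, violence_p = 0.0003, substance_p = 0.008,
    maltreatment_p = 0.063,
    immigration_p = 0.25, immigration_miss = 0.12,
    refugee_p = 0.03,
    reconstituted_p = c(0.944, 0.036, 0.020), reconstituted_miss = 0.23,
    parent_age_mean = 34.4, parent_age_sd = 6.6,
    two_parent_p = 0.85,
    n_children_p = c(0.46, 0.37, 0.12, 0.035, 0.012, 0.003),
    child_born_in_study_p = 0.75, child_prestudy_years = 10)
}

#' Ground-truth relative risks of a simulation configuration
#'
#' @param config a [sim_config()].
#' @return a data.frame with columns `category`, `log_rr`, `rr`.
#' @export
true_params <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  data.frame(category = names(config$true_log_rr),
             log_rr = unname(config$true_log_rr),
             rr = exp(unname(config$true_log_rr)),
             row.names = NULL)
}

#' Read / write a simulation configuration as YAML
#'
#' Only scalar and vector fields are serialised; the taxonomy travels as its
#' source file path.
#'
#' @param config a [sim_config()]; `path` a file path.
#' @return `read_sim_config()` returns a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- config
  x$study_start <- format(x$study_start); x$study_end <- format(x$study_end)
  x$calendar_breaks <- format(x$calendar_breaks)
  ## yaml drops names of atomic vectors; persist the keyed rates as maps
  x$category_diagnosis_rates <- as.list(x$category_diagnosis_rates)
  x$prescription_rates <- as.list(x$prescription_rates)
  x$true_log_rr <- as.list(x$true_log_rr)
  x$taxonomy <- if (is.na(x$taxonomy$source)) NULL else x$taxonomy$source
  class(x) <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  tax <- if (is.null(x$taxonomy)) default_taxonomy() else load_taxonomy(x$taxonomy)
  sim_config(
    n_families = x$n_families, study_start = x$study_start,
    study_end = x$study_end, burn_in_years = x$burn_in_years,
    category_diagnosis_rates = unlist(x$category_diagnosis_rates),
    prescription_rates = unlist(x$prescription_rates),
    true_log_rr = unlist(x$true_log_rr),
    baseline_abuse_hazard = x$baseline_abuse_hazard,
    death_hazard = x$death_hazard,
    censoring_hazards_by_period = unlist(x$censoring_hazards_by_period),
    calendar_breaks = unlist(x$calendar_breaks),
    covariate_distributions = x$covariate_distributions,
    confounding = x$confounding, family_frailty_sd = x$family_frailty_sd,
    taxonomy = tax, seed = x$seed)
}
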