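## Synthetic source population: families, parent-child links, and yearly
## family covariate records.  Covariates are step functions of time, renewed
## each calendar year (the `month` column of a record is the month index of
## that January; values persist until the next record).

#' Generate the synthetic source population
#'
#' Families receive one or two parents and one or more children; children are
#' mostly born during the study window (median age at entry near zero), the
#' rest up to `child_prestudy_years` before it.  Family covariates are drawn
#' per calendar year from the marginal laws in
#' `config$covariate_distributions`, with missing-completely-at-random gaps
#' on the five fields that carry missingness in register extracts.
#'
#' @param config a [sim_config()].
#' @return an object of class `registry_snapshot`: list with data.tables
#'   `persons` (person_id, family_id, role, sex, birth_date), `links`
#'   (family_id, parent_id, child_id, link_start, link_end), `families`
#'   (family_id, n_children_cat, adversity, frailty), `covariates` (one row
#'   per family x calendar year), and the `config`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  cd <- config$covariate_distributions
  nf <- config$n_families
  empty <- function() data.table::data.table()
  if (nf == 0L) {
    snap <- list(persons = empty(), links = empty(), families = empty(),
                 covariates = empty(), config = config)
    class(snap) <- "registry_snapshot"
    return(snap)
  }

  family_id <- sprintf("F%05d", seq_len(nf))
  n_parents <- 1L + rbinom(nf, 1L, cd$two_parent_p)
  n_children <- sample.int(length(cd$n_children_p), nf, replace = TRUE,
                           prob = cd$n_children_p)
  adversity <- rnorm(nf)
  frailty <- if (config$family_frailty_sd > 0)
    rnorm(nf, sd = config$family_frailty_sd) else numeric(nf)

  ## parents: age at study start from the marginal law
  pfam <- rep.int(seq_len(nf), n_parents)
  npar <- length(pfam)
  parent_age <- pmax(18, rnorm(npar, cd$parent_age_mean, cd$parent_age_sd))
  parent_birth <- config$study_start - round(parent_age * 365.25)
  parents <- data.table::data.table(
    person_id = sprintf("P%06d", seq_len(npar)),
    family_id = family_id[pfam], role = "parent",
    sex = ifelse(stats::ave(pfam, pfam, FUN = seq_along) == 1L, "F", "M"),
    birth_date = parent_birth)

  ## children: birth dates mostly inside the study window
  cfam <- rep.int(seq_len(nf), n_children)
  nch <- length(cfam)
  in_study <- runif(nch) < cd$child_born_in_study_p
  span <- as.numeric(config$study_end - config$study_start)
  pre <- cd$child_prestudy_years * 365.25
  birth <- config$study_start + ifelse(
    in_study, round(runif(nch) * span), -round(runif(nch) * pre))
  children <- data.table::data.table(
    person_id = sprintf("C%06d", seq_len(nch)),
    family_id = family_id[cfam], role = "child",
    sex = sample(c("F", "M"), nch, replace = TRUE),
    birth_date = as.Date(birth, origin = "1970-01-01"))

  persons <- rbind(parents, children)
  links <- merge(parents[, c("family_id", "person_id")],
                 children[, c("family_id", "person_id")],
                 by = "family_id", allow.cartesian = TRUE,
                 suffixes = c("_parent", "_child"))
  data.table::setnames(links, c("person_id_parent", "person_id_child"),
                       c("parent_id", "child_id"))
  links$link_start <- as.Date(NA)  # open-ended guardianship by default
  links$link_end <- as.Date(NA)

  n_children_cat <- cut(n_children, c(0, 1, 2, 5, Inf),
                        labels = c("1", "2", "3-5", "6+"))
  families <- data.table::data.table(
    family_id = family_id, n_children = n_children,
    n_children_cat = as.character(n_children_cat),
    adversity = adversity, frailty = frailty)

  covariates <- generate_covariates(config, families, parents)

  snap <- list(persons = persons, links = links, families = families,
               covariates = covariates, config = config)
  class(snap) <- "registry_snapshot"
  snap
}

## one record per family x calendar year; binary adversity-linked covariates
## are drawn once per family, yearly fields (income, reconstituted family)
## are redrawn each year
generate_covariates <- function(config, families, parents) {
  cd <- config$covariate_distributions
  nf <- nrow(families)
  years <- seq(as.integer(format(config$study_start, "%Y")),
               as.integer(format(config$study_end, "%Y")))
  ny <- length(years)

  adv <- families$adversity
  base_income <- rnorm(nf, cd$income_mean, cd$income_sd) - 15 * adv
  neighborhood <- rnorm(nf, cd$neighborhood_mean, cd$neighborhood_sd)
  education <- ifelse(runif(nf) < cd$education_tertiary_p,
                      "tertiary", "primary_secondary")
  psychiatric <- as.integer(runif(nf) < plogis(qlogis(cd$psychiatric_p) + 0.3 * adv))
  violence <- as.integer(runif(nf) < cd$violence_p)
  substance <- as.integer(runif(nf) < plogis(qlogis(cd$substance_p) + 0.3 * adv))
  maltreat <- as.integer(runif(nf) < plogis(qlogis(cd$maltreatment_p) + 0.3 * adv))
  immigration <- ifelse(runif(nf) < cd$immigration_p, "immigrant", "native")
  refugee <- as.integer(runif(nf) < cd$refugee_p)

  mean_par_age0 <- stats::aggregate(
    years_between(parents$birth_date, config$study_start),
    by = list(family_id = parents$family_id), FUN = mean)

  fam_idx <- rep(seq_len(nf), each = ny)
  year <- rep(years, times = nf)
  recon_lv <- c("biological", "unrelated_adult", "adopted_foster")
  out <- data.table::data.table(
    family_id = families$family_id[fam_idx],
    year = year,
    month = month_index(as.Date(sprintf("%d-01-01", year)),
                        config$study_start),  # month index of that January
    income = round(base_income[fam_idx] + rnorm(nf * ny, 0, 10), 2),
    neighborhood_resources = round(neighborhood[fam_idx] + rnorm(nf * ny, 0, 3), 2),
    education = education[fam_idx],
    psychiatric_disease = psychiatric[fam_idx],
    interparental_violence = violence[fam_idx],
    substance_abuse = substance[fam_idx],
    parental_maltreatment = maltreat[fam_idx],
    immigration_background = immigration[fam_idx],
    refugee_status = refugee[fam_idx],
    reconstituted_family = sample(recon_lv, nf * ny, replace = TRUE,
                                  prob = cd$reconstituted_p),
    n_children_category = families$n_children_cat[fam_idx])
  ## reconstituted family is sticky: redrawn yearly but mostly unchanged
  keep <- runif(nf * ny) > 0.03
  first_of_fam <- !duplicated(out$family_id)
  keep[first_of_fam] <- FALSE
  rec <- out$reconstituted_family
  for (k in which(keep)) rec[k] <- rec[k - 1L]
  out$reconstituted_family <- rec

  age0 <- mean_par_age0$x[match(out$family_id, mean_par_age0$family_id)]
  out$mean_parental_age <- round(age0 + (out$year - years[1]), 1)
  out$calendar_period <- calendar_period_of(
    as.Date(sprintf("%d-07-01", out$year)), config)

  ## MCAR missingness on the five fields that carry it in register data
  miss <- function(x, rate) { x[runif(length(x)) < rate] <- NA; x }
  out$neighborhood_resources <- miss(out$neighborhood_resources, cd$neighborhood_miss)
  out$reconstituted_family <- miss(out$reconstituted_family, cd$reconstituted_miss)
  out$education <- miss(out$education, cd$education_miss)
  out$income <- miss(out$income, cd$income_miss)
  out$immigration_background <- miss(out$immigration_background, cd$immigration_miss)
  out
}

#' Calendar-time group of a date
#'
#' @param date a `Date` vector; `config` a [sim_config()].
#' @return character vector with levels `"period1"`, `"period2"`, `"period3"`.
#' @export
calendar_period_of <- function(date, config) {
  br <- config$calendar_breaks
  ifelse(as.Date(date) < br[1], "period1",
         ifelse(as.Date(date) < br[2], "period2", "period3"))
}

#' Look up family covariates in force at given dates
#'
#' Covariate records are yearly step functions; the record of the calendar
#' year of `date` applies.
#'
#' @param covariates the `covariates` table of a snapshot.
#' @param family_id,date equal-length vectors.
#' @return a data.table with one row per query, `NA`-filled when the family
#'   has no record for that year.
#' @export
covariates_at <- function(covariates, family_id, date) {
  q <- data.table::data.table(family_id = family_id,
                              year = as.integer(format(as.Date(date), "%Y")))
  covariates[q, on = c("family_id", "year")]
}

#' @export
print.registry_snapshot <- function(x, ...) {
  cat(sprintf(paste0("<registry_snapshot> %d persons, %d families, ",
                     "%d diagnoses, %d prescriptions, %d outcome records\n"),
              nrow(x$persons), nrow(x$families),
              nrow(x$diagnoses %||% data.frame()),
              nrow(x$prescriptions %||% data.frame()),
              nrow(x$outcomes %||% data.frame())))
  invisible(x)
}
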