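## Incidence-density (risk-set) matched cohort construction: per disease
## category, newly exposed children are matched 1:`ratio` to children
## unexposed at the same index date, on calendar time (controls inherit the
## exposed child's index date, so the +/-3-month window holds by
## construction), reconstituted-family level, birth date within a year,
## family-size level, and mean parental age within five years.

## covariates of the two model specifications (the parsimonious set drops
## immigration background and refugee status)
FULL_COVARIATES <- c("income", "neighborhood_resources",
                     "immigration_background", "refugee_status",
                     "calendar_period", "education", "psychiatric_disease",
                     "interparental_violence", "substance_abuse",
                     "parental_maltreatment")
PARSIMONIOUS_COVARIATES <- setdiff(
  FULL_COVARIATES, c("immigration_background", "refugee_status"))
MATCHING_COVARIATES <- c("reconstituted_family", "n_children_category",
                         "mean_parental_age")

## small-cell guard mirroring how published models are "reduced to avoid
## collinearity and small cells": a categorical adjustment covariate is kept
## only if every level carries at least `min_cell` outcome events
covariates_with_support <- function(followup, covariates, min_cell = 5L) {
  ev <- followup$event == "abuse"
  keep <- vapply(covariates, function(v) {
    x <- followup[[v]]
    if (length(unique(x[!is.na(x)])) < 2) return(FALSE)   # constant
    if (is.numeric(x) && length(unique(x)) > 6) return(TRUE)  # continuous
    tab <- tapply(ev, x, sum)
    all(!is.na(tab)) && all(tab >= min_cell)
  }, logical(1))
  covariates[keep]
}

#' Identify newly exposed children and their index dates
#'
#' A child is exposed in a category when at least one parent qualifies; the
#' index date is the later of the start of the family's first qualifying
#' exposure spell (at month resolution) and the child's birth date.  Children
#' whose first documented abuse precedes the index date are excluded, as are
#' children whose follow-up ended (death, emigration, 18th birthday, study
#' end) before the index date.
#'
#' @param timeline an [build_exposure_timeline()] result.
#' @param children data.frame of children: `child_id`, `family_id`,
#'   `birth_date`.
#' @param outcomes the single-terminal-record outcome table.
#' @param category category name.
#' @param config a [sim_config()] (used for the calendar-time grouping).
#' @return data.table of index records: `child_id`, `family_id`, `category`,
#'   `index_date`, `stratum`, `birth_date`.
#' @export
find_exposed <- function(timeline, children, outcomes, category, config) {
  stopifnot(inherits(timeline, "exposure_timeline"))
  if (!category %in% timeline$categories)
    stopf("unknown category: %s", category)
  children <- data.table::as.data.table(children)
  outcomes <- data.table::as.data.table(outcomes)
  empty <- data.table::data.table(
    child_id = character(), family_id = character(), category = character(),
    index_date = as.Date(character()), stratum = character(),
    birth_date = as.Date(character()))
  sel_cat <- timeline$intervals[["category"]] == category
  iv <- timeline$intervals[sel_cat, ]
  if (!nrow(iv) || !nrow(children)) return(empty)

  x <- merge(children, iv, by = "family_id", allow.cartesian = TRUE)
  x$birth_date <- as.Date(x$birth_date)
  m_b <- month_index(x$birth_date, timeline$study_start)
  ## first exposure spell still active at or after the birth month
  x <- x[x$m_end >= m_b, ]
  if (!nrow(x)) return(empty)
  m_b <- month_index(x$birth_date, timeline$study_start)
  spell_start <- month_index_date(x$m_start, timeline$study_start)
  x$index_date <- pmax(x$birth_date, spell_start, timeline$study_start)
  data.table::setorderv(x, c("child_id", "index_date"))
  x <- x[!duplicated(x$child_id), ]

  ## at risk at index: no terminal record and no abuse at or before the index
  term <- outcomes[match(x$child_id, outcomes$child_id), ]
  ok <- !is.na(term$date) & as.Date(term$date) > x$index_date
  abused_before <- !is.na(term$date) & term$type == "abuse" &
    as.Date(term$date) <= x$index_date
  x <- x[ok & !abused_before, ]
  if (!nrow(x)) return(empty)
  x <- x[x$index_date <= timeline$study_end, ]

  out <- data.table::data.table(
    child_id = x$child_id, family_id = x$family_id, category = category,
    index_date = x$index_date,
    stratum = calendar_period_of(x$index_date, config),
    birth_date = x$birth_date)
  data.table::setorderv(out, c("index_date", "child_id"))
  out
}

#' Draw incidence-density matched controls
#'
#' Controls are sampled uniformly without replacement among children who, at
#' the exposed child's index date, are alive, under 18, abuse-free, in the
#' source population, unexposed in the category, have complete matching and
#' model covariates, satisfy all matching windows, and have not already been
#' used in this cohort.  Exposed children with fewer than `ratio` eligible
#' controls are dropped, as are exposed children with incomplete covariates;
#' a child never appears twice within one category's cohort.
#'
#' @param index_records a [find_exposed()] result.
#' @param snapshot the registry snapshot (children, covariates, outcomes).
#' @param timeline the exposure timeline.
#' @param category category name.
#' @param ratio controls per exposed child (default 5).
#' @param seed RNG seed for the control draws.
#' @param age_tol,birth_tol_days,cal_window_days matching windows: mean
#'   parental age within `age_tol` years, birth dates within
#'   `birth_tol_days`, calendar inclusion dates within `cal_window_days`
#'   (satisfied by construction since controls inherit the index date).
#' @return a `matched_cohort` data.table: `set_id`, `child_id`, `family_id`,
#'   `role` (`exposed`/`control`), `category`, `index_date`, `stratum`, with
#'   bookkeeping counts in attributes (`n_dropped_insufficient`,
#'   `n_dropped_incomplete`, `n_dropped_used`).
#' @export
draw_matched_controls <- function(index_records, snapshot, timeline, category,
                                  ratio = 5L, seed = 1L, age_tol = 5,
                                  birth_tol_days = 365L,
                                  cal_window_days = 92L) {
  outcomes <- snapshot$outcomes
  if (is.null(outcomes)) stopf("snapshot has no outcome table")
  set.seed(derive_seed(seed, 11L))
  ratio <- as.integer(ratio)
  empty <- data.table::data.table(
    set_id = integer(), child_id = character(), family_id = character(),
    role = character(), category = character(),
    index_date = as.Date(character()), stratum = character())
  cohort_attrs <- function(x, ins = 0L, inc = 0L, used = 0L) {
    data.table::setattr(x, "category", category)
    data.table::setattr(x, "ratio", ratio)
    data.table::setattr(x, "seed", seed)
    data.table::setattr(x, "n_dropped_insufficient", ins)
    data.table::setattr(x, "n_dropped_incomplete", inc)
    data.table::setattr(x, "n_dropped_used", used)
    data.table::setattr(x, "class", c("matched_cohort", class(x)))
    x
  }
  if (nrow(index_records) == 0) {
    warnf("no exposed children for category '%s'", category)
    return(cohort_attrs(empty))
  }

  children <- snapshot$persons[snapshot$persons$role == "child", ]
  pool <- data.table::data.table(
    child_id = children$person_id, family_id = children$family_id,
    birth = as.numeric(as.Date(children$birth_date)))
  om <- match(pool$child_id, outcomes$child_id)
  pool$term <- as.numeric(as.Date(outcomes$date[om]))
  pool$term[is.na(pool$term)] <- -Inf  # no record = never at risk
  covs <- snapshot$covariates
  need <- unique(c(MATCHING_COVARIATES, FULL_COVARIATES))
  covs_ok <- covs[, c("family_id", "year", need), with = FALSE]
  covs_ok$complete <- complete.cases(covs_ok)

  ## exposed family-months of this category, for the unexposed-at-index check
  sel_cat <- timeline$intervals[["category"]] == category
  ivc <- timeline$intervals[sel_cat, ]
  exp_key <- if (nrow(ivc)) exposure_key(ivc) else character(0)

  used <- new.env(hash = TRUE, parent = emptyenv())
  n_ins <- 0L; n_inc <- 0L; n_used <- 0L
  sets <- vector("list", nrow(index_records))
  set_no <- 0L

  for (r in seq_len(nrow(index_records))) {
    rec <- index_records[r, ]
    if (!is.null(used[[rec$child_id]])) { n_used <- n_used + 1L; next }
    idx_num <- as.numeric(rec$index_date)
    idx_year <- as.integer(format(rec$index_date, "%Y"))
    idx_month <- month_index(rec$index_date, timeline$study_start)

    cv <- covs_ok[covs_ok$year == idx_year, ]
    me <- cv[match(rec$family_id, cv$family_id), ]
    if (is.na(me$complete) || !me$complete) { n_inc <- n_inc + 1L; next }

    cand <- pool[abs(pool$birth - as.numeric(rec$birth_date)) <= birth_tol_days &
                   pool$birth <= idx_num & pool$term > idx_num &
                   pool$child_id != rec$child_id, ]
    if (nrow(cand)) {
      cc <- cv[match(cand$family_id, cv$family_id), ]
      keep <- !is.na(cc$complete) & cc$complete &
        cc$reconstituted_family == me$reconstituted_family &
        cc$n_children_category == me$n_children_category &
        abs(cc$mean_parental_age - me$mean_parental_age) <= age_tol
      keep[is.na(keep)] <- FALSE
      cand <- cand[keep, ]
    }
    if (nrow(cand)) {
      cand <- cand[!paste(cand$family_id, idx_month) %in% exp_key, ]
    }
    if (nrow(cand)) {
      in_use <- vapply(cand$child_id, function(id) !is.null(used[[id]]),
                       logical(1))
      cand <- cand[!in_use, ]
    }
    if (nrow(cand) < ratio) { n_ins <- n_ins + 1L; next }

    pick <- if (nrow(cand) == ratio) seq_len(ratio)
            else sample.int(nrow(cand), ratio)
    ctrl <- cand[pick, ]
    set_no <- set_no + 1L
    sets[[r]] <- data.table::data.table(
      set_id = set_no,
      child_id = c(rec$child_id, ctrl$child_id),
      family_id = c(rec$family_id, ctrl$family_id),
      role = c("exposed", rep("control", ratio)),
      category = category, index_date = rec$index_date,
      stratum = rec$stratum)
    used[[rec$child_id]] <- TRUE
    for (id in ctrl$child_id) used[[id]] <- TRUE
  }
  res <- data.table::rbindlist(sets)
  if (nrow(res) == 0) res <- empty
  cohort_attrs(res, n_ins, n_inc, n_used)
}

#' Cap the number of exposed children in a cohort
#'
#' When a cohort holds more matched sets than `max_n`, a uniform random
#' subsample of whole sets is kept.
#'
#' @param matched_sets a `matched_cohort`.
#' @param max_n maximum number of exposed children (default 100000).
#' @param seed RNG seed for the subsample.
#' @return a `matched_cohort` of at most `max_n` sets.
#' @export
cap_exposed <- function(matched_sets, max_n = 100000L, seed = 1L) {
  ids <- unique(matched_sets$set_id)
  if (length(ids) <= max_n) return(matched_sets)
  set.seed(derive_seed(seed, 12L))
  keep <- sort(sample(ids, max_n))
  out <- matched_sets[matched_sets$set_id %in% keep, ]
  for (a in c("category", "ratio", "seed", "n_dropped_insufficient",
              "n_dropped_incomplete", "n_dropped_used"))
    data.table::setattr(out, a, attr(matched_sets, a))
  data.table::setattr(out, "class", class(matched_sets))
  out
}

#' Build follow-up records for a matched cohort
#'
#' Follow-up enters one month after the index date and ends at the child's
#' terminal record or eighteen years after the index, whichever comes first.
#' Children whose terminal event falls inside the excluded first month are
#' dropped individually (the set survives).  Event types map to `abuse`,
#' `death` (competing risk) or `censored`; times are years since the index
#' date.  Covariates in force at the index date are attached.
#'
#' @param matched_sets a `matched_cohort`.
#' @param snapshot the registry snapshot (for outcomes and covariates).
#' @return a `followup` data.table: identifiers, `exposed` flag, `entry`,
#'   `exit` (years since index), `event`, `stratum` and covariate columns.
#' @export
build_followup <- function(matched_sets, snapshot) {
  outcomes <- snapshot$outcomes
  x <- data.table::as.data.table(matched_sets)
  if (nrow(x) == 0) {
    out <- data.table::data.table(
      set_id = integer(), child_id = character(), family_id = character(),
      exposed = logical(), entry = numeric(), exit = numeric(),
      event = character(), stratum = character(), index_date = as.Date(character()))
    data.table::setattr(out, "class", c("followup", class(out)))
    return(out)
  }
  om <- match(x$child_id, outcomes$child_id)
  if (anyNA(om)) stopf("%d cohort child(ren) lack a terminal outcome record",
                       sum(is.na(om)))
  term_date <- as.Date(outcomes$date[om])
  term_type <- outcomes$type[om]

  entry_date <- add_months(x$index_date, 1L)
  cap18 <- add_months(x$index_date, 216L)  # < 18 years exposure-to-outcome
  exit_date <- pmin(term_date, cap18)
  event <- ifelse(term_date <= cap18 & term_type == "abuse", "abuse",
                  ifelse(term_date <= cap18 & term_type == "death", "death",
                         "censored"))
  keep <- exit_date > entry_date
  x <- x[keep, ]
  if (!nrow(x)) {
    warnf("all cohort members left before follow-up entry")
  }
  out <- data.table::data.table(
    set_id = x$set_id, child_id = x$child_id, family_id = x$family_id,
    exposed = x$role == "exposed",
    entry = years_between(x$index_date, entry_date[keep]),
    exit = years_between(x$index_date, exit_date[keep]),
    event = event[keep], stratum = x$stratum, index_date = x$index_date)
  cv <- covariates_at(snapshot$covariates, x$family_id, x$index_date)
  for (v in unique(c(FULL_COVARIATES, MATCHING_COVARIATES)))
    out[[v]] <- cv[[v]]
  out$calendar_period <- out$stratum  # calendar group at inclusion
  data.table::setattr(out, "category", attr(matched_sets, "category"))
  data.table::setattr(out, "class", c("followup", class(out)))
  out
}
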