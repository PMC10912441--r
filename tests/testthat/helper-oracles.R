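# Independent oracles used by the dual-route checks.  They deliberately do
# not reuse package internals: survival::survfit for the product-limit
# route, plus brute-force re-implementations of the exposure predicate and
# the matching eligibility filter.

# cause-1 cumulative incidence via survival::survfit (left truncation ok)
oracle_cif1 <- function(entry, exit, ev, tau) {
  f <- survival::survfit(survival::Surv(entry, exit,
                                        factor(ev, levels = 0:2)) ~ 1)
  # pstate columns: (s0), abuse, death
  step_at <- function(times, vals, t0) {
    j <- findInterval(t0, times)
    c(0, vals)[j + 1L]
  }
  step_at(f$time, f$pstate[, 2], tau)
}

# naive leave-one-out pseudo-values built on the survfit oracle
oracle_pseudo <- function(entry, exit, ev, tau) {
  n <- length(exit)
  Fhat <- oracle_cif1(entry, exit, ev, tau)
  out <- matrix(0, n, length(tau))
  for (i in seq_len(n))
    out[i, ] <- n * Fhat - (n - 1) * oracle_cif1(entry[-i], exit[-i], ev[-i], tau)
  out
}

# random competing-risks fixture with delayed entry and ties on demand;
# tied times are built by integer arithmetic divided once, so equal times
# are bit-identical (1-ulp jitter would make "tied" times distinct for an
# exact estimator while survfit merges them via aeqSurv)
random_fixture <- function(n, tie_grid = NULL) {
  if (is.null(tie_grid)) {
    entry <- runif(n, 0, 1.5)
    exit <- entry + rexp(n, 0.6)
  } else {
    denom <- length(tie_grid)
    ei <- sample.int(denom, n, replace = TRUE)
    gi <- sample.int(denom, n, replace = TRUE) + 1L
    entry <- tie_grid[1] * ei
    exit <- tie_grid[1] * (ei + gi)
  }
  ev <- sample(0:2, n, replace = TRUE, prob = c(0.35, 0.4, 0.25))
  list(entry = entry, exit = exit, ev = ev)
}

# brute-force exposure predicate: rescan the raw event lists for one family
# and month, mirroring the documented window conventions
oracle_exposed <- function(month_date, window, min_rx, diag_dates, rx_dates,
                           read_in) {
  s <- as.numeric(month_date)
  wd <- c(ever = Inf, last_1y = 365, last_2y = 730, last_3y = 1095,
          last_5y = 1825)[[window]]
  d <- as.numeric(diag_dates)
  d <- d[d >= as.numeric(read_in)]
  diag_ok <- any(d <= s & (!is.finite(wd) | d >= s - wd))
  rx_ok <- FALSE
  if (min_rx > 0 && length(rx_dates)) {
    r <- as.numeric(rx_dates)
    r <- r[r >= as.numeric(read_in)]
    rx_ok <- sum(r <= s & r >= s - 365) >= min_rx
  }
  isTRUE(diag_ok) || isTRUE(rx_ok)
}

# brute-force re-check of every matched set against the five matching
# criteria plus risk-set and uniqueness conditions; returns a character
# vector of violations (empty = audit passed)
audit_matched_cohort <- function(sets, snapshot, timeline, category,
                                 ratio = 5L, age_tol = 5,
                                 birth_tol_days = 365, cal_window_days = 92) {
  bad <- character(0)
  if (nrow(sets) == 0) return(bad)
  persons <- as.data.frame(snapshot$persons)
  outcomes <- as.data.frame(snapshot$outcomes)
  covs <- as.data.frame(snapshot$covariates)
  need <- unique(c(regpseudo:::MATCHING_COVARIATES,
                   regpseudo:::FULL_COVARIATES))
  if (anyDuplicated(sets$child_id))
    bad <- c(bad, "child appears twice in cohort")
  for (sid in unique(sets$set_id)) {
    ss <- sets[sets$set_id == sid, ]
    ex <- ss[ss$role == "exposed", ]
    ct <- ss[ss$role == "control", ]
    if (nrow(ct) != ratio) bad <- c(bad, sprintf("set %d: ratio", sid))
    idx <- as.Date(ex$index_date)
    yr <- as.integer(format(idx, "%Y"))
    cv_of <- function(fid) covs[covs$family_id == fid & covs$year == yr, ]
    cve <- cv_of(ex$family_id)
    if (nrow(cve) != 1 || anyNA(cve[need]))
      bad <- c(bad, sprintf("set %d: exposed covariates incomplete", sid))
    for (j in seq_len(nrow(ct))) {
      cid <- ct$child_id[j]
      p <- persons[persons$person_id == cid, ]
      o <- outcomes[outcomes$child_id == cid, ]
      cvc <- cv_of(ct$family_id[j])
      pex <- persons[persons$person_id == ex$child_id, ]
      # five criteria + risk-set conditions
      if (abs(as.numeric(as.Date(ct$index_date[j]) - idx)) > cal_window_days)
        bad <- c(bad, sprintf("set %d: calendar window", sid))
      if (nrow(cvc) != 1 || anyNA(cvc[need])) {
        bad <- c(bad, sprintf("set %d: control covariates incomplete", sid))
        next
      }
      if (cvc$reconstituted_family != cve$reconstituted_family)
        bad <- c(bad, sprintf("set %d: reconstituted mismatch", sid))
      if (cvc$n_children_category != cve$n_children_category)
        bad <- c(bad, sprintf("set %d: family size mismatch", sid))
      if (abs(cvc$mean_parental_age - cve$mean_parental_age) > age_tol)
        bad <- c(bad, sprintf("set %d: parental age window", sid))
      if (abs(as.numeric(as.Date(p$birth_date) - as.Date(pex$birth_date))) >
            birth_tol_days)
        bad <- c(bad, sprintf("set %d: birth window", sid))
      if (as.Date(p$birth_date) > idx)
        bad <- c(bad, sprintf("set %d: control unborn at index", sid))
      if (nrow(o) != 1 || as.Date(o$date) <= idx)
        bad <- c(bad, sprintf("set %d: control not at risk at index", sid))
      if (exposure_at(timeline, ct$family_id[j], category, idx))
        bad <- c(bad, sprintf("set %d: control exposed at index", sid))
    }
  }
  bad
}

# small hand-built snapshot for sampler unit tests
mini_snapshot <- function(children, outcomes, covariates, config) {
  persons <- data.table::data.table(
    person_id = children$child_id, family_id = children$family_id,
    role = "child", sex = "F", birth_date = as.Date(children$birth_date))
  structure(list(persons = persons, covariates = covariates,
                 outcomes = outcomes, config = config),
            class = "registry_snapshot")
}

# constant-covariate table for a set of families over the study years
mini_covariates <- function(family_ids, years, age = 30) {
  g <- expand.grid(family_id = family_ids, year = years,
                   stringsAsFactors = FALSE)
  data.table::data.table(
    family_id = g$family_id, year = g$year,
    month = 0L, income = 100, neighborhood_resources = 100,
    education = "tertiary", psychiatric_disease = 0L,
    interparental_violence = 0L, substance_abuse = 0L,
    parental_maltreatment = 0L, immigration_background = "native",
    refugee_status = 0L, reconstituted_family = "biological",
    n_children_category = "1", mean_parental_age = age,
    calendar_period = "period1")
}
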