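## Dated event streams: homogeneous-Poisson diagnosis/prescription processes
## per parent, and a per-child competing-risks race (abuse vs death vs
## emigration) with a piecewise-constant, exposure-dependent abuse hazard.

## code pools for the reserved diagnosis streams; none of these match any
## named-category pattern of the shipped taxonomy
UNSPECIFIC_CODES <- c("R10", "R51", "R53", "R42", "R07", "R00")
OTHER_CODES <- c("Q80", "E83", "L40", "N20", "M54", "D11", "G25", "J95",
                 "K80", "H60")
EXCLUDED_CODES <- c("S72", "T14", "A09", "B34", "O80", "Z01", "V01", "W19")
PSYCH_CODES <- c("F32", "F41", "F20", "F60")

read_in_start <- function(config) {
  add_months(config$study_start, -12L * config$burn_in_years)
}

#' Generate parental diagnosis and prescription event streams
#'
#' Each parent emits, per diagnosis stream and per ATC group, a homogeneous
#' Poisson process over the window from `burn_in_years` before study start to
#' study end.  Codes are drawn from the taxonomy patterns of the stream, so
#' the exposure engine can classify them back; the reserved streams
#' (`UNSPECIFIC`, `OTHER`, `EXCLUDED`, `PSYCH`) use fixed pools that match no
#' named category.  When `config$confounding$diag` is non-zero, each family's
#' diagnosis intensities are scaled by `exp(diag * adversity)`.
#'
#' @param snapshot a [generate_population()] result.
#' @param config the same [sim_config()].
#' @return list with data.tables `diagnoses` (person_id, date, code) and
#'   `prescriptions` (person_id, date, atc_code).
#' @export
generate_health_events <- function(snapshot, config) {
  stopifnot(inherits(snapshot, "registry_snapshot"),
            inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 2L))
  tax <- config$taxonomy
  t0 <- read_in_start(config)
  span_days <- as.numeric(config$study_end - t0)
  span_years <- span_days / 365.25

  parents <- snapshot$persons[snapshot$persons$role == "parent", ]
  empty_d <- data.table::data.table(person_id = character(),
                                    date = as.Date(character()),
                                    code = character())
  empty_p <- data.table::data.table(person_id = character(),
                                    date = as.Date(character()),
                                    atc_code = character())
  if (nrow(parents) == 0)
    return(list(diagnoses = empty_d, prescriptions = empty_p))

  adv <- snapshot$families$adversity[
    match(parents$family_id, snapshot$families$family_id)]
  scale <- exp((config$confounding$diag %||% 0) * adv)

  icd_pool <- function(stream) {
    switch(stream,
           UNSPECIFIC = UNSPECIFIC_CODES, OTHER = OTHER_CODES,
           EXCLUDED = EXCLUDED_CODES, PSYCH = PSYCH_CODES,
           tax$patterns$pattern[tax$patterns$kind == "icd" &
                                  tax$patterns$target == stream])
  }

  diag_list <- list(empty_d)
  for (stream in names(config$category_diagnosis_rates)) {
    r <- config$category_diagnosis_rates[[stream]]
    pool <- icd_pool(stream)
    if (r <= 0 || length(pool) == 0) next
    n_i <- rpois(nrow(parents), r * scale * span_years)
    tot <- sum(n_i)
    if (tot == 0) next
    diag_list[[length(diag_list) + 1L]] <- data.table::data.table(
      person_id = rep.int(parents$person_id, n_i),
      date = t0 + floor(runif(tot) * (span_days + 1)),
      code = sample(pool, tot, replace = TRUE))
  }
  diagnoses <- data.table::rbindlist(diag_list)

  rx_list <- list(empty_p)
  for (atc in names(config$prescription_rates)) {
    r <- config$prescription_rates[[atc]]
    if (r <= 0) next
    n_i <- rpois(nrow(parents), r * span_years)
    tot <- sum(n_i)
    if (tot == 0) next
    rx_list[[length(rx_list) + 1L]] <- data.table::data.table(
      person_id = rep.int(parents$person_id, n_i),
      date = t0 + floor(runif(tot) * (span_days + 1)),
      atc_code = atc)
  }
  prescriptions <- data.table::rbindlist(rx_list)
  data.table::setorderv(diagnoses, c("person_id", "date"))
  data.table::setorderv(prescriptions, c("person_id", "date"))
  list(diagnoses = diagnoses, prescriptions = prescriptions)
}

#' Generate first-event outcome records under competing risks
#'
#' Each child in the study window runs a race between three exponential-type
#' processes with piecewise-constant monthly hazards: abuse (baseline hazard
#' multiplied by `exp(true_log_rr[c])` for every category `c` the family is
#' exposed to that month, and by the family frailty), non-abuse death, and
#' emigration (hazard switched by the calendar-time group of the month).
#' Whichever fires first before `min(18th birthday, study end)` becomes the
#' child's single terminal record; otherwise the record is the boundary
#' itself (`age18` or `study_end`).  Children born after study end get no
#' record.
#'
#' @param snapshot a populated [generate_population()] snapshot.
#' @param exposure_timeline an [build_exposure_timeline()] result (typically
#'   built from the generated event streams, giving confounding-free ground
#'   truth when `confounding` is zero).
#' @param config the [sim_config()].
#' @return data.table with columns `child_id`, `family_id`, `date`, `type`
#'   (`abuse`, `death`, `emigration`, `age18`, `study_end`): exactly one row
#'   per child alive in the window.
#' @export
generate_outcomes <- function(snapshot, exposure_timeline, config) {
  stopifnot(inherits(snapshot, "registry_snapshot"),
            inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 3L))
  children <- snapshot$persons[snapshot$persons$role == "child", ]
  out_empty <- data.table::data.table(
    child_id = character(), family_id = character(),
    date = as.Date(character()), type = character())
  if (nrow(children) == 0) return(out_empty)

  enter <- pmax(children$birth_date, config$study_start)
  bday18 <- add_months(children$birth_date, 216L)
  end <- pmin(bday18, config$study_end)
  keep <- enter < end
  if (!any(keep)) return(out_empty)
  children <- children[keep, ]
  enter <- enter[keep]; end <- end[keep]; bday18 <- bday18[keep]

  fam <- snapshot$families
  adv <- fam$adversity[match(children$family_id, fam$family_id)]
  frail <- fam$frailty[match(children$family_id, fam$family_id)]
  child_lp0 <- (config$confounding$abuse %||% 0) * adv + frail

  ## child x month grid with interval lengths
  m_from <- month_index(enter, config$study_start)
  m_to <- month_index(end - 1, config$study_start)
  nm <- m_to - m_from + 1L
  ci <- rep.int(seq_len(nrow(children)), nm)
  m <- unlist(lapply(seq_len(nrow(children)),
                     function(i) seq.int(m_from[i], m_to[i])), use.names = FALSE)
  m0 <- month_index_date(m, config$study_start)
  m1 <- month_index_date(m + 1L, config$study_start)
  lo <- pmax(as.numeric(enter[ci]), as.numeric(m0))
  hi <- pmin(as.numeric(end[ci]), as.numeric(m1))
  grid <- data.table::data.table(ci = ci, m = m, t0 = lo,
                                 len = (hi - lo) / 365.25)

  ## abuse hazard: baseline x exp(sum of active category effects)
  lp <- child_lp0[ci]
  beta <- config$true_log_rr[config$true_log_rr != 0]
  if (length(beta) && nrow(exposure_timeline$intervals %||% data.table::data.table())) {
    iv <- exposure_timeline$intervals
    gfam <- children$family_id[ci]
    for (cat in names(beta)) {
      ivc <- iv[iv$category == cat, ]
      if (!nrow(ivc)) next
      ## exposed months per family as a lookup on (family, month)
      key <- exposure_key(ivc)
      hit <- paste(gfam, grid$m) %in% key
      lp[hit] <- lp[hit] + beta[[cat]]
    }
  }
  grid$ha <- config$baseline_abuse_hazard * exp(lp)
  grid$hd <- config$death_hazard
  grid$hc <- config$censoring_hazards_by_period[
    match(calendar_period_of(as.Date(grid$t0, origin = "1970-01-01"), config),
          c("period1", "period2", "period3"))]

  nC <- nrow(children)
  t_abuse <- invert_piecewise(grid, rexp(nC), "ha", nC)
  t_death <- invert_piecewise(grid, rexp(nC), "hd", nC)
  t_cens <- invert_piecewise(grid, rexp(nC), "hc", nC)

  t_end <- as.numeric(end)
  tmat <- cbind(abuse = t_abuse, death = t_death, emigration = t_cens,
                bound = t_end)
  first <- max.col(-tmat, ties.method = "first")
  type <- c("abuse", "death", "emigration", "bound")[first]
  t_star <- tmat[cbind(seq_len(nC), first)]
  type[type == "bound"] <- ifelse(bday18[type == "bound"] <= config$study_end,
                                  "age18", "study_end")
  data.table::data.table(
    child_id = children$person_id, family_id = children$family_id,
    date = as.Date(floor(t_star), origin = "1970-01-01"), type = type)
}

## expanded (family, month) keys of an interval table
exposure_key <- function(iv) {
  nm <- iv$m_end - iv$m_start + 1L
  paste(rep.int(iv$family_id, nm),
        unlist(lapply(seq_len(nrow(iv)),
                      function(i) seq.int(iv$m_start[i], iv$m_end[i])),
               use.names = FALSE))
}

## first passage time of a per-child piecewise-constant cumulative hazard
## past an Exp(1) draw; +Inf when the total hazard is never reached
invert_piecewise <- function(grid, E, col, n_children) {
  h <- grid[[col]]
  ch <- h * grid$len
  cum <- stats::ave(ch, grid$ci, FUN = cumsum)
  Eg <- E[grid$ci]
  hit <- cum >= Eg & h > 0
  idx <- tapply(seq_len(nrow(grid))[hit], grid$ci[hit], min)
  t_out <- rep(Inf, n_children)
  if (length(idx)) {
    i <- as.integer(idx)
    prev <- cum[i] - ch[i]
    frac <- (Eg[i] - prev) / h[i] * 365.25
    t_out[as.integer(names(idx))] <- grid$t0[i] + frac
  }
  t_out
}
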