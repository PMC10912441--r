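## Time-updated exposure engine.  Diagnosis and prescription streams are
## classified by the taxonomy and condensed into monthly family-level
## exposure states, stored compactly as month-index intervals.
##
## Conventions (fixed for reproducibility, documented in the vignette):
##   * exposure state applies from the first day of a calendar month and is
##     evaluated at that month start;
##   * a diagnosis qualifies month m for a "last_k" window iff
##     month_start(m) - k_days <= date <= month_start(m), boundary inclusive;
##     "ever" windows have no lower bound beyond the read-in start;
##   * prescriptions qualify month m iff at least `min_rx` redemptions fall
##     in the rolling 365 days ending at month_start(m).

#' Build the monthly family-level exposure timeline
#'
#' @param taxonomy a [load_taxonomy()] object.
#' @param diagnoses data.frame with `person_id`, `date`, `code` (ICD-10).
#' @param prescriptions data.frame with `person_id`, `date`, `atc_code`.
#' @param links parent-family link table with `family_id`, `parent_id` and
#'   optional `link_start`, `link_end` dates bounding guardianship (exposure
#'   through a parent only counts for months inside the link period).
#' @param study_start,study_end the study window.
#' @param burn_in_years pre-study years of health data read in (default 3);
#'   events before the read-in start are dropped with a warning.
#' @return an object of class `exposure_timeline`: exposed months per family
#'   and category as closed month-index intervals, plus the month grid.
#' @export
build_exposure_timeline <- function(taxonomy, diagnoses, prescriptions, links,
                                    study_start, study_end,
                                    burn_in_years = 3L) {
  stopifnot(inherits(taxonomy, "taxonomy"))
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  n_months <- month_index(study_end, study_start) + 1L
  t_read <- add_months(study_start, -12L * as.integer(burn_in_years))
  links <- data.table::as.data.table(links)

  diagnoses <- data.table::as.data.table(diagnoses)
  prescriptions <- data.table::as.data.table(prescriptions)
  if (nrow(diagnoses)) diagnoses$date <- as.Date(diagnoses$date)
  if (nrow(prescriptions)) prescriptions$date <- as.Date(prescriptions$date)

  early <- c(if (nrow(diagnoses)) sum(diagnoses$date < t_read) else 0,
             if (nrow(prescriptions)) sum(prescriptions$date < t_read) else 0)
  if (sum(early) > 0) {
    warnf("%d event(s) before read-in start %s ignored", sum(early),
          format(t_read))
    if (nrow(diagnoses)) diagnoses <- diagnoses[diagnoses$date >= t_read, ]
    if (nrow(prescriptions))
      prescriptions <- prescriptions[prescriptions$date >= t_read, ]
  }

  diag_target <- if (nrow(diagnoses))
    classify_code(taxonomy, diagnoses$code, "icd") else character(0)
  rx_target <- if (nrow(prescriptions))
    classify_code(taxonomy, prescriptions$atc_code, "atc") else character(0)

  cats <- taxonomy$categories
  iv_list <- list()
  for (k in seq_len(nrow(cats))) {
    cat_name <- cats$category[k]
    w <- cats$window[k]
    wd <- WINDOW_DAYS[[w]]
    diag_stream <- switch(cat_name,
                          `Unspecific symptoms, two years back` = "UNSPECIFIC",
                          `Unspecific symptoms, ever` = "UNSPECIFIC",
                          `Other` = "OTHER",
                          cat_name)
    dsel <- diag_target == diag_stream
    iv <- NULL
    if (any(dsel)) {
      dts <- diagnoses$date[dsel]
      pid <- diagnoses$person_id[dsel]
      ms <- month_start(dts)
      m_from <- month_index(dts, study_start) + as.integer(dts > ms)
      m_to <- if (is.finite(wd))
        month_index(dts + wd, study_start) else rep(n_months - 1L, length(dts))
      ok <- m_from <= m_to & m_to >= 0L & m_from <= n_months - 1L
      if (any(ok))
        iv <- data.table::data.table(
          person_id = pid[ok],
          m_start = pmax(m_from[ok], 0L), m_end = pmin(m_to[ok], n_months - 1L))
    }
    ## prescription qualification: >= min_rx in the trailing 365 days
    k_rx <- cats$min_rx[k]
    if (k_rx > 0 && any(rx_target == cat_name)) {
      rx <- prescriptions[rx_target == cat_name, ]
      s_num <- as.numeric(month_index_date(seq_len(n_months) - 1L, study_start))
      per_parent <- split(as.numeric(rx$date), rx$person_id)
      rx_iv <- lapply(names(per_parent), function(p) {
        d <- sort(per_parent[[p]])
        if (length(d) < k_rx) return(NULL)
        cnt <- findInterval(s_num, d) - findInterval(s_num - 366, d)
        q <- cnt >= k_rx
        if (!any(q)) return(NULL)
        r <- rle(q)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        data.table::data.table(person_id = p,
                               m_start = starts[r$values] - 1L,
                               m_end = ends[r$values] - 1L)
      })
      rx_iv <- data.table::rbindlist(rx_iv)
      iv <- if (is.null(iv)) rx_iv else rbind(iv, rx_iv)
    }
    if (is.null(iv) || nrow(iv) == 0) next
    ## parent -> family, clamped to the guardianship period
    iv <- merge(iv, links, by.x = "person_id", by.y = "parent_id",
                allow.cartesian = TRUE)
    if ("link_start" %in% names(iv)) {
      ls <- iv$link_start; le <- iv$link_end
      m_ls <- ifelse(is.na(ls), 0L, month_index(as.Date(ls), study_start) +
                       as.integer(as.Date(ls) > month_start(as.Date(ls))))
      m_le <- ifelse(is.na(le), n_months - 1L,
                     month_index(as.Date(le), study_start))
      iv$m_start <- pmax(iv$m_start, m_ls)
      iv$m_end <- pmin(iv$m_end, m_le)
      iv <- iv[iv$m_start <= iv$m_end, ]
    }
    if (!nrow(iv)) next
    iv <- unique(iv[, c("family_id", "m_start", "m_end")])
    iv$category <- cat_name
    iv_list[[length(iv_list) + 1L]] <- iv
  }

  intervals <- if (length(iv_list))
    merge_month_intervals(data.table::rbindlist(iv_list, use.names = TRUE))
  else data.table::data.table(family_id = character(), category = character(),
                              m_start = integer(), m_end = integer())

  structure(list(intervals = intervals,
                 families = unique(links$family_id),
                 categories = cats$category,
                 study_start = study_start, study_end = study_end,
                 n_months = n_months),
            class = "exposure_timeline")
}

## merge overlapping/adjacent closed month intervals per family x category
merge_month_intervals <- function(iv) {
  data.table::setorderv(iv, c("family_id", "category", "m_start", "m_end"))
  g <- paste(iv$family_id, iv$category, sep = "\r")
  new_grp <- logical(nrow(iv))
  run_max <- integer(nrow(iv))
  # vectorised pass: running maximum of m_end within group
  first <- !duplicated(g)
  rm <- iv$m_end
  for (i in seq_len(nrow(iv))) {
    if (first[i]) { run_max[i] <- rm[i]; new_grp[i] <- TRUE }
    else {
      new_grp[i] <- iv$m_start[i] > run_max[i - 1L] + 1L
      run_max[i] <- if (new_grp[i]) rm[i] else max(run_max[i - 1L], rm[i])
    }
  }
  run <- cumsum(new_grp)
  out <- data.table::data.table(
    family_id = iv$family_id, category = iv$category,
    m_start = iv$m_start, m_end = iv$m_end, run = run)
  res <- out[, list(family_id = family_id[1L], category = category[1L],
                    m_start = min(m_start), m_end = max(m_end)), by = "run"]
  res$run <- NULL
  res[]
}

#' Query the exposure state of a family at a date
#'
#' Exposure is constant within a calendar month.
#'
#' @param timeline an [build_exposure_timeline()] result.
#' @param family_id,date equal-length (or scalar-recycled) vectors.
#' @param category a single category name.
#' @return logical vector.
#' @export
exposure_at <- function(timeline, family_id, category, date) {
  stopifnot(inherits(timeline, "exposure_timeline"))
  if (!category %in% timeline$categories)
    stopf("unknown category: %s", category)
  if (any(!family_id %in% timeline$families))
    stopf("unknown family id(s): %s",
          paste(head(setdiff(family_id, timeline$families), 3), collapse = ", "))
  m <- month_index(as.Date(date), timeline$study_start)
  sel_cat <- timeline$intervals[["category"]] == category
  iv <- timeline$intervals[sel_cat, ]
  if (!nrow(iv)) return(rep(FALSE, max(length(family_id), length(m))))
  q <- data.table::data.table(family_id = family_id, m = m,
                              i = seq_along(family_id))
  hits <- iv[q, on = c("family_id", "m_start<=m", "m_end>=m"), nomatch = NULL,
             which = FALSE]
  out <- rep(FALSE, nrow(q))
  out[hits$i] <- TRUE
  out
}

#' @export
print.exposure_timeline <- function(x, ...) {
  cat(sprintf("<exposure_timeline> %d families, %d categories, %d months, %d exposure intervals\n",
              length(x$families), length(x$categories), x$n_months,
              nrow(x$intervals)))
  invisible(x)
}

#' Export / import a timeline as long-format TSV
#'
#' Rows are the exposed family x category x month triples (`exposed` always
#' `TRUE`; absent combinations are unexposed).
#'
#' @param timeline an `exposure_timeline`; `path` a file path.
#' @export
export_timeline <- function(timeline, path) {
  iv <- timeline$intervals
  nm <- iv$m_end - iv$m_start + 1L
  long <- data.table::data.table(
    family_id = rep.int(iv$family_id, nm),
    category = rep.int(iv$category, nm),
    month = unlist(lapply(seq_len(nrow(iv)),
                          function(i) seq.int(iv$m_start[i], iv$m_end[i])),
                   use.names = FALSE),
    exposed = TRUE)
  data.table::fwrite(long, path, sep = "\t")
  invisible(path)
}
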