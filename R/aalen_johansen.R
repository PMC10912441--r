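## Nonparametric cumulative incidence under competing risks with delayed
## (left-truncated) entry.  Cause 1 is the event of interest (abuse), cause
## 2 the competing event (death); 0 is censoring.  The risk set at time s is
## {i : entry_i < s <= exit_i}.

## coerce event labels to 0/1/2
event_code <- function(event) {
  if (is.numeric(event)) {
    if (any(!event %in% 0:2)) stopf("numeric event must be 0, 1 or 2")
    return(as.integer(event))
  }
  map <- c(censored = 0L, abuse = 1L, death = 2L)
  x <- map[as.character(event)]
  if (anyNA(x)) stopf("event labels must be censored/abuse/death or 0/1/2")
  unname(x)
}

#' Aalen-Johansen cumulative incidence with a competing risk
#'
#' Estimates the cause-specific cumulative incidence functions
#' `F1(t) = sum_{s<=t} S(s-) d1(s)/n(s)` (and `F2` likewise) together with
#' the all-cause Kaplan-Meier survival `S(t)`, supporting delayed entry.
#' With no competing events `F1 = 1 - S`; with no censoring and no
#' competing events `F1` is the empirical CDF of the event times.  The
#' conservation identity `F1 + F2 + S = 1` holds at every jump time.
#'
#' @param entry,exit numeric entry and exit times, `entry < exit`.
#' @param event event type at exit: 0/1/2 or `censored`/`abuse`/`death`.
#' @return object of class `cif_estimate`: `times` (ordered event times),
#'   `n_risk`, `d1`, `d2`, `surv`, `cif1`, `cif2`, `n`.
#' @export
aalen_johansen <- function(entry, exit, event) {
  ev <- event_code(event)
  entry <- as.numeric(entry); exit <- as.numeric(exit)
  if (length(entry) == 1L) entry <- rep(entry, length(exit))
  if (length(exit) < 1L) stopf("at least one record required")
  if (any(!(entry < exit))) stopf("entry must precede exit")
  g <- aj_grid(entry, exit, ev)
  structure(list(times = g$s, n_risk = g$n, d1 = g$d1, d2 = g$d2,
                 surv = g$A, cif1 = g$C1, cif2 = g$C2, n = length(exit)),
            class = "cif_estimate")
}

## grid quantities shared by the estimator and the jackknife
aj_grid <- function(entry, exit, ev) {
  s <- sort(unique(exit[ev > 0L]))
  m <- length(s)
  if (m == 0L)
    return(list(s = numeric(0), n = integer(0), d1 = integer(0),
                d2 = integer(0), A = numeric(0), C1 = numeric(0),
                C2 = numeric(0)))
  se <- sort(entry); sx <- sort(exit)
  n_at <- findInterval(s, se, left.open = TRUE) -
    findInterval(s, sx, left.open = TRUE)
  d1 <- tab_at(exit[ev == 1L], s)
  d2 <- tab_at(exit[ev == 2L], s)
  d <- d1 + d2
  a <- ifelse(n_at > 0, 1 - d / n_at, 1)
  A <- cumprod(a)
  Aprev <- c(1, A[-m])
  inc1 <- ifelse(n_at > 0, Aprev * d1 / n_at, 0)
  inc2 <- ifelse(n_at > 0, Aprev * d2 / n_at, 0)
  list(s = s, n = n_at, d1 = d1, d2 = d2, a = a, A = A, Aprev = Aprev,
       C1 = cumsum(inc1), C2 = cumsum(inc2))
}

## counts of x at each grid point s (x values are all in s)
tab_at <- function(x, s) {
  if (!length(x)) return(integer(length(s)))
  tabulate(match(x, s), nbins = length(s))
}

#' Evaluate a cumulative incidence or survival curve
#'
#' Right-continuous step-function lookup.
#'
#' @param fit a [aalen_johansen()] result.
#' @param tau evaluation time(s).
#' @param what `"cif1"`, `"cif2"` or `"surv"`.
#' @return numeric vector, one value per `tau`.
#' @export
cif_at <- function(fit, tau, what = c("cif1", "cif2", "surv")) {
  what <- match.arg(what)
  stopifnot(inherits(fit, "cif_estimate"))
  j <- findInterval(tau, fit$times)
  vals <- c(if (what == "surv") 1 else 0, fit[[what]])
  vals[j + 1L]
}

#' @export
print.cif_estimate <- function(x, ...) {
  cat(sprintf("<cif_estimate> n = %d, %d event times, F1(max) = %.4f, F2(max) = %.4f\n",
              x$n, length(x$times),
              if (length(x$cif1)) tail(x$cif1, 1) else 0,
              if (length(x$cif2)) tail(x$cif2, 1) else 0))
  invisible(x)
}
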