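#' @importFrom stats qnorm rbinom rexp rnorm rpois runif setNames aggregate
#'   model.matrix complete.cases plogis qlogis
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' First day of the calendar month containing a date
#'
#' @param x a `Date` vector.
#' @return a `Date` vector of month starts.
#' @keywords internal
month_start <- function(x) {
  x <- as.Date(x)
  as.Date(format(x, "%Y-%m-01"))
}

## months elapsed between the month of `origin` and the month of `x`
month_index <- function(x, origin) {
  x <- as.POSIXlt(as.Date(x))
  o <- as.POSIXlt(month_start(origin))
  12L * (x$year - o$year) + (x$mon - o$mon)
}

## inverse of month_index(): first day of month `idx` (0-based) after origin
month_index_date <- function(idx, origin) {
  o <- as.POSIXlt(month_start(origin))
  y <- o$year + (o$mon + idx) %/% 12L
  m <- (o$mon + idx) %% 12L
  as.Date(sprintf("%04d-%02d-01", y + 1900L, m + 1L))
}

#' Shift dates by whole calendar months
#'
#' Day-of-month is clamped to the length of the target month (e.g. Jan 31 + 1
#' month = Feb 28/29), the convention used for follow-up entry one month after
#' the index date.
#'
#' @param x a `Date` vector.
#' @param k integer number of months (scalar).
#' @return a `Date` vector.
#' @keywords internal
add_months <- function(x, k) {
  lt <- as.POSIXlt(as.Date(x))
  mon <- lt$mon + k
  y <- lt$year + mon %/% 12L
  m <- mon %% 12L
  dmax <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[m + 1L]
  leap <- (m == 1L) & ((y + 1900L) %% 4L == 0L &
                         ((y + 1900L) %% 100L != 0L | (y + 1900L) %% 400L == 0L))
  dmax[leap] <- 29L
  d <- pmin(lt$mday, dmax)
  as.Date(sprintf("%04d-%02d-%02d", y + 1900L, m + 1L, d))
}

## years between two dates, average-year convention
years_between <- function(from, to) {
  as.numeric(as.Date(to) - as.Date(from)) / 365.25
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## draw one sub-seed per purpose from a master seed, keeping results
## insensitive to the order in which downstream stages consume randomness
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset) * 1009) %% 2147483562)
}
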