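# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo = -Inf, hi = Inf) pmin(pmax(x, lo), hi)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Cumulative day-of-month offsets of the 365-day standard calendar
#' @noRd
.std_month_days <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
.std_month_start <- c(0L, cumsum(.std_month_days))[1:12]

#' Standard (non-leap) day of year from month and day of month.
#' Feb 29 maps to NA: it does not exist on the 365-day calendar.
#' @noRd
std_doy <- function(month, mday) {
  doy <- .std_month_start[month] + mday
  doy[month == 2L & mday == 29L] <- NA_integer_
  as.integer(doy)
}

#' Month (1..12) of a standard-calendar day of year.
#' @noRd
std_month_of_doy <- function(doy) {
  findInterval(doy - 1L, cumsum(.std_month_days)) + 1L
}

is_leap_year <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
}

#' AR(1) series with standard-normal innovations scaled to a stationary sd.
#' @noRd
ar1_series <- function(n, phi, sd_stat) {
  innov_sd <- sd_stat * sqrt(1 - phi^2)
  as.numeric(stats::filter(stats::rnorm(n, sd = innov_sd), phi,
                           method = "recursive"))
}

#' Run-length starts/lengths of a logical vector (TRUE runs only).
#' @noRd
true_runs <- function(x) {
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & !is.na(r$values)
  list(start = starts[keep], length = r$lengths[keep])
}
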