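#' Calendar-day percentile thresholds from a base period
#'
#' For each standard-calendar day the empirical q-th percentile of all
#' base-period values falling in the centered `window`-day window (wrapping
#' across the year boundary) is computed with the linear-interpolation
#' estimator (R quantile type 7).  No in-base bootstrap is applied: the
#' thresholds are computed once and used for every year evaluated.
#'
#' @param daily multi-year `daily_record` (or data frame with `year`,
#'   `doy` and the variable column)
#' @param var variable column, typically `"tmin"` or `"tmax"`
#' @param q percentile in percent (10 or 90 for the standard indices)
#' @param window centered window width in days (default 5)
#' @return numeric vector of 365 thresholds
#' @export
percentile_thresholds <- function(daily, var, q, window = 5L) {
  years <- unique(daily$year)
  if (length(years) < 5L)
    warnf("percentile_thresholds: only %d base year(s); thresholds will be noisy",
          length(years))
  half <- (as.integer(window) - 1L) %/% 2L
  m <- matrix(NA_real_, nrow = 365L, ncol = length(years))
  for (j in seq_along(years)) {
    sub <- daily[daily$year == years[j], , drop = FALSE]
    m[sub$doy, j] <- sub[[var]]
  }
  vapply(1:365, function(d) {
    days <- ((d - half - 1L):(d + half - 1L)) %% 365L + 1L
    pool <- as.numeric(m[days, ])
    stats::quantile(pool, q / 100, na.rm = TRUE, names = FALSE, type = 7)
  }, numeric(1))
}

#' Percentile-based temperature exceedance indices
#'
#' TN10p/TX10p: percentage of days with daily minimum/maximum temperature
#' strictly below the calendar-day 10th percentile of the base period;
#' TN90p/TX90p: strictly above the 90th percentile.
#'
#' @param tmin,tmax daily minimum/maximum temperature, 365 values each
#' @param thresholds list with elements `tn10`, `tx10`, `tn90`, `tx90`
#'   (365-day threshold vectors from [percentile_thresholds()])
#' @return named list of the four percentages
#' @export
percent_exceedance_indices <- function(tmin, tmax, thresholds) {
  if (length(tmin) != 365L || length(tmax) != 365L)
    stopf("percent_exceedance_indices: need full 365-day year")
  if (anyNA(tmin) || anyNA(tmax))
    stopf("percent_exceedance_indices: missing days")
  list(TN10p = 100 * sum(tmin < thresholds$tn10) / 365,
       TX10p = 100 * sum(tmax < thresholds$tx10) / 365,
       TN90p = 100 * sum(tmin > thresholds$tn90) / 365,
       TX90p = 100 * sum(tmax > thresholds$tx90) / 365)
}

#' Growing season length
#'
#' Days between the first span of at least 6 days with daily mean
#' temperature above 5 degC and the first span after July 1 of at least
#' 6 days below 5 degC.  Returns 0 without a starting span and runs to
#' December 31 without a terminating span.
#'
#' @param tg daily mean temperature (365 values, mean of the 24 hourly
#'   values)
#' @return growing season length in days
#' @export
gsl <- function(tg) {
  stopifnot(length(tg) == 365L)
  warm <- true_runs(tg > 5)
  wi <- which(warm$length >= 6L)
  if (!length(wi)) return(0L)
  start <- warm$start[wi[1L]]
  cold <- true_runs(tg < 5)
  ci <- which(cold$length >= 6L & cold$start > 182L)  # after July 1 (doy 182)
  end <- if (length(ci)) cold$start[ci[1L]] else 366L
  if (end <= start) return(0L)
  end - start
}

#' Frost days and summer days
#'
#' FD0: annual count of days with minimum temperature strictly below
#' 0 degC; SU25: days with maximum temperature strictly above 25 degC.
#'
#' @param tmin,tmax daily minimum/maximum temperature (365 values)
#' @return list with `FD0` and `SU25`
#' @export
count_indices <- function(tmin, tmax) {
  stopifnot(length(tmin) == 365L, length(tmax) == 365L)
  list(FD0 = sum(tmin < 0), SU25 = sum(tmax > 25))
}

#' Warm spell duration indicator
#'
#' Total number of days belonging to runs of at least 6 consecutive days
#' with maximum temperature strictly above the calendar-day 90th percentile.
#'
#' @param tmax daily maximum temperature (365 values)
#' @param thr90 calendar-day 90th-percentile thresholds (365 values)
#' @return WSDI day count
#' @export
wsdi <- function(tmax, thr90) {
  stopifnot(length(tmax) == 365L, length(thr90) == 365L)
  runs <- true_runs(tmax > thr90)
  sum(runs$length[runs$length >= 6L])
}

#' Full extreme-index set of one year against a base period
#'
#' @param daily_year single-year `daily_record` (365 rows with `tmin`,
#'   `tmax`, `tmean`)
#' @param base_daily multi-year base `daily_record` for the percentile
#'   thresholds
#' @return named list: TN10p, TX10p, TN90p, TX90p (%), GSL, FD0, SU25,
#'   WSDI (days)
#' @export
extreme_indices <- function(daily_year, base_daily) {
  stopifnot(nrow(daily_year) == 365L)
  thr <- list(tn10 = percentile_thresholds(base_daily, "tmin", 10),
              tx10 = percentile_thresholds(base_daily, "tmax", 10),
              tn90 = percentile_thresholds(base_daily, "tmin", 90),
              tx90 = percentile_thresholds(base_daily, "tmax", 90))
  d <- daily_year[order(daily_year$doy), , drop = FALSE]
  out <- percent_exceedance_indices(d$tmin, d$tmax, thr)
  out$GSL <- gsl(d$tmean)
  counts <- count_indices(d$tmin, d$tmax)
  out$FD0 <- counts$FD0
  out$SU25 <- counts$SU25
  out$WSDI <- wsdi(d$tmax, thr$tx90)
  out
}

#' Kernel density estimate of a climate series
#'
#' Gaussian kernel with a fixed bandwidth (default 1.5, in the units of the
#' series), evaluated exactly (no grid binning) on `n` nodes spanning the
#' data range extended by `cut` bandwidths, so the density integrates to 1
#' within 1e-3 even for very small samples.
#'
#' @param x numeric series
#' @param bandwidth kernel bandwidth (sd of the Gaussian kernel)
#' @param n number of grid nodes
#' @param cut grid extension beyond the data range, in bandwidths
#' @return data frame with columns `x` (grid) and `density`
#' @export
pdf_kde <- function(x, bandwidth = 1.5, n = 512L, cut = 4) {
  x <- x[!is.na(x)]
  if (!length(x)) stopf("pdf_kde: empty input")
  grid <- seq(min(x) - cut * bandwidth, max(x) + cut * bandwidth,
              length.out = n)
  dens <- vapply(grid, function(g)
    mean(stats::dnorm(g, mean = x, sd = bandwidth)), numeric(1))
  data.frame(x = grid, density = dens)
}

#' Prescribed-versus-measured deviation statistics
#'
#' The 99th percentile of the absolute deviation, the fraction of pairs
#' within the tolerance, Pearson's correlation coefficient and the pair
#' count.  `NA` pairs (data losses/dropouts) are removed first.
#'
#' @param prescribed,measured paired series of equal length
#' @param tolerance tolerated absolute deviation (> 0)
#' @return a `deviation_stats` list: `p99`, `fraction_within`, `r`, `n`
#' @export
compare_prescribed_measured <- function(prescribed, measured, tolerance) {
  if (length(prescribed) != length(measured))
    stopf("compare_prescribed_measured: length mismatch (%d vs %d)",
          length(prescribed), length(measured))
  stopifnot(tolerance > 0)
  ok <- !is.na(prescribed) & !is.na(measured)
  p <- prescribed[ok]; m <- measured[ok]
  if (length(p) < 2L)
    stopf("compare_prescribed_measured: fewer than 2 complete pairs")
  d <- abs(m - p)
  structure(list(p99 = stats::quantile(d, 0.99, names = FALSE, type = 7),
                 fraction_within = mean(d <= tolerance),
                 r = stats::cor(p, m),
                 n = length(p)),
            class = "deviation_stats")
}

#' @export
print.deviation_stats <- function(x, ...) {
  cat(sprintf("<deviation_stats> n = %d, p99 = %.4g, within tolerance = %.1f%%, r = %.4f\n",
              x$n, x$p99, 100 * x$fraction_within, x$r))
  invisible(x)
}

#' Default tolerated deviations per variable
#'
#' Facility tolerances: 1 degC (ta), 10 % (rh), 10 ppb (O3), 20 ppm (CO2),
#' 50 umol m-2 s-1 (PPFD).
#'
#' @return named numeric vector
#' @export
deviation_tolerances <- function() {
  c(ta = 1, rh = 10, o3 = 10, co2 = 20, ppfd = 50)
}

#' Pairwise Pearson correlation among chambers
#'
#' @param logs named list of equally long measured series (one per chamber)
#' @return correlation matrix
#' @export
chamber_correlation <- function(logs) {
  stopifnot(length(logs) >= 2L)
  stats::cor(do.call(cbind, logs), use = "pairwise.complete.obs")
}
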