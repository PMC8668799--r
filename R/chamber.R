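#' Facility limits of the climate chambers
#'
#' Technical bounds and slew rates of an ecotron-class walk-in chamber:
#' maximum air temperature 30 degC, day/night temperature floors 10/4 degC,
#' day/night humidity caps 75/90 %, humidity floor 30 %, LED minimum 24
#' umol m-2 s-1, PPFD compression of the 600..2030 range onto 600..800,
#' and per-minute slew limits (0.08 degC, 0.3 % rh, 0.3 ppb O3, 0.7 ppm CO2
#' for enrichment only).
#'
#' @param ... named overrides of individual entries
#' @return named list of limits
#' @export
facility_limits <- function(...) {
  lim <- list(t_max = 30, t_min_day = 10, t_min_night = 4,
              rh_max_day = 75, rh_max_night = 90, rh_min = 30,
              ppfd_floor = 24, ppfd_compress_lo = 600,
              ppfd_compress_hi_in = 2030, ppfd_compress_hi_out = 800,
              slew = c(ta = 0.08, rh = 0.3, o3 = 0.3, co2 = 0.7))
  utils::modifyList(lim, list(...))
}

#' Clip temperature and humidity to chamber bounds
#'
#' Day hours (prescribed radiation > 0, i.e. the facility photoperiod)
#' use the day floors/caps, night hours the night ones.  Idempotent.
#'
#' @param try a `try_year` (or any data frame with `ta`, `rh`, `rg`)
#' @param limits a [facility_limits()] list
#' @return data frame with clipped `ta` and `rh` columns
#' @export
apply_facility_limits <- function(try, limits = facility_limits()) {
  day <- try$rg > 0
  out <- try
  out$ta <- clamp(try$ta,
                  ifelse(day, limits$t_min_day, limits$t_min_night),
                  limits$t_max)
  out$rh <- clamp(try$rh, limits$rh_min,
                  ifelse(day, limits$rh_max_day, limits$rh_max_night))
  out
}

#' Default month-specific global-radiation to PPFD conversion factors
#'
#' Empirical quantum-flux factors (umol J-1) ramping from 1.90 in winter to
#' 2.10 in high summer with 2.00 shoulder seasons; fully configurable.
#'
#' @return numeric vector of 12 monthly factors
#' @export
ppfd_factors <- function() {
  c(1.90, 1.90, 2.00, 2.00, 2.00, 2.10, 2.10, 2.10, 2.00, 2.00, 2.00, 1.90)
}

#' Convert global radiation to PPFD
#'
#' `ppfd = rg * factor[month]` with a month-specific empirical factor.
#' Factors outside the plausible 1.90..2.10 range trigger a warning.
#'
#' @param rg global radiation (W m-2)
#' @param month month index 1..12 (recycled against `rg`)
#' @param factors 12 monthly conversion factors
#' @return PPFD (umol m-2 s-1)
#' @export
rg_to_ppfd <- function(rg, month, factors = ppfd_factors()) {
  stopifnot(length(factors) == 12L)
  if (any(factors < 1.90 | factors > 2.10))
    warnf("rg_to_ppfd: factor(s) outside the empirical 1.90..2.10 range")
  rg * factors[month]
}

#' Compress PPFD into the chamber's light range
#'
#' Values between `ppfd_compress_lo` (600) and `ppfd_compress_hi_in` (2030)
#' are mapped linearly onto `ppfd_compress_lo`..`ppfd_compress_hi_out`
#' (600..800); values above the input maximum are clipped to the output
#' maximum with a warning.  Positive values below the LED minimum (24) are
#' raised to it; zeros (lights off) stay zero.  Because the compressed
#' output (600, 800\] lies inside the input band, re-applying the function
#' to already-compressed data compresses again: the mapping is meant to be
#' applied exactly once, and is idempotent only outside the compression
#' band.
#'
#' @param ppfd PPFD values (umol m-2 s-1)
#' @param limits a [facility_limits()] list
#' @return compressed PPFD
#' @export
compress_ppfd <- function(ppfd, limits = facility_limits()) {
  lo <- limits$ppfd_compress_lo
  hi_in <- limits$ppfd_compress_hi_in
  hi_out <- limits$ppfd_compress_hi_out
  out <- ppfd
  over <- ppfd > hi_in
  if (any(over)) {
    warnf("compress_ppfd: %d value(s) above %g clipped to %g",
          sum(over), hi_in, hi_out)
    out[over] <- hi_out
  }
  mid <- ppfd > lo & ppfd <= hi_in
  out[mid] <- lo + (ppfd[mid] - lo) * (hi_out - lo) / (hi_in - lo)
  dim_on <- out > 0 & out < limits$ppfd_floor
  out[dim_on] <- limits$ppfd_floor
  out
}

#' Ozone treatment gradients
#'
#' Per-hour piecewise adjustment of a present-climate ozone series for the
#' experimental gradient: `"unchanged"` (identity), `"preindustrial"`
#' (normalized to an annual mean of exactly 10 ppb), `"moderate"` (< 40 ppb
#' raised by +5, > 45 ppb lowered by -5, 40..45 unchanged) and `"high"`
#' (< 40 ppb +10, 40..<50 +5, >= 50 -5).
#'
#' @param o3 hourly ozone series (ppb)
#' @param treatment one of `"unchanged"`, `"preindustrial"`, `"moderate"`,
#'   `"high"`
#' @return adjusted series
#' @export
o3_treatment <- function(o3, treatment = c("unchanged", "preindustrial",
                                           "moderate", "high")) {
  treatment <- match.arg(treatment)
  switch(treatment,
         unchanged = o3,
         preindustrial = o3 / mean(o3) * 10,
         moderate = ifelse(o3 < 40, o3 + 5, ifelse(o3 > 45, o3 - 5, o3)),
         high = ifelse(o3 < 40, o3 + 10, ifelse(o3 < 50, o3 + 5, o3 - 5)))
}

#' Minute-resolution trajectory between hourly setpoints
#'
#' Each hourly setpoint is approached along the linear path in 60 one-minute
#' steps; where the linear path would require a per-minute change larger
#' than the slew limit, the trajectory is rate-limited (pursuing the current
#' hourly target without overshoot) and may arrive late.  The CO2 cap
#' applies to enrichment (increases) only; decreases follow the linear
#' path.  Light (PPFD) responds within seconds, so its minute values simply
#' hold the hourly setpoint.
#'
#' @param hourly data frame of hourly setpoints with any of the columns
#'   `ta`, `rh`, `o3`, `co2`, `ppfd`
#' @param slew named per-minute slew limits (see [facility_limits()])
#' @return data frame with `minute_of_year` and one column per input
#'   variable, `60 * nrow(hourly)` rows
#' @export
ramp_setpoints <- function(hourly, slew = facility_limits()$slew) {
  n <- nrow(hourly)
  vars <- intersect(c("ta", "rh", "o3", "co2", "ppfd"), names(hourly))
  out <- data.frame(minute_of_year = seq_len(60L * n))
  m_step <- 1:60
  for (v in vars) {
    sp <- hourly[[v]]
    if (v == "ppfd") {
      out[[v]] <- rep(sp, each = 60L)
      next
    }
    cap <- slew[[v]]
    # per-hour closed form: starting from the value reached so far, the
    # capped linear pursuit moves by sign(d) * min(|d|/60, cap) per minute
    # (decreases uncapped for CO2 enrichment-only limiting)
    start <- numeric(n)
    step <- numeric(n)
    cur <- sp[1L]
    for (h in seq_len(n)) {
      d <- sp[h] - cur
      rate <- abs(d) / 60
      capped <- if (v == "co2" && d < 0) rate else min(rate, cap)
      start[h] <- cur
      step[h] <- sign(d) * capped
      cur <- cur + 60 * step[h]
    }
    out[[v]] <- rep(start, each = 60L) + rep(step, each = 60L) * m_step
  }
  out
}

#' Facility-feasible chamber program from a TRY
#'
#' Applies the chamber bounds to temperature and humidity, converts global
#' radiation to PPFD and compresses it into the light range, applies the
#' requested ozone treatment, and (optionally) derives the slew-limited
#' minute trajectory.
#'
#' @param try a `try_year`
#' @param limits a [facility_limits()] list
#' @param treatment ozone treatment, see [o3_treatment()]
#' @param minutes also compute the minute-resolution trajectory
#' @param factors monthly radiation-to-PPFD factors
#' @return a `chamber_program` list with elements `hourly` (data frame of
#'   setpoints), `minute` (`NULL` unless requested), `treatment`, `limits`
#' @export
build_chamber_program <- function(try, limits = facility_limits(),
                                  treatment = "unchanged", minutes = FALSE,
                                  factors = ppfd_factors()) {
  clipped <- apply_facility_limits(try, limits)
  month <- std_month_of_doy(try$doy)
  ppfd <- compress_ppfd(rg_to_ppfd(try$rg, month, factors), limits)
  hourly <- data.frame(hour_of_year = try$hour_of_year,
                       ta = clipped$ta, rh = clipped$rh, ppfd = ppfd,
                       o3 = o3_treatment(try$o3, treatment), co2 = try$co2)
  minute <- if (minutes) ramp_setpoints(hourly, limits$slew) else NULL
  structure(list(hourly = hourly, minute = minute, treatment = treatment,
                 limits = limits, scenario = attr(try, "scenario")),
            class = "chamber_program")
}

#' @export
print.chamber_program <- function(x, ...) {
  cat(sprintf("<chamber_program> scenario %s, O3 treatment '%s', %d hourly setpoints%s\n",
              x$scenario %||% "?", x$treatment, nrow(x$hourly),
              if (is.null(x$minute)) "" else
                sprintf(", %d minute steps", nrow(x$minute))))
  invisible(x)
}
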