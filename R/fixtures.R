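#' Configuration of the synthetic fixture world
#'
#' Defaults emulate the statistical structure of a mid-elevation central
#' European forest climate station: annual mean air temperature 8.3 degC
#' with a 9 degC seasonal and a season-scaled diurnal cycle plus AR(1)
#' weather noise; relative humidity around 78.6 % anti-correlated with the
#' temperature anomaly; global radiation as a latitude-driven clear-sky
#' envelope modulated by smooth cloudiness; ozone positively coupled to
#' radiation and temperature with a ~30 ppb mean; pressure around 956 hPa;
#' a CO2 record centered on 375 ppm with trend, seasonal and diurnal
#' cycles.  The mock ensemble has 9 members on a 3 x 3 grid (one member on
#' a shifted 2 x 2 grid, one delivering specific humidity, one delivering
#' 3-hourly pressure, and one weather-generator member averaged over 10
#' runs) with injected scenario signals whose annual means are +1.1 degC
#' (rcp26) and +3.3 degC (rcp85) for temperature and a summer-peaked
#' humidity decline reaching -2 % (rcp26) and -6 % (rcp85).
#'
#' @param seed integer RNG seed fixing the whole fixture world
#' @param years number of record years
#' @param ... named overrides of any default listed above (see the source
#'   for the full set)
#' @return a `fixture_config` list
#' @export
fixture_config <- function(seed = 1L, years = 30L, ...) {
  doy <- 1:365
  summer <- cos(2 * pi * (doy - 196) / 365)
  cfg <- list(
    seed = as.integer(seed), years = as.integer(years), start_year = 1987L,
    lat = 50.16,
    ta_mean = 8.3, ta_seasonal_amp = 9, ta_diurnal_amp = 4,
    ta_phi = 0.95, ta_sd = 1.5,       # fast hourly weather noise
    ta_syn_phi = 0.85, ta_syn_sd = 2, # daily-scale synoptic anomalies
    ta_year_sd = 0.8,                 # warm/cold-year anomalies
    rh_mean = 78.6, rh_seasonal_amp = 4, rh_diurnal_amp = 8,
    rh_ta_slope = -1.2, rh_phi = 0.95, rh_sd = 5,
    rh_syn_phi = 0.85, rh_syn_sd = 4,
    p_mean = 956, p_phi = 0.995, p_sd = 8,
    rg_clear_max = 1000, cloud_phi = 0.995,
    o3_base = 20, o3_rg_coef = 0.04, o3_ta_coef = 0.5,
    o3_phi = 0.95, o3_sd = 4, o3_syn_phi = 0.8, o3_syn_sd = 4,
    co2_mean = 375, co2_trend = 1.9, co2_seasonal_amp = 5,
    co2_diurnal_amp = 1, co2_phi = 0.9, co2_sd = 1.5,
    # ensemble
    n_members = 9L, grid_dim = 3L, shifted_member = 9L, q_member = 2L,
    subdaily_p_member = 3L, multirun_member = 4L, n_runs = 10L,
    member_spread = 0.5, grid_spread = 0.1, day_sd = 1, day_sd_rh = 2,
    split_year = 2005L, fc_years = c(2071L, 2100L),
    delta = list(
      rcp26 = list(ta = 1.1 + 0.3 * summer, rh = -1 - 1 * summer),
      rcp85 = list(ta = 3.3 + 1.0 * summer, rh = -3 - 3 * summer)))
  out <- utils::modifyList(cfg, list(...))
  if (out$years < 2L) stopf("fixture_config: need years >= 2")
  structure(out, class = "fixture_config")
}

# Hourly calendar scaffold (real calendar, leap days included).
.hourly_calendar <- function(start_year, years) {
  t0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", start_year), tz = "UTC")
  t1 <- as.POSIXct(sprintf("%d-12-31 23:00:00", start_year + years - 1L),
                   tz = "UTC")
  ts <- seq(t0, t1, by = "hour")
  lt <- as.POSIXlt(ts, tz = "UTC")
  list(ts = ts, yday = lt$yday + 1L, hour = lt$hour,
       frac_year = as.numeric(ts - t0, units = "days") / 365.25)
}

# Solar elevation sine for the clear-sky envelope (simplified geometry:
# only the statistical shape of the diurnal/seasonal radiation cycle
# matters for the fixtures, not astronomical accuracy).
.sin_elevation <- function(lat, yday, hour) {
  decl <- -23.44 * cos(2 * pi * (yday + 10) / 365.25) * pi / 180
  ha <- (hour + 0.5 - 12) * 15 * pi / 180
  latr <- lat * pi / 180
  sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(ha)
}

# Smooth hourly interpolation of a daily-resolution AR(1) anomaly series.
.synoptic_hourly <- function(n_hours, phi, sd_stat) {
  n_days <- n_hours %/% 24L
  daily <- ar1_series(n_days, phi, sd_stat)
  stats::approx(seq_len(n_days), daily,
                xout = (seq_len(n_hours) - 0.5) / 24 + 0.5, rule = 2)$y
}

#' Generate a synthetic multi-year hourly station record
#'
#' Temperature anomalies are a sum of three scales a real station record
#' exhibits and the resampling method relies on: fast hourly weather noise
#' (AR(1), e-folding time below a day), multi-day synoptic anomalies (a
#' daily-scale AR(1) smoothly interpolated to hours), and independent
#' warm/cold-year offsets.  Humidity is anti-correlated with the combined
#' temperature anomaly, radiation is a latitude-driven clear-sky envelope
#' modulated by slowly varying cloudiness, ozone is positively coupled to
#' radiation and temperature, and pressure wanders slowly around its mean.
#' Deterministic for a fixed config seed.  All generated series satisfy the
#' record invariants: humidity in \[0, 100\], non-negative radiation and
#' ozone, zero radiation at night.
#'
#' @param config a [fixture_config()]
#' @return a [station_record()] with variables `ta`, `rh`, `P`, `rg`, `o3`
#' @export
gen_station_record <- function(config = fixture_config()) {
  set.seed(config$seed)
  cal <- .hourly_calendar(config$start_year, config$years)
  n <- length(cal$ts)
  summer <- cos(2 * pi * (cal$yday - 196) / 365.25)
  afternoon <- cos(2 * pi * (cal$hour - 14) / 24)
  year_idx <- as.POSIXlt(cal$ts, tz = "UTC")$year + 1900L - config$start_year + 1L
  ta_anom <- ar1_series(n, config$ta_phi, config$ta_sd) +
    .synoptic_hourly(n, config$ta_syn_phi, config$ta_syn_sd) +
    stats::rnorm(config$years, sd = config$ta_year_sd)[year_idx]
  ta <- config$ta_mean + config$ta_seasonal_amp * summer +
    config$ta_diurnal_amp * (0.6 + 0.4 * summer) * afternoon + ta_anom
  rh <- config$rh_mean - config$rh_seasonal_amp * summer -
    config$rh_diurnal_amp * afternoon + config$rh_ta_slope * ta_anom +
    ar1_series(n, config$rh_phi, config$rh_sd) +
    .synoptic_hourly(n, config$rh_syn_phi, config$rh_syn_sd)
  rh <- clamp(rh, 0, 100)
  cloud <- 0.15 + 0.85 * stats::plogis(ar1_series(n, config$cloud_phi, 1.2))
  rg <- config$rg_clear_max * pmax(.sin_elevation(config$lat, cal$yday, cal$hour), 0) * cloud
  o3 <- pmax(config$o3_base + config$o3_rg_coef * rg +
               config$o3_ta_coef * pmax(ta, 0) +
               ar1_series(n, config$o3_phi, config$o3_sd) +
               .synoptic_hourly(n, config$o3_syn_phi, config$o3_syn_sd), 0)
  P <- config$p_mean + ar1_series(n, config$p_phi, config$p_sd)
  station_record(data.frame(timestamp = cal$ts, ta = ta, rh = rh, P = P,
                            rg = rg, o3 = o3),
                 vars = c("ta", "rh", "P", "rg", "o3"))
}

#' Generate a synthetic multi-year hourly CO2 record
#'
#' Linear trend centered on the configured long-term mean, spring-peaked
#' seasonal cycle, small diurnal cycle and AR(1) noise.
#'
#' @param config a [fixture_config()]
#' @return a [station_record()] with the single variable `co2`
#' @export
gen_co2_record <- function(config = fixture_config()) {
  set.seed(config$seed + 2L)
  cal <- .hourly_calendar(config$start_year, config$years)
  n <- length(cal$ts)
  trend <- config$co2_trend * (cal$frac_year - mean(cal$frac_year))
  seasonal <- config$co2_seasonal_amp * cos(2 * pi * (cal$yday - 105) / 365.25)
  diurnal <- config$co2_diurnal_amp * cos(2 * pi * (cal$hour - 4) / 24)
  co2 <- config$co2_mean + trend + seasonal + diurnal +
    ar1_series(n, config$co2_phi, config$co2_sd)
  station_record(data.frame(timestamp = cal$ts, co2 = co2), vars = "co2")
}

# One scenario-period block of daily member data on the standard calendar.
.member_block <- function(config, years, scenario, delta_ta, delta_rh,
                          model_id, run_id, lat, lon, off_ta, off_rh,
                          humidity_kind, subdaily_p) {
  ny <- length(years)
  doy <- rep(1:365, times = ny)
  yr <- rep(years, each = 365L)
  summer <- cos(2 * pi * (doy - 196) / 365)
  clim_ta <- config$ta_mean + config$ta_seasonal_amp * summer
  clim_rh <- config$rh_mean - config$rh_seasonal_amp * summer
  ta <- clim_ta + off_ta + delta_ta[doy] +
    stats::rnorm(ny * 365L, sd = config$day_sd)
  rh <- clamp(clim_rh + off_rh + delta_rh[doy] +
                stats::rnorm(ny * 365L, sd = config$day_sd_rh), 0, 100)
  P <- config$p_mean + stats::rnorm(ny * 365L, sd = 2)
  hum <- rh
  if (humidity_kind == "q") {
    e <- rh / 100 * saturation_vapor_pressure(ta)
    hum <- 0.622 * e / (P - 0.378 * e)
  }
  p_sub <- NULL
  daily_p <- P
  if (subdaily_p) {
    hours <- seq(0L, 21L, by = 3L)
    p_sub <- data.frame(
      year = rep(yr, each = 8L), doy = rep(doy, each = 8L),
      hour = rep(hours, times = ny * 365L),
      value = rep(P, each = 8L) +
        1.5 * cos(2 * pi * (rep(hours, times = ny * 365L) - 15) / 24))
    daily_p <- NA_real_
  }
  member_series(data.frame(year = yr, doy = doy, ta = ta, hum = hum,
                           P = daily_p),
                model_id = model_id, scenario = scenario, run_id = run_id,
                lat = lat, lon = lon, humidity_kind = humidity_kind,
                p_subdaily = p_sub)
}

#' Generate a mock regional climate model ensemble
#'
#' Produces, for every member x grid point, daily blocks for the historical
#' reference years, both RCP scenarios over the post-split reference years
#' (no injected signal: the mock world has no transient warming before the
#' future period) and both RCP scenarios over the future period carrying
#' the injected climate signals of the config.  Member and grid-point
#' offsets are drawn once per member so they cancel in the
#' future-minus-present difference.
#'
#' @param config a [fixture_config()]
#' @return list of [member_series()] blocks
#' @export
gen_ensemble <- function(config = fixture_config()) {
  set.seed(config$seed + 1L)
  ref_years <- config$start_year:(config$start_year + config$years - 1L)
  ref_end <- max(ref_years)
  hist_years <- ref_years[ref_years <= config$split_year]
  near_years <- ref_years[ref_years > config$split_year]
  fc_years <- config$fc_years[1]:config$fc_years[2]
  zero <- numeric(365L)
  members <- list()
  for (i in seq_len(config$n_members)) {
    model_id <- sprintf("GCM%d:RCM%d", (i - 1L) %/% 3L + 1L, i)
    off_ta <- stats::rnorm(1, sd = config$member_spread)
    off_rh <- stats::rnorm(1, sd = 2 * config$member_spread)
    hkind <- if (i == config$q_member) "q" else "rh"
    subp <- i == config$subdaily_p_member
    n_runs <- if (i == config$multirun_member) config$n_runs else 1L
    gdim <- if (i == config$shifted_member) config$grid_dim - 1L else config$grid_dim
    lats <- 50.0 + 0.1 * (seq_len(gdim) - 1L) + if (gdim < config$grid_dim) 0.05 else 0
    lons <- 9.2 + 0.15 * (seq_len(gdim) - 1L) + if (gdim < config$grid_dim) 0.075 else 0
    for (la in lats) for (lo in lons) {
      g_ta <- stats::rnorm(1, sd = config$grid_spread)
      g_rh <- stats::rnorm(1, sd = config$grid_spread)
      for (r in seq_len(n_runs)) {
        run_id <- sprintf("r%d", r)
        blk <- function(years, scenario, dta, drh)
          .member_block(config, years, scenario, dta, drh, model_id, run_id,
                        la, lo, off_ta + g_ta, off_rh + g_rh, hkind, subp)
        members <- c(members, list(
          blk(hist_years, "historical", zero, zero),
          blk(near_years, "rcp26", zero, zero),
          blk(near_years, "rcp85", zero, zero),
          blk(fc_years, "rcp26", config$delta$rcp26$ta, config$delta$rcp26$rh),
          blk(fc_years, "rcp85", config$delta$rcp85$ta, config$delta$rcp85$rh)))
      }
    }
  }
  members
}

#' Generate noisy "measured" facility logs from a chamber program
#'
#' Adds seeded Gaussian sensor noise to the minute trajectory and applies
#' optional fault episodes: `"stuck"` (value frozen at episode start),
#' `"offset"` (constant bias) or `"dropout"` (`NA`, removed from pair
#' counts downstream).
#'
#' @param program a `chamber_program` with a minute trajectory
#' @param sigma named per-variable noise sd (defaults: 0.1 degC, 2 % rh,
#'   2 ppb O3, 8 ppm CO2, 20 umol m-2 s-1 PPFD)
#' @param faults list of fault episodes, each a list with `var`, `start`
#'   (minute index), `length`, `type` and (for `"offset"`) `value`
#' @param seed RNG seed
#' @return data frame of measured minute series (same shape as the
#'   trajectory)
#' @export
gen_measured_logs <- function(program,
                              sigma = c(ta = 0.1, rh = 2, o3 = 2, co2 = 8,
                                        ppfd = 20),
                              faults = list(), seed = 1L) {
  if (is.null(program$minute))
    stopf("gen_measured_logs: program has no minute trajectory")
  set.seed(seed)
  traj <- program$minute
  out <- traj
  vars <- intersect(names(sigma), names(traj))
  for (v in vars)
    out[[v]] <- traj[[v]] + stats::rnorm(nrow(traj), sd = sigma[[v]])
  for (f in faults) {
    idx <- f$start:(f$start + f$length - 1L)
    out[[f$var]][idx] <- switch(f$type,
                                stuck = out[[f$var]][f$start],
                                offset = out[[f$var]][idx] + f$value,
                                dropout = NA_real_,
                                stopf("unknown fault type '%s'", f$type))
  }
  out
}
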