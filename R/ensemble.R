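#' Ensemble member series
#'
#' One block of daily model output for one model/run/grid-point/scenario:
#' a data frame with columns `year`, `doy` (standard 365-day calendar),
#' `ta` (degC), `hum` (relative humidity % or specific humidity kg kg-1,
#' see `humidity_kind`) and `P` (hPa).  Members that deliver pressure at
#' sub-daily resolution carry it in the `p_subdaily` attribute (columns
#' `year`, `doy`, `hour`, `value`) with `NA` in the daily `P` column.
#'
#' @param df data frame with columns `year`, `doy`, `ta`, `hum`, `P`
#' @param model_id,scenario,lat,lon,run_id,humidity_kind member metadata;
#'   `scenario` is one of `"historical"`, `"rcp26"`, `"rcp85"`;
#'   `humidity_kind` is `"rh"` or `"q"`
#' @param p_subdaily optional sub-daily pressure data frame
#' @return an object of class `member_series`
#' @export
member_series <- function(df, model_id, scenario, lat, lon, run_id = "r1",
                          humidity_kind = "rh", p_subdaily = NULL) {
  stopifnot(all(c("year", "doy", "ta", "hum", "P") %in% names(df)))
  if (!scenario %in% c("historical", "rcp26", "rcp85"))
    stopf("member_series: unknown scenario '%s'", scenario)
  if (!humidity_kind %in% c("rh", "q"))
    stopf("member_series: humidity_kind must be 'rh' or 'q'")
  df <- as.data.frame(df)[order(df$year, df$doy), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, model_id = model_id, scenario = scenario, run_id = run_id,
            lat = lat, lon = lon, humidity_kind = humidity_kind,
            p_subdaily = p_subdaily,
            class = c("member_series", "data.frame"))
}

#' Collapse a sub-daily series to daily means
#'
#' @param x data frame with columns `year`, `doy`, `hour`, `value`
#' @param step_hours time step of the input (must divide 24)
#' @return data frame with columns `year`, `doy`, `value` (daily means)
#' @export
subdaily_to_daily <- function(x, step_hours) {
  stopifnot(all(c("year", "doy", "value") %in% names(x)))
  if (24 %% step_hours != 0)
    stopf("subdaily_to_daily: step_hours must divide 24")
  per_day <- 24L %/% as.integer(step_hours)
  dt <- data.table::as.data.table(x)
  agg <- dt[, list(n = .N, value = mean(value)), by = c("year", "doy")]
  if (any(agg$n != per_day))
    stopf("subdaily_to_daily: partial day (expected %d values per day)", per_day)
  as.data.frame(agg[order(year, doy), c("year", "doy", "value")])
}

#' Average multiple runs of one ensemble member
#'
#' Day-wise arithmetic mean over stochastic realizations of the same
#' model/scenario/grid point (e.g. the 10 runs of a statistical
#' weather-generator downscaling).
#'
#' @param runs list of [member_series()] with identical calendars
#' @return a single [member_series()]
#' @export
average_member_runs <- function(runs) {
  if (!length(runs)) stopf("average_member_runs: empty run list")
  if (length(runs) == 1L) return(runs[[1L]])
  ref <- runs[[1L]]
  for (r in runs[-1L]) {
    if (!identical(attr(r, "model_id"), attr(ref, "model_id")) ||
        !identical(attr(r, "scenario"), attr(ref, "scenario")) ||
        !identical(c(attr(r, "lat"), attr(r, "lon")),
                   c(attr(ref, "lat"), attr(ref, "lon"))))
      stopf("average_member_runs: runs from different member/scenario/grid")
    if (!identical(r$year, ref$year) || !identical(r$doy, ref$doy))
      stopf("average_member_runs: mismatched calendars across runs")
    if (!identical(attr(r, "humidity_kind"), attr(ref, "humidity_kind")))
      stopf("average_member_runs: mixed humidity kinds across runs")
  }
  out <- ref
  for (v in c("ta", "hum", "P"))
    out[[v]] <- rowMeans(vapply(runs, function(r) r[[v]], numeric(nrow(ref))))
  attr(out, "run_id") <- paste(vapply(runs, attr, "", "run_id"), collapse = "+")
  out
}

#' Map one model year of arbitrary calendar length to the 365-day calendar
#'
#' 360-day and leap calendars are mapped by linear index interpolation with
#' an additive correction so the annual mean is preserved exactly.
#'
#' @param v numeric vector of one year's daily values (length 360, 365 or 366)
#' @return numeric vector of length 365 with the same mean
#' @export
map_to_standard_year <- function(v) {
  n <- length(v)
  if (n == 365L) return(v)
  if (!n %in% c(360L, 366L))
    stopf("map_to_standard_year: unsupported calendar length %d", n)
  out <- stats::approx(seq(1, 365, length.out = n), v, xout = 1:365)$y
  out + (mean(v) - mean(out))
}

#' Mean annual course of a daily series
#'
#' `value[d]` is the mean over years of the day-`d` value, `d = 1..365`.
#' Every year present must be complete on the standard calendar.
#'
#' @param df data frame with columns `year`, `doy` and the value column
#' @param var name of the value column
#' @return numeric vector of length 365
#' @export
annual_course <- function(df, var = "value") {
  tab <- table(df$year)
  if (any(tab != 365L))
    stopf("annual_course: incomplete year(s): %s",
          paste(names(tab)[tab != 365L], collapse = ", "))
  m <- matrix(df[[var]][order(df$year, df$doy)], nrow = 365L)
  rowMeans(m)
}

#' Low-order Fourier smoothing of a 365-day climatology
#'
#' Retains the annual-mean term and the harmonics with 1..`max_order`
#' cycles per year of the discrete Fourier transform; all higher
#' frequencies are eliminated.  The series mean is preserved exactly.
#'
#' @param x numeric vector of length 365
#' @param max_order highest harmonic retained (default 3)
#' @return smoothed numeric vector of length 365
#' @export
fft_smooth <- function(x, max_order = 3) {
  if (length(x) != 365L) stopf("fft_smooth: input must have length 365")
  f <- stats::fft(x)
  keep <- c(1L, seq_len(max_order) + 1L, 365L + 1L - seq_len(max_order))
  f[setdiff(seq_len(365L), keep)] <- 0
  Re(stats::fft(f, inverse = TRUE)) / 365
}

#' Assemble the present-climate series of one member
#'
#' The present-climate (PC) period of a projection-driven member is the
#' concatenation of its historical years up to `split_year` with the
#' day-wise average of its two RCP projections for the remaining reference
#' years.
#'
#' @param historical,rcp26,rcp85 [member_series()] of one member/grid point
#' @param split_year last year taken from the historical block
#' @param ref_end last year of the reference period
#' @return a [member_series()] covering the full reference period
#' @export
build_pc_series <- function(historical, rcp26, rcp85, split_year, ref_end) {
  hist_part <- historical[historical$year <= split_year, , drop = FALSE]
  post_years <- (split_year + 1L):ref_end
  a <- rcp26[rcp26$year %in% post_years, , drop = FALSE]
  b <- rcp85[rcp85$year %in% post_years, , drop = FALSE]
  if (!all(post_years %in% a$year) || !all(post_years %in% b$year) ||
      nrow(a) != length(post_years) * 365L || nrow(b) != length(post_years) * 365L)
    stopf("build_pc_series: RCP coverage gap in %s..%d", split_year + 1L, ref_end)
  if (!identical(a$year, b$year) || !identical(a$doy, b$doy))
    stopf("build_pc_series: RCP calendars differ")
  post <- a
  for (v in c("ta", "hum", "P")) post[[v]] <- (a[[v]] + b[[v]]) / 2
  out <- rbind(as.data.frame(hist_part)[, c("year", "doy", "ta", "hum", "P")],
               as.data.frame(post)[, c("year", "doy", "ta", "hum", "P")])
  member_series(out, model_id = attr(historical, "model_id"), scenario = "historical",
                lat = attr(historical, "lat"), lon = attr(historical, "lon"),
                run_id = attr(historical, "run_id"),
                humidity_kind = attr(historical, "humidity_kind"))
}

#' Climate signal of one member/grid point
#'
#' Additive day-of-year deltas between a future-scenario climatology and
#' the present-climate climatology: `delta[d] = FC[d] - PC[d]`.
#'
#' @param fc,pc lists with elements `ta` and `rh`, each a smoothed 365-day
#'   climatology
#' @param scenario scenario label carried on the result
#' @param id provenance string for this member/grid point
#' @return a `climate_signal` data frame (`doy`, `delta_ta`, `delta_rh`)
#' @export
climate_signal <- function(fc, pc, scenario = "rcp85", id = NULL) {
  if (length(fc$ta) != length(pc$ta) || length(fc$rh) != length(pc$rh))
    stopf("climate_signal: climatology length mismatch")
  out <- data.frame(doy = seq_along(fc$ta),
                    delta_ta = fc$ta - pc$ta,
                    delta_rh = fc$rh - pc$rh)
  structure(out, scenario = scenario, provenance = if (is.null(id)) character() else id,
            class = c("climate_signal", "data.frame"))
}

#' Ensemble-mean climate signal
#'
#' Flat day-wise arithmetic mean over all member x grid-point signals,
#' with provenance recorded.
#'
#' @param signals non-empty list of `climate_signal` objects of equal length
#' @return a `climate_signal`
#' @export
ensemble_mean_signal <- function(signals) {
  if (!length(signals)) stopf("ensemble_mean_signal: empty signal set")
  n <- nrow(signals[[1L]])
  for (s in signals)
    if (nrow(s) != n) stopf("ensemble_mean_signal: signal length mismatch")
  out <- signals[[1L]]
  out$delta_ta <- rowMeans(vapply(signals, function(s) s$delta_ta, numeric(n)))
  out$delta_rh <- rowMeans(vapply(signals, function(s) s$delta_rh, numeric(n)))
  attr(out, "provenance") <- unlist(lapply(signals, attr, "provenance"))
  out
}

# --- orchestration ---------------------------------------------------------

member_key <- function(m) {
  paste(attr(m, "model_id"), attr(m, "lat"), attr(m, "lon"), sep = "|")
}

# Daily rh series of one member after run averaging, sub-daily pressure
# aggregation and (if needed) q -> rh conversion.
normalize_member <- function(m) {
  ps <- attr(m, "p_subdaily")
  if (!is.null(ps)) {
    daily_p <- subdaily_to_daily(ps, step_hours = attr(m, "p_step_hours") %||% 3)
    idx <- match(paste(m$year, m$doy), paste(daily_p$year, daily_p$doy))
    if (anyNA(idx)) stopf("normalize_member: sub-daily pressure coverage gap")
    m$P <- daily_p$value[idx]
  }
  if (attr(m, "humidity_kind") == "q") {
    m$hum <- as.numeric(specific_humidity_to_rh(m$hum, m$P, m$ta))
    attr(m, "humidity_kind") <- "rh"
  }
  m
}

# Smoothed ta/rh climatologies of a member series restricted to given years.
member_climatology <- function(m, years, max_order = 3) {
  sub <- m[m$year %in% years, , drop = FALSE]
  if (!setequal(unique(sub$year), years))
    stopf("member climatology: years %s..%s not fully covered by member %s",
          min(years), max(years), attr(m, "model_id"))
  list(ta = fft_smooth(annual_course(data.frame(year = sub$year, doy = sub$doy,
                                                value = sub$ta)), max_order),
       rh = fft_smooth(annual_course(data.frame(year = sub$year, doy = sub$doy,
                                                value = sub$hum)), max_order))
}

#' Ensemble-mean climate signal from raw member series
#'
#' Full signal pipeline: per member/grid point, runs are averaged, sub-daily
#' pressure is aggregated, specific humidity is converted to relative
#' humidity, the present-climate period is assembled from historical plus
#' averaged RCP years, climatologies are computed and Fourier-smoothed, and
#' the future-minus-present difference is taken; signals are then averaged
#' flat over all member x grid-point combinations.
#'
#' @param members list of [member_series()] blocks (any mix of scenarios,
#'   periods and runs)
#' @param scenario future scenario, `"rcp26"` or `"rcp85"`
#' @param ref_years reference (present-climate) period, `c(first, last)`
#' @param split_year last reference year taken from the historical blocks
#' @param fc_years future period, `c(first, last)`
#' @param max_order highest Fourier harmonic retained in the smoothing
#' @return ensemble-mean `climate_signal`
#' @export
build_ensemble_signal <- function(members, scenario = c("rcp85", "rcp26"),
                                  ref_years = c(1987L, 2016L),
                                  split_year = 2005L,
                                  fc_years = c(2071L, 2100L),
                                  max_order = 3) {
  scenario <- match.arg(scenario)
  keys <- vapply(members, member_key, "")
  signals <- list()
  for (k in unique(keys)) {
    blocks <- members[keys == k]
    scen <- vapply(blocks, attr, "", "scenario")
    per_scen <- lapply(c(historical = "historical", rcp26 = "rcp26",
                         rcp85 = "rcp85"), function(s) {
      bl <- blocks[scen == s]
      if (!length(bl)) stopf("build_ensemble_signal: member %s lacks %s data", k, s)
      # merge period chunks of each run, then average runs
      runs <- split(bl, vapply(bl, attr, "", "run_id"))
      runs <- lapply(runs, function(chunks) {
        if (length(chunks) == 1L) return(chunks[[1L]])
        df <- do.call(rbind, lapply(chunks, function(x)
          as.data.frame(x)[, c("year", "doy", "ta", "hum", "P")]))
        tmpl <- chunks[[1L]]
        subs <- lapply(chunks, attr, "p_subdaily")
        subs <- subs[!vapply(subs, is.null, TRUE)]
        member_series(df, model_id = attr(tmpl, "model_id"),
                      scenario = s, lat = attr(tmpl, "lat"),
                      lon = attr(tmpl, "lon"), run_id = attr(tmpl, "run_id"),
                      humidity_kind = attr(tmpl, "humidity_kind"),
                      p_subdaily = if (length(subs)) do.call(rbind, subs))
      })
      normalize_member(average_member_runs(lapply(runs, normalize_member)))
    })
    pc <- build_pc_series(per_scen$historical, per_scen$rcp26, per_scen$rcp85,
                          split_year = split_year, ref_end = ref_years[2])
    pc_clim <- member_climatology(pc, ref_years[1]:ref_years[2], max_order)
    fc_clim <- member_climatology(per_scen[[scenario]],
                                  fc_years[1]:fc_years[2], max_order)
    signals[[k]] <- climate_signal(fc_clim, pc_clim, scenario = scenario, id = k)
  }
  ensemble_mean_signal(signals)
}
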