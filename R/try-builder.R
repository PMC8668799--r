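#' Reference climatology of the station record
#'
#' The multi-year mean, daily resolved annual course of air temperature,
#' relative humidity and global radiation, plus the per-day standard
#' deviation of daily mean air temperature across years.  The mean courses
#' are optionally Fourier-smoothed (default, 3 harmonics) to match the
#' noise reduction applied to the model climatologies; the SD course is
#' left unsmoothed.
#'
#' @param daily a `daily_record` from [daily_aggregate()]
#' @param smooth apply [fft_smooth()] to the mean courses
#' @param max_order highest harmonic kept when smoothing
#' @return a `ref_climatology` data frame (`doy`, `ta`, `rh`, `rg`, `sd_ta`)
#' @export
reference_climatology <- function(daily, smooth = TRUE, max_order = 3) {
  years <- complete_years(daily)
  if (length(years) < 2L)
    stopf("reference_climatology: need at least 2 complete years (SD undefined)")
  d <- daily[daily$year %in% years, , drop = FALSE]
  d <- d[order(d$year, d$doy), , drop = FALSE]
  mat <- function(v) matrix(d[[v]], nrow = 365L)
  ta <- rowMeans(mat("tmean"))
  rh <- rowMeans(mat("rh"))
  rg <- rowMeans(mat("rg"))
  sd_ta <- apply(mat("tmean"), 1L, stats::sd)
  if (smooth) {
    ta <- fft_smooth(ta, max_order)
    rh <- fft_smooth(rh, max_order)
    rg <- fft_smooth(rg, max_order)
  }
  structure(data.frame(doy = 1:365, ta = ta, rh = rh, rg = rg, sd_ta = sd_ta),
            scenario = "pc", n_years = length(years),
            class = c("ref_climatology", "data.frame"))
}

#' Shift a reference climatology by a climate signal
#'
#' Adds the daily `delta_ta`/`delta_rh` of an ensemble-mean climate signal
#' to the temperature and humidity courses; humidity is clipped to
#' \[0, 100\] (clip count in attribute `n_clipped`).  Radiation and the SD
#' course are copied unchanged.
#'
#' @param rc a `ref_climatology`
#' @param signal a `climate_signal`
#' @return the scenario `ref_climatology`
#' @export
apply_signal <- function(rc, signal) {
  if (nrow(signal) != nrow(rc)) stopf("apply_signal: length mismatch")
  out <- rc
  out$ta <- rc$ta + signal$delta_ta
  rh <- rc$rh + signal$delta_rh
  n_clipped <- sum(rh < 0 | rh > 100)
  out$rh <- clamp(rh, 0, 100)
  attr(out, "scenario") <- attr(signal, "scenario")
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Enumerate candidate weather segments at a start day
#'
#' One candidate per (record year, segment length).  In the interior of the
#' year lengths run `min_len..max_len`, truncated so no candidate extends
#' past day 365; if fewer than `min_len` days remain, a single tail length
#' covering exactly the remaining days is used so the year can be tiled to
#' December 31.
#'
#' @param years integer vector of record years to draw from
#' @param start_doy first day (standard day-of-year) of the segment
#' @param min_len,max_len segment length bounds in days
#' @return data frame with columns `year`, `start_doy`, `length`
#' @export
enumerate_candidates <- function(years, start_doy, min_len = 10L, max_len = 30L) {
  remaining <- 365L - start_doy + 1L
  lens <- if (remaining < min_len) remaining
          else seq.int(min_len, min(max_len, remaining))
  out <- expand.grid(year = as.integer(years), length = as.integer(lens),
                     KEEP.OUT.ATTRS = FALSE)
  out$start_doy <- as.integer(start_doy)
  out[order(out$year, out$length), c("year", "start_doy", "length")]
}

#' Default rank-score weights for segment selection
#'
#' The two air-temperature criteria are reweighted (0.3 for the mean, 0.7
#' for the SD); humidity, radiation and the continuity criterion keep unit
#' weight.
#'
#' @return named list of criterion weights
#' @export
score_weights <- function() {
  list(mean_ta = 0.3, sd_ta = 0.7, mean_rh = 1, mean_rg = 1, continuity = 1)
}

# Per-year prefix sums of the daily record, for O(1) segment statistics.
daily_prefix <- function(daily) {
  years <- complete_years(daily)
  d <- daily[daily$year %in% years, , drop = FALSE]
  d <- d[order(d$year, d$doy), , drop = FALSE]
  mk <- function(v) {
    m <- matrix(d[[v]], nrow = 365L, dimnames = list(NULL, years))
    apply(m, 2L, cumsum)
  }
  list(years = years,
       ta = mk("tmean"), ta2 = {
         m <- matrix(d$tmean^2, nrow = 365L, dimnames = list(NULL, years))
         apply(m, 2L, cumsum)
       },
       rh = mk("rh"), rg = mk("rg"))
}

seg_sum <- function(cs, year, s, e) {
  col <- as.character(year)
  cs[e, col] - if (s > 1L) cs[s - 1L, col] else 0
}

#' Rank-score candidate segments against a reference climatology
#'
#' For each candidate the absolute differences to the target window of
#' identical start and length are computed for four criteria (mean ta, SD
#' of daily ta, mean rh, mean rg) plus, when `prev_mean_ta` is given, the
#' continuity criterion (absolute difference of mean ta to the preceding
#' segment).  Candidates are ranked per criterion in ascending order of
#' difference with integer scores 0, 1, 2, ... (ties share the minimum
#' rank); the weighted rank sum is the total score.
#'
#' @param candidates data frame from [enumerate_candidates()]
#' @param rc target `ref_climatology`
#' @param daily the `daily_record` the candidates are drawn from
#' @param prev_mean_ta mean daily ta of the previously chosen segment, or
#'   `NULL` for the first segment (continuity criterion omitted)
#' @param weights list as from [score_weights()]
#' @return `candidates` with criterion values, per-criterion scores and
#'   `total_score`
#' @export
score_segments <- function(candidates, rc, daily, prev_mean_ta = NULL,
                           weights = score_weights()) {
  if (!nrow(candidates)) stopf("score_segments: empty candidate set")
  pre <- daily_prefix(daily)
  n <- nrow(candidates)
  stats <- matrix(NA_real_, n, 4,
                  dimnames = list(NULL, c("mean_ta", "sd_ta", "mean_rh", "mean_rg")))
  tgt <- matrix(NA_real_, n, 4)
  rc_ta_cs <- cumsum(rc$ta); rc_rh_cs <- cumsum(rc$rh)
  rc_rg_cs <- cumsum(rc$rg); rc_sd_cs <- cumsum(rc$sd_ta)
  wsum <- function(cs, s, e) cs[e] - if (s > 1L) cs[s - 1L] else 0
  for (i in seq_len(n)) {
    y <- candidates$year[i]; s <- candidates$start_doy[i]
    L <- candidates$length[i]; e <- s + L - 1L
    m_ta <- seg_sum(pre$ta, y, s, e) / L
    ss <- seg_sum(pre$ta2, y, s, e)
    sd_ta <- if (L > 1L) sqrt(max(0, (ss - L * m_ta^2) / (L - 1L))) else 0
    stats[i, ] <- c(m_ta, sd_ta,
                    seg_sum(pre$rh, y, s, e) / L, seg_sum(pre$rg, y, s, e) / L)
    tgt[i, ] <- c(wsum(rc_ta_cs, s, e) / L, wsum(rc_sd_cs, s, e) / L,
                  wsum(rc_rh_cs, s, e) / L, wsum(rc_rg_cs, s, e) / L)
  }
  out <- candidates
  out$mean_ta <- stats[, "mean_ta"]
  out$d_mean_ta <- abs(stats[, "mean_ta"] - tgt[, 1])
  out$d_sd_ta <- abs(stats[, "sd_ta"] - tgt[, 2])
  out$d_mean_rh <- abs(stats[, "mean_rh"] - tgt[, 3])
  out$d_mean_rg <- abs(stats[, "mean_rg"] - tgt[, 4])
  score <- function(d) rank(d, ties.method = "min") - 1L
  total <- weights$mean_ta * score(out$d_mean_ta) +
    weights$sd_ta * score(out$d_sd_ta) +
    weights$mean_rh * score(out$d_mean_rh) +
    weights$mean_rg * score(out$d_mean_rg)
  if (!is.null(prev_mean_ta)) {
    out$d_continuity <- abs(out$mean_ta - prev_mean_ta)
    total <- total + weights$continuity * score(out$d_continuity)
  }
  out$total_score <- total
  out
}

#' Greedy segment selection tiling the year
#'
#' Starting on January 1, all candidates at the current day are scored with
#' [score_segments()] and the lowest-total-score segment is chosen; the
#' procedure repeats from the day after the segment end until December 31.
#' Ties on the total score are broken deterministically: smallest mean-ta
#' difference, then earliest source year, then shortest length.
#'
#' @param daily the `daily_record` (complete standard-calendar years)
#' @param rc target `ref_climatology` for the scenario
#' @param config list overriding `min_len` (10), `max_len` (30),
#'   `start_doy` (1) and `weights` ([score_weights()])
#' @return a `segment_plan` data frame
#'   (`segment`, `source_year`, `start_doy`, `length_days`, `total_score`)
#' @export
select_segments <- function(daily, rc, config = list()) {
  min_len <- config$min_len %||% 10L
  max_len <- config$max_len %||% 30L
  weights <- config$weights %||% score_weights()
  years <- complete_years(daily)
  if (!length(years)) stopf("select_segments: no complete years in record")
  pos <- as.integer(config$start_doy %||% 1L)
  prev_mean_ta <- NULL
  rows <- list()
  while (pos <= 365L) {
    cand <- enumerate_candidates(years, pos, min_len, max_len)
    scored <- score_segments(cand, rc, daily, prev_mean_ta, weights)
    ord <- order(scored$total_score, scored$d_mean_ta, scored$year,
                 scored$length)
    best <- scored[ord[1L], ]
    rows[[length(rows) + 1L]] <-
      data.frame(segment = length(rows) + 1L, source_year = best$year,
                 start_doy = pos, length_days = best$length,
                 total_score = best$total_score)
    prev_mean_ta <- best$mean_ta
    pos <- pos + best$length
  }
  plan <- do.call(rbind, rows)
  structure(plan, weights = weights,
            class = c("segment_plan", "data.frame"))
}

#' Replace selected daily segments by their hourly source records
#'
#' Each planned segment's hours are copied verbatim from the source year at
#' the same calendar positions, producing the 8,760-hour annual cycle.
#'
#' @param hourly a filled, standard-calendar [station_record()]
#' @param plan a `segment_plan`
#' @param scenario scenario label carried on the result
#' @return a `try_year` data frame with 8,760 rows
#'   (`hour_of_year`, `doy`, `hour`, `ta`, `rh`, `P`, `rg`, `o3`, `co2`,
#'   `segment_id`, `interpolated`)
#' @export
assemble_hourly <- function(hourly, plan, scenario = "pc") {
  vars <- intersect(c("ta", "rh", "P", "rg", "o3"), record_vars(hourly))
  if (sum(plan$length_days) != 365L)
    stopf("assemble_hourly: plan does not tile 365 days")
  key_rec <- hourly$year * 10000L + hourly$doy * 24L + hourly$hour
  out <- data.frame(hour_of_year = 1:8760,
                    doy = rep(1:365, each = 24L),
                    hour = rep(0:23, times = 365L))
  out$segment_id <- rep(plan$segment, times = plan$length_days * 24L)
  src_year <- rep(plan$source_year, times = plan$length_days * 24L)
  key_out <- src_year * 10000L + out$doy * 24L + out$hour
  idx <- match(key_out, key_rec)
  if (anyNA(idx))
    stopf("assemble_hourly: source hours missing for year(s) %s",
          paste(unique(src_year[is.na(idx)]), collapse = ", "))
  for (v in vars) out[[v]] <- hourly[[v]][idx]
  if (anyNA(out[, vars]))
    stopf("assemble_hourly: missing values in source record; fill gaps first")
  out$co2 <- NA_real_
  out$interpolated <- FALSE
  structure(out, plan = plan, scenario = scenario,
            class = c("try_year", "data.frame"))
}

#' Linearly smooth segment transitions
#'
#' At each internal segment boundary the listed variables are replaced, for
#' the 15 hours strictly between 8 h before the boundary and 8 h after it,
#' by the straight line joining the values at those two anchor hours.
#' Radiation (and CO2) are never modified; the affected hours are marked in
#' the `interpolated` column.
#'
#' @param try a `try_year` from [assemble_hourly()]
#' @param window_hours half-window in hours (anchors at +/- this distance)
#' @param variables variables to interpolate
#' @return the smoothed `try_year`
#' @export
smooth_transitions <- function(try, window_hours = 8L,
                               variables = c("ta", "rh", "P", "o3")) {
  plan <- attr(try, "plan")
  if (nrow(plan) < 2L) return(try)
  w <- as.integer(window_hours)
  bounds <- 24L * cumsum(plan$length_days)
  bounds <- bounds[-length(bounds)] + 1L  # first hour of each next segment
  last_end <- -Inf
  for (b in bounds) {
    a <- b - w; z <- b + w
    if (a <= last_end)
      stopf("smooth_transitions: interpolation windows overlap at hour %d", b)
    if (a < 1L || z > nrow(try))
      stopf("smooth_transitions: window out of range at hour %d", b)
    k <- seq_len(2L * w - 1L)  # interior hours a+1 .. z-1
    for (v in variables) {
      try[[v]][a + k] <- try[[v]][a] + (try[[v]][z] - try[[v]][a]) * k / (2 * w)
    }
    try$interpolated[a + k] <- TRUE
    last_end <- z
  }
  try
}

#' Rescale an ozone series to a scenario target mean
#'
#' The series is normalized by its own annual mean and multiplied by the
#' long-term station mean times the scenario factor (0.75 for the
#' mitigation scenario, 1.115 for the high-emission scenario, 1 for present
#' climate), so the output mean equals `longterm_mean * factor` exactly and
#' the hourly shape is preserved.
#'
#' @param o3 hourly ozone series (ppb)
#' @param longterm_mean long-term mean ozone of the reference station (ppb)
#' @param factor scenario factor
#' @return rescaled series
#' @export
adjust_o3_scenario <- function(o3, longterm_mean, factor = 1) {
  m <- mean(o3)
  if (!is.finite(m) || m <= 0)
    stopf("adjust_o3_scenario: non-positive annual mean")
  o3 / m * (longterm_mean * factor)
}

#' Scenario CO2 series from a multi-year record
#'
#' The mean annual hourly cycle (per calendar hour over all years) of the
#' CO2 record is normalized by its overall mean and multiplied by the
#' scenario target so the output annual mean equals `target_mean` exactly.
#'
#' @param co2_record a filled, standard-calendar [station_record()] with a
#'   `co2` variable
#' @param target_mean scenario annual-mean CO2 (ppm)
#' @return numeric vector of 8,760 hourly values
#' @export
build_co2_series <- function(co2_record, target_mean) {
  if (!"co2" %in% record_vars(co2_record))
    stopf("build_co2_series: record has no co2 variable")
  if (!nrow(co2_record)) stopf("build_co2_series: empty record")
  x <- co2_record$co2
  if (anyNA(x)) stopf("build_co2_series: missing CO2 values; fill gaps first")
  key <- (co2_record$doy - 1L) * 24L + co2_record$hour + 1L
  cyc <- as.numeric(tapply(x, factor(key, levels = 1:8760), mean))
  if (anyNA(cyc)) stopf("build_co2_series: incomplete annual CO2 cycle")
  cyc / mean(cyc) * target_mean
}

# Scenario defaults: ozone factors after hemispheric chemistry-transport
# projections for 2100 (Sicard et al.), CO2 targets for the station
# long-term mean and the 2100 scenario concentrations.
scenario_defaults <- function(scenario) {
  switch(scenario,
         pc = list(o3_factor = 1, co2_target = 375),
         rcp26 = list(o3_factor = 0.75, co2_target = 421),
         rcp85 = list(o3_factor = 1.115, co2_target = 936),
         stopf("unknown scenario '%s'", scenario))
}

#' Build a complete Test Reference Year
#'
#' Orchestrates the whole resampling pipeline: reference climatology from
#' the station record, optional climate-signal shift, greedy segment
#' selection, hourly assembly, transition smoothing, ozone scenario
#' rescaling and CO2 series construction.
#'
#' @param hourly a quality-controlled, filled [station_record()] with
#'   variables `ta`, `rh`, `P`, `rg`, `o3` (leap days are removed here if
#'   still present)
#' @param co2_record a filled [station_record()] with variable `co2`
#' @param signal an ensemble-mean `climate_signal`, or `NULL` for the
#'   present-climate scenario
#' @param scenario `"pc"`, `"rcp26"` or `"rcp85"`
#' @param config list overriding segment-selection settings (see
#'   [select_segments()]) plus `window_hours`, `o3_factor`, `co2_target`,
#'   `smooth_rc`, `max_order`
#' @return a `try_year` with all six variables populated and the segment
#'   plan attached as attribute `plan`
#' @export
build_try <- function(hourly, co2_record, signal = NULL,
                      scenario = c("pc", "rcp26", "rcp85"), config = list()) {
  scenario <- match.arg(scenario)
  defaults <- scenario_defaults(scenario)
  if (is.null(signal) && scenario != "pc")
    stopf("build_try: scenario '%s' requires a climate signal", scenario)
  hourly <- to_standard_calendar(hourly)
  co2_record <- to_standard_calendar(co2_record)
  daily <- daily_aggregate(hourly)
  rc <- reference_climatology(daily, smooth = config$smooth_rc %||% TRUE,
                              max_order = config$max_order %||% 3)
  if (!is.null(signal)) rc <- apply_signal(rc, signal)
  plan <- select_segments(daily, rc, config)
  try <- assemble_hourly(hourly, plan, scenario = scenario)
  try <- smooth_transitions(try, window_hours = config$window_hours %||% 8L)
  o3_factor <- config$o3_factor %||% defaults$o3_factor
  if (o3_factor != 1) {
    longterm_o3 <- mean(hourly$o3)
    try$o3 <- adjust_o3_scenario(try$o3, longterm_o3, o3_factor)
  }
  co2_target <- config$co2_target %||% defaults$co2_target
  try$co2 <- build_co2_series(co2_record, co2_target)
  attr(try, "provenance") <- list(
    scenario = scenario, o3_factor = o3_factor, co2_target = co2_target,
    record_years = complete_years(daily),
    weights = attr(plan, "weights"))
  try
}

#' @export
print.try_year <- function(x, ...) {
  plan <- attr(x, "plan")
  cat(sprintf("<try_year> scenario %s: 8760 hours, %d segments\n",
              attr(x, "scenario"), nrow(plan)))
  cat(sprintf("  annual means: ta %.2f degC, rh %.1f %%, P %.0f hPa, rg %.0f W/m2, o3 %.1f ppb, co2 %.0f ppm\n",
              mean(x$ta), mean(x$rh), mean(x$P), mean(x$rg), mean(x$o3),
              mean(x$co2)))
  invisible(x)
}
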