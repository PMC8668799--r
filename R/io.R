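# Serialization of the pipeline artifacts.  All formats are plain text
# (CSV / JSON) with bit-stable row ordering.

#' Write a climate signal to CSV
#' @param signal a `climate_signal`
#' @param path output CSV (`day_of_year`, `delta_ta`, `delta_rh`)
#' @export
write_signal_csv <- function(signal, path) {
  data.table::fwrite(data.frame(day_of_year = signal$doy,
                                delta_ta = signal$delta_ta,
                                delta_rh = signal$delta_rh,
                                scenario = attr(signal, "scenario")), path)
  invisible(path)
}

#' Read a climate signal from CSV
#' @param path CSV written by [write_signal_csv()]
#' @return a `climate_signal`
#' @export
read_signal_csv <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  structure(data.frame(doy = df$day_of_year, delta_ta = df$delta_ta,
                       delta_rh = df$delta_rh),
            scenario = df$scenario[1] %||% "unknown",
            class = c("climate_signal", "data.frame"))
}

#' Write a Test Reference Year to CSV (plus JSON segment-plan sidecar)
#'
#' Timestamps use a nominal non-leap calendar year.
#'
#' @param try a `try_year`
#' @param path output CSV; the plan is written next to it as
#'   `<path>.plan.json`
#' @param nominal_year non-leap year used for the timestamp column
#' @export
write_try_csv <- function(try, path, nominal_year = 2001L) {
  if (is_leap_year(nominal_year)) stopf("nominal_year must not be a leap year")
  t0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", nominal_year), tz = "UTC")
  out <- data.frame(
    timestamp = format(t0 + (try$hour_of_year - 1L) * 3600, "%Y-%m-%dT%H:%M:%S"),
    ta_C = try$ta, rh_pct = try$rh, P_hPa = try$P, Rg_Wm2 = try$rg,
    o3_ppb = try$o3, co2_ppm = try$co2, segment_id = try$segment_id,
    interpolated_flag = as.integer(try$interpolated))
  data.table::fwrite(out, path)
  plan <- attr(try, "plan")
  jsonlite::write_json(
    list(scenario = attr(try, "scenario"),
         weights = attr(plan, "weights"),
         segments = as.data.frame(plan)),
    paste0(path, ".plan.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a Test Reference Year written by [write_try_csv()]
#' @param path CSV path (the `.plan.json` sidecar is read if present)
#' @return a `try_year`
#' @export
read_try_csv <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  out <- data.frame(hour_of_year = seq_len(nrow(df)),
                    doy = (seq_len(nrow(df)) - 1L) %/% 24L + 1L,
                    hour = (seq_len(nrow(df)) - 1L) %% 24L,
                    segment_id = df$segment_id,
                    ta = df$ta_C, rh = df$rh_pct, P = df$P_hPa,
                    rg = df$Rg_Wm2, o3 = df$o3_ppb, co2 = df$co2_ppm,
                    interpolated = df$interpolated_flag == 1L)
  plan_path <- paste0(path, ".plan.json")
  plan <- NULL
  scenario <- "unknown"
  if (file.exists(plan_path)) {
    meta <- jsonlite::read_json(plan_path, simplifyVector = TRUE)
    plan <- structure(meta$segments, weights = as.list(meta$weights),
                      class = c("segment_plan", "data.frame"))
    scenario <- meta$scenario
  }
  structure(out, plan = plan, scenario = scenario,
            class = c("try_year", "data.frame"))
}

#' Write an ensemble member list to long-format CSV
#'
#' One row per value: `model_id`, `run_id`, `scenario`, `lat`, `lon`,
#' `year`, `doy`, `hour` (`NA` for daily values), `variable`
#' (`ta`, `rh`, `q`, `P`, `P_sub`), `value`.
#'
#' @param members list of [member_series()]
#' @param path output CSV
#' @export
write_ensemble_csv <- function(members, path) {
  blocks <- lapply(members, function(m) {
    base <- data.frame(model_id = attr(m, "model_id"),
                       run_id = attr(m, "run_id"),
                       scenario = attr(m, "scenario"),
                       lat = attr(m, "lat"), lon = attr(m, "lon"),
                       year = m$year, doy = m$doy, hour = NA_integer_)
    hum_var <- attr(m, "humidity_kind")
    long <- rbind(cbind(base, variable = "ta", value = m$ta),
                  cbind(base, variable = hum_var, value = m$hum))
    if (!all(is.na(m$P)))
      long <- rbind(long, cbind(base, variable = "P", value = m$P))
    ps <- attr(m, "p_subdaily")
    if (!is.null(ps)) {
      sub <- data.frame(model_id = attr(m, "model_id"),
                        run_id = attr(m, "run_id"),
                        scenario = attr(m, "scenario"),
                        lat = attr(m, "lat"), lon = attr(m, "lon"),
                        year = ps$year, doy = ps$doy, hour = ps$hour,
                        variable = "P_sub", value = ps$value)
      long <- rbind(long, sub)
    }
    long
  })
  data.table::fwrite(data.table::rbindlist(blocks), path)
  invisible(path)
}

#' Read an ensemble member list from long-format CSV
#' @param path CSV written by [write_ensemble_csv()]
#' @return list of [member_series()]
#' @export
read_ensemble_csv <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  key <- paste(df$model_id, df$run_id, df$scenario, df$lat, df$lon, sep = "\r")
  lapply(split(df, key), function(g) {
    daily <- g[is.na(g$hour), , drop = FALSE]
    wide <- data.table::dcast(data.table::as.data.table(daily),
                              year + doy ~ variable, value.var = "value")
    wide <- as.data.frame(wide)
    hkind <- if ("q" %in% names(wide)) "q" else "rh"
    sub <- g[!is.na(g$hour) & g$variable == "P_sub", , drop = FALSE]
    p_sub <- NULL
    if (nrow(sub))
      p_sub <- data.frame(year = sub$year, doy = sub$doy, hour = sub$hour,
                          value = sub$value)
    member_series(data.frame(year = wide$year, doy = wide$doy, ta = wide$ta,
                             hum = wide[[hkind]],
                             P = if ("P" %in% names(wide)) wide$P else NA_real_),
                  model_id = g$model_id[1], scenario = g$scenario[1],
                  run_id = g$run_id[1], lat = g$lat[1], lon = g$lon[1],
                  humidity_kind = hkind, p_subdaily = p_sub)
  })
}

#' Write a chamber program to CSV
#' @param program a `chamber_program`
#' @param path hourly CSV path; if a minute trajectory exists it is written
#'   to `<path>.minute.csv`
#' @export
write_program_csv <- function(program, path) {
  data.table::fwrite(program$hourly, path)
  if (!is.null(program$minute))
    data.table::fwrite(program$minute, paste0(path, ".minute.csv"))
  invisible(path)
}
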