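#' Hourly station records
#'
#' An `station_record` is a data frame of strictly increasing hourly
#' timestamps carrying one column per meteorological variable and one
#' quality-control flag column (`qc_<var>`, values `"observed"`, `"filled"`
#' or `"invalid"`) per variable.  Invalid cells hold `NA`; after gap filling
#' no cell is `NA` and every reconstructed cell is flagged `"filled"`.
#'
#' Canonical variable names and units are `ta` (air temperature, degC),
#' `rh` (relative humidity, %), `P` (air pressure, hPa), `rg` (global
#' radiation, W m-2), `o3` (ozone, ppb) and `co2` (ppm).  Timestamps are
#' timezone-naive local standard time (stored as UTC) marking the start of
#' the averaging hour.
#'
#' @param df data frame with columns `timestamp` (POSIXct) and the variables
#' @param vars character vector of variable names present
#' @return an object of class `station_record`
#' @export
station_record <- function(df, vars) {
  stopifnot(is.data.frame(df), "timestamp" %in% names(df))
  missing_vars <- setdiff(vars, names(df))
  if (length(missing_vars))
    stopf("station_record: missing variable column(s): %s",
          paste(missing_vars, collapse = ", "))
  df <- as.data.frame(df)
  ts <- df$timestamp
  if (anyDuplicated(ts))
    stopf("station_record: duplicate timestamps (first at %s)",
          format(ts[anyDuplicated(ts)], "%Y-%m-%d %H:%M"))
  df <- df[order(ts), , drop = FALSE]
  lt <- as.POSIXlt(df$timestamp, tz = "UTC")
  df$year <- lt$year + 1900L
  df$month <- lt$mon + 1L
  df$mday <- lt$mday
  df$hour <- lt$hour
  df$doy <- std_doy(df$month, df$mday)
  for (v in vars) {
    qc <- paste0("qc_", v)
    if (!qc %in% names(df))
      df[[qc]] <- ifelse(is.na(df[[v]]), "invalid", "observed")
  }
  rownames(df) <- NULL
  structure(df, vars = vars, class = c("station_record", "data.frame"))
}

record_vars <- function(record) attr(record, "vars")

#' @export
print.station_record <- function(x, ...) {
  cat(sprintf("<station_record> %d hours, %s .. %s\n", nrow(x),
              format(x$timestamp[1], "%Y-%m-%d %H:%M"),
              format(x$timestamp[nrow(x)], "%Y-%m-%d %H:%M")))
  cat("  variables:", paste(record_vars(x), collapse = ", "), "\n")
  flags <- unlist(lapply(record_vars(x), function(v) x[[paste0("qc_", v)]]))
  tab <- table(factor(flags, levels = c("observed", "filled", "invalid")))
  cat(sprintf("  cells: %d observed, %d filled, %d invalid\n",
              tab[["observed"]], tab[["filled"]], tab[["invalid"]]))
  invisible(x)
}

# Unit spellings accepted per canonical variable; readers reject anything else.
.canonical_units <- list(
  ta = c("C", "degC", "°C"),
  rh = c("%", "pct", "percent"),
  P = c("hPa", "mbar"),
  rg = c("W/m2", "Wm-2", "W m-2"),
  o3 = c("ppb"),
  co2 = c("ppm")
)

#' Read an hourly station record from CSV
#'
#' Reads a header CSV with ISO-8601 timestamps, renames columns to the
#' canonical variable set via `format_spec`, sorts, and regularizes the
#' series to a strict hourly grid: missing hours are inserted with `NA`
#' values flagged `"invalid"`.
#'
#' @param path CSV file path
#' @param format_spec list with elements `timestamp` (timestamp column
#'   name), `columns` (named character vector mapping canonical name ->
#'   file column name) and optionally `units` (named vector of unit strings
#'   per canonical name; unknown units are a hard error)
#' @return a [station_record()]
#' @export
read_station_record <- function(path, format_spec) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  stopifnot(is.list(format_spec), !is.null(format_spec$columns))
  ts_col <- format_spec$timestamp %||% "timestamp"
  raw <- data.table::fread(path, data.table = FALSE)
  if (!ts_col %in% names(raw))
    stopf("timestamp column '%s' not found in %s", ts_col, path)
  cols <- format_spec$columns
  for (v in names(cols)) {
    if (!cols[[v]] %in% names(raw))
      stopf("column '%s' (variable %s) not found in %s", cols[[v]], v, path)
  }
  units <- format_spec$units
  if (!is.null(units)) {
    for (v in names(units)) {
      ok <- .canonical_units[[v]]
      if (is.null(ok) || !(units[[v]] %in% ok))
        stopf("unknown unit '%s' for variable %s", units[[v]], v)
    }
  }
  ts_raw <- raw[[ts_col]]
  if (inherits(ts_raw, "POSIXct")) {
    ts <- as.POSIXct(format(ts_raw, tz = "UTC"), tz = "UTC")
  } else {
    ts_chr <- as.character(ts_raw)
    fmts <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
              "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")
    parsed <- lapply(fmts, function(f) as.POSIXct(strptime(ts_chr, f, tz = "UTC")))
    ts <- parsed[[which.max(vapply(parsed, function(p) sum(!is.na(p)), 0))]]
    if (anyNA(ts)) {
      bad <- which(is.na(ts))[1]
      stopf("unparseable timestamp at data row %d: '%s'", bad, ts_chr[bad])
    }
  }
  df <- data.frame(timestamp = ts)
  for (v in names(cols)) df[[v]] <- as.numeric(raw[[cols[[v]]]])
  df <- df[order(df$timestamp), , drop = FALSE]
  full <- seq(df$timestamp[1], df$timestamp[nrow(df)], by = "hour")
  if (length(full) != nrow(df) || !all(df$timestamp == full)) {
    idx <- match(as.numeric(full), as.numeric(df$timestamp))
    out <- data.frame(timestamp = full)
    for (v in names(cols)) out[[v]] <- df[[v]][idx]
    df <- out
  }
  station_record(df, vars = names(cols))
}

#' Write a station record to CSV (lossless numeric round trip)
#'
#' @param record a [station_record()]
#' @param path output file
#' @param flags write the `qc_<var>` flag columns too
#' @export
write_station_csv <- function(record, path, flags = FALSE) {
  vars <- record_vars(record)
  out <- data.frame(timestamp = format(record$timestamp, "%Y-%m-%dT%H:%M:%S"))
  # 17 significant digits guarantee an exact double round trip through text
  for (v in vars) out[[v]] <- sprintf("%.17g", record[[v]])
  if (flags) for (v in vars) out[[paste0("qc_", v)]] <- record[[paste0("qc_", v)]]
  data.table::fwrite(out, path, quote = FALSE)
  invisible(path)
}

#' Default plausibility limits for quality control
#'
#' Per-variable `c(min, max, jump)` where `jump` is the maximum plausible
#' hour-to-hour change.  Radiation and CO2 jumps are unlimited by default
#' (both are legitimately spiky at this resolution).
#'
#' @return named list usable as the `limits` argument of [quality_control()]
#' @export
qc_limits <- function() {
  list(ta = c(-40, 45, 10),
       rh = c(0, 100, 60),
       P = c(850, 1080, 8),
       rg = c(0, 1200, Inf),
       o3 = c(0, 250, 75),
       co2 = c(250, 1500, Inf))
}

#' Flag implausible station values as invalid
#'
#' Applies a per-variable range check and a spike check: an interior value
#' whose jumps to both hourly neighbours exceed the jump limit with opposite
#' signs is flagged.  Flagged cells are set to `NA`.  The operation is
#' idempotent and always succeeds; the number of changes is attached as the
#' `qc_report` attribute (and retrievable with `attr(x, "qc_report")`).
#'
#' @param record a [station_record()]
#' @param limits list as returned by [qc_limits()]
#' @return the flagged record
#' @export
quality_control <- function(record, limits = qc_limits()) {
  vars <- record_vars(record)
  report <- list()
  for (v in vars) {
    lim <- limits[[v]]
    if (is.null(lim)) { report[[v]] <- c(range = 0L, spike = 0L); next }
    x <- record[[v]]
    bad_range <- !is.na(x) & (x < lim[1] | x > lim[2])
    x[bad_range] <- NA
    bad_spike <- rep(FALSE, length(x))
    if (is.finite(lim[3]) && length(x) > 2) {
      d_prev <- c(NA, diff(x))
      d_next <- c(diff(x), NA)
      bad_spike <- !is.na(d_prev) & !is.na(d_next) &
        abs(d_prev) > lim[3] & abs(d_next) > lim[3] & d_prev * d_next < 0
      x[bad_spike] <- NA
    }
    qc <- record[[paste0("qc_", v)]]
    qc[bad_range | bad_spike] <- "invalid"
    record[[v]] <- x
    record[[paste0("qc_", v)]] <- qc
    report[[v]] <- c(range = sum(bad_range), spike = sum(bad_spike))
  }
  attr(record, "qc_report") <- report
  record
}

#' Fill gaps in a station record
#'
#' Gaps up to `max_gap` hours with valid anchors on both sides are linearly
#' interpolated; longer gaps (and edge gaps) are filled with the per
#' calendar-hour climatology (mean over all years of the valid values at the
#' same month/day/hour).  Every filled cell is flagged `"filled"`; cells
#' flagged `"observed"` are never modified.
#'
#' @param record a [station_record()]
#' @param max_gap longest gap (hours) filled by linear interpolation
#' @return record without missing cells
#' @export
fill_gaps <- function(record, max_gap = 6) {
  vars <- record_vars(record)
  n <- nrow(record)
  key <- record$month * 10000L + record$mday * 100L + record$hour
  for (v in vars) {
    x <- record[[v]]
    if (all(is.na(x))) stopf("fill_gaps: variable '%s' is entirely missing", v)
    if (!anyNA(x)) next
    was_na <- is.na(x)
    filled <- x
    # linear fill for short interior gaps
    runs <- true_runs(was_na)
    for (i in seq_along(runs$start)) {
      s <- runs$start[i]; len <- runs$length[i]; e <- s + len - 1L
      if (len <= max_gap && s > 1L && e < n) {
        filled[s:e] <- x[s - 1L] + (x[e + 1L] - x[s - 1L]) *
          seq_len(len) / (len + 1L)
      }
    }
    # climatological fill for whatever remains
    still <- is.na(filled)
    if (any(still)) {
      clim <- tapply(x, key, mean, na.rm = TRUE)
      filled[still] <- clim[as.character(key[still])]
    }
    # last resort (calendar hour missing in every year): interpolate/extend
    if (anyNA(filled)) {
      ok <- which(!is.na(filled))
      filled <- stats::approx(ok, filled[ok], xout = seq_len(n),
                              rule = 2)$y
    }
    qc <- record[[paste0("qc_", v)]]
    qc[was_na] <- "filled"
    record[[v]] <- filled
    record[[paste0("qc_", v)]] <- qc
  }
  record
}

#' Remove leap days to obtain the 365-day standard calendar
#'
#' Every February 29 is dropped so each complete year has exactly 8,760
#' hours; the standard day-of-year column is recomputed.  Idempotent.
#'
#' @param record a [station_record()]
#' @return leap-free record
#' @export
to_standard_calendar <- function(record) {
  keep <- !(record$month == 2L & record$mday == 29L)
  out <- record[keep, , drop = FALSE]
  out$doy <- std_doy(out$month, out$mday)
  rownames(out) <- NULL
  attr(out, "vars") <- record_vars(record)
  class(out) <- class(record)
  out
}

#' Aggregate a standard-calendar hourly record to daily resolution
#'
#' Computes the per-day mean of every variable plus `tmin`/`tmax`/`tmean`
#' from the 24 hourly air temperatures.  Requires a gap-free record on the
#' standard calendar (filling must precede aggregation).
#'
#' @param record a filled, standard-calendar [station_record()]
#' @return a `daily_record` data frame (one row per year x day-of-year)
#' @export
daily_aggregate <- function(record) {
  vars <- record_vars(record)
  if (anyNA(record$doy))
    stopf("daily_aggregate: record contains leap days; apply to_standard_calendar() first")
  for (v in vars)
    if (anyNA(record[[v]]))
      stopf("daily_aggregate: variable '%s' has missing cells; apply fill_gaps() first", v)
  dt <- data.table::as.data.table(record[, c("year", "doy", vars)])
  agg <- dt[, lapply(.SD, mean), by = c("year", "doy"), .SDcols = vars]
  if ("ta" %in% vars) {
    ext <- dt[, list(tmin = min(ta), tmax = max(ta), tmean = mean(ta)),
              by = c("year", "doy")]
    agg <- merge(agg, ext, by = c("year", "doy"), sort = TRUE)
  }
  out <- as.data.frame(agg[order(year, doy)])
  structure(out, vars = vars, class = c("daily_record", "data.frame"))
}

#' Complete standard-calendar years of a daily record
#' @noRd
complete_years <- function(daily) {
  tab <- table(daily$year)
  as.integer(names(tab)[tab == 365L])
}
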