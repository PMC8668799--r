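# Shared fixtures, generated once per test run and memoised.  The "full"
# world is the frozen 30-year default config (seed 1) used by the
# acceptance criteria; the "small" world is a scaled-down 4-year record
# for cheap unit tests.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

full_cfg <- function() fixture_config(seed = 1)

full_record_raw <- function() memo("full_record_raw",
                                   gen_station_record(full_cfg()))

full_record <- function() memo(
  "full_record",
  to_standard_calendar(fill_gaps(quality_control(full_record_raw()))))

full_daily <- function() memo("full_daily", daily_aggregate(full_record()))

full_co2 <- function() memo("full_co2",
                            to_standard_calendar(gen_co2_record(full_cfg())))

full_try_pc <- function() memo("full_try_pc",
                               build_try(full_record(), full_co2(),
                                         scenario = "pc"))

small_cfg <- function() fixture_config(seed = 42, years = 4)

small_record <- function() memo(
  "small_record",
  to_standard_calendar(fill_gaps(quality_control(
    gen_station_record(small_cfg())))))

small_daily <- function() memo("small_daily", daily_aggregate(small_record()))

# Tiny mock ensemble: 3 members, 2x2 grid, short periods.  Covers the
# q-humidity, sub-daily-pressure and multi-run paths (members 2, 3, 1).
tiny_ens_cfg <- function(...) {
  fixture_config(seed = 11, years = 6, n_members = 3, grid_dim = 2,
                 shifted_member = 3, q_member = 2, subdaily_p_member = 3,
                 multirun_member = 1, n_runs = 2, split_year = 1990L,
                 fc_years = c(2071L, 2076L), ...)
}

tiny_ensemble <- function() memo("tiny_ensemble", gen_ensemble(tiny_ens_cfg()))

tiny_signal <- function(scenario = "rcp85") {
  memo(paste0("tiny_signal_", scenario),
       build_ensemble_signal(tiny_ensemble(), scenario,
                             ref_years = c(1987L, 1992L), split_year = 1990L,
                             fc_years = c(2071L, 2076L)))
}

# A constant synthetic daily record: `years` years in which every variable
# is flat (per-year offsets optional), handy for hand-checkable scoring.
flat_daily <- function(years, ta = 10, rh = 70, rg = 100, offsets = 0) {
  offsets <- rep_len(offsets, length(years))
  do.call(rbind, lapply(seq_along(years), function(i) {
    data.frame(year = years[i], doy = 1:365,
               ta = ta + offsets[i], rh = rh + offsets[i],
               P = 956, rg = rg + offsets[i],
               tmin = ta + offsets[i], tmax = ta + offsets[i],
               tmean = ta + offsets[i])
  }))
}

flat_rc <- function(ta = 10, rh = 70, rg = 100, sd_ta = 0) {
  structure(data.frame(doy = 1:365, ta = ta, rh = rh, rg = rg,
                       sd_ta = sd_ta),
            scenario = "pc", class = c("ref_climatology", "data.frame"))
}

constant_signal <- function(delta_ta, delta_rh = 0, scenario = "rcp85") {
  structure(data.frame(doy = 1:365, delta_ta = delta_ta,
                       delta_rh = delta_rh),
            scenario = scenario, class = c("climate_signal", "data.frame"))
}
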