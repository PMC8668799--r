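test_that("reference_climatology reproduces brute-force per-day statistics", {
  base <- flat_daily(2000L)
  two <- rbind(base, transform(base, year = 2001L))
  rc <- reference_climatology(structure(two, class = c("daily_record",
                                                       "data.frame")))
  expect_equal(rc$sd_ta, rep(0, 365))        # identical years -> SD 0

  # years at x-1 and x+1 -> mean x, SD sqrt(2)
  pm <- flat_daily(2000:2001, ta = 10, offsets = c(-1, 1))
  rc2 <- reference_climatology(structure(pm, class = c("daily_record",
                                                       "data.frame")),
                               smooth = FALSE)
  expect_equal(rc2$ta, rep(10, 365))
  expect_equal(rc2$sd_ta, rep(sqrt(2), 365))

  daily <- small_daily()
  rc3 <- reference_climatology(daily, smooth = FALSE)
  years <- unique(daily$year)
  m <- matrix(daily$tmean[order(daily$year, daily$doy)], nrow = 365)
  expect_equal(rc3$ta, rowMeans(m), tolerance = 1e-12)
  expect_equal(rc3$sd_ta, apply(m, 1, sd), tolerance = 1e-12)

  expect_error(reference_climatology(structure(base,
                                               class = c("daily_record", "data.frame"))),
               "at least 2")
})

test_that("apply_signal shifts additively and clips humidity", {
  rc <- flat_rc(ta = 10, rh = 99)
  expect_equal(apply_signal(rc, constant_signal(0))$ta, rc$ta)
  shifted <- apply_signal(rc, constant_signal(3.3))
  expect_equal(shifted$ta, rc$ta + 3.3)
  expect_equal(shifted$rg, rc$rg)            # radiation untouched
  clipped <- apply_signal(rc, constant_signal(0, delta_rh = 5))
  expect_equal(clipped$rh, rep(100, 365))
  expect_equal(attr(clipped, "n_clipped"), 365L)
})

test_that("enumerate_candidates counts and tail mode match the contract", {
  expect_equal(nrow(enumerate_candidates(1987:2016, 1)), 630L)
  expect_equal(nrow(enumerate_candidates(2000L, 1)), 21L)
  tail_mode <- enumerate_candidates(1987:2016, 360)
  expect_true(all(tail_mode$length == 6L))   # 6 days remain: tail segments
  expect_equal(nrow(tail_mode), 30L)
  trunc <- enumerate_candidates(2000L, 350)  # 16 days remain: lengths 10..16
  expect_equal(sort(trunc$length), 10:16)
})

test_that("score_segments matches a hand-built ranking table", {
  # three one-year "candidates" with known criterion values against a flat
  # target: year A matches exactly, B is off in ta only, C off in rh only
  daily <- rbind(flat_daily(2000L, ta = 10, rh = 70, rg = 100),
                 flat_daily(2001L, ta = 12, rh = 70, rg = 100),
                 flat_daily(2002L, ta = 10, rh = 75, rg = 100))
  rc <- flat_rc(ta = 10, rh = 70, rg = 100, sd_ta = 0)
  cand <- data.frame(year = 2000:2002, start_doy = 1L, length = 10L)
  sc <- score_segments(cand, rc, structure(daily, class = c("daily_record",
                                                            "data.frame")))
  # ranks: ta-diff -> A,C tie 0, B 2; rh-diff -> A,B tie 0, C 2;
  # sd and rg tie at 0 for all
  expect_equal(sc$total_score[sc$year == 2000], 0)
  expect_equal(sc$total_score[sc$year == 2001], 0.3 * 2)
  expect_equal(sc$total_score[sc$year == 2002], 1.0 * 2)

  expect_error(score_segments(cand[0, ], rc, daily), "empty")
  one <- score_segments(cand[1, ], rc,
                        structure(daily, class = c("daily_record", "data.frame")))
  expect_equal(one$total_score, 0)           # single candidate: all ranks 0
})

test_that("continuity criterion enters for non-first segments", {
  daily <- rbind(flat_daily(2000L, ta = 10), flat_daily(2001L, ta = 14))
  rc <- flat_rc(ta = 12)
  cand <- enumerate_candidates(2000:2001, 50, 10, 10)
  no_prev <- score_segments(cand, rc, structure(daily, class = c("daily_record", "data.frame")))
  expect_equal(no_prev$total_score, c(0, 0))  # symmetric without continuity
  with_prev <- score_segments(cand, rc,
                              structure(daily, class = c("daily_record", "data.frame")),
                              prev_mean_ta = 14)
  expect_gt(with_prev$total_score[with_prev$year == 2000],
            with_prev$total_score[with_prev$year == 2001])
})

test_that("a record year equal to the climatology is always selected", {
  set.seed(10)
  curve <- 10 + 8 * cos(2 * pi * (1:365 - 196) / 365)
  match_year <- data.frame(year = 2000L, doy = 1:365, ta = curve,
                           rh = 70 + curve / 10, P = 956, rg = 100 + curve,
                           tmin = curve, tmax = curve, tmean = curve)
  off_year <- transform(match_year, year = 2001L, ta = ta + 4,
                        tmean = tmean + 4, tmin = tmin + 4, tmax = tmax + 4,
                        rh = rh - 5, rg = rg + 30)
  daily <- structure(rbind(match_year, off_year),
                     class = c("daily_record", "data.frame"))
  rc <- structure(data.frame(doy = 1:365, ta = curve, rh = 70 + curve / 10,
                             rg = 100 + curve, sd_ta = 0),
                  scenario = "pc", class = c("ref_climatology", "data.frame"))
  w <- score_weights(); w$continuity <- 0
  plan <- select_segments(daily, rc, config = list(weights = w))
  expect_true(all(plan$source_year == 2000L))
  expect_equal(sum(plan$length_days), 365L)
})

test_that("identical record years give a deterministic tie-broken plan", {
  one <- flat_daily(2000L, ta = 10)
  daily <- structure(rbind(one, transform(one, year = 2001L)),
                     class = c("daily_record", "data.frame"))
  rc <- flat_rc(ta = 10)
  p1 <- select_segments(daily, rc)
  p2 <- select_segments(daily, rc)
  expect_identical(p1, p2)
  expect_true(all(p1$source_year == 2000L))  # earliest year wins ties
  expect_true(all(p1$length_days[-nrow(p1)] == 10L))  # shortest length wins
})

test_that("select_segments equals the brute-force oracle on toy records", {
  for (seed in c(21L, 22L)) {
    cfg <- fixture_config(seed = seed, years = 3)
    rec <- to_standard_calendar(fill_gaps(quality_control(
      gen_station_record(cfg))))
    daily <- daily_aggregate(rec)
    rc <- reference_climatology(daily)
    for (sig in list(NULL, constant_signal(2, -2))) {
      target <- if (is.null(sig)) rc else apply_signal(rc, sig)
      got <- select_segments(daily, target)
      want <- oracle_select(daily, target)
      expect_equal(got$source_year, want$source_year)
      expect_equal(got$start_doy, want$start_doy)
      expect_equal(got$length_days, want$length_days)
      expect_equal(got$total_score, want$total_score, tolerance = 1e-9)
    }
  }
})

test_that("assemble_hourly copies source hours verbatim", {
  rec <- small_record()
  plan <- structure(data.frame(segment = 1L, source_year = 1988L,
                               start_doy = 1L, length_days = 365L,
                               total_score = 0),
                    weights = score_weights(),
                    class = c("segment_plan", "data.frame"))
  try1 <- assemble_hourly(rec, plan)
  src <- rec[rec$year == 1988L, ]
  expect_equal(try1$ta, src$ta)
  expect_equal(try1$o3, src$o3)

  plan2 <- structure(data.frame(segment = 1:2, source_year = c(1987L, 1989L),
                                start_doy = c(1L, 101L),
                                length_days = c(100L, 265L),
                                total_score = 0),
                     weights = score_weights(),
                     class = c("segment_plan", "data.frame"))
  try2 <- assemble_hourly(rec, plan2)
  for (i in c(1L, 1200L, 2400L)) {          # spot-check against oracle lookup
    row <- try2[i, ]
    y <- plan2$source_year[row$segment_id]
    src_val <- rec$ta[rec$year == y & rec$doy == row$doy & rec$hour == row$hour]
    expect_equal(row$ta, src_val)
  }
  expect_error(assemble_hourly(rec, transform(plan, source_year = 1950L)),
               "missing")
})

test_that("smooth_transitions draws straight lines and spares radiation", {
  rec <- small_record()
  plan <- structure(data.frame(segment = 1:2, source_year = c(1987L, 1989L),
                               start_doy = c(1L, 101L),
                               length_days = c(100L, 265L),
                               total_score = 0),
                    weights = score_weights(),
                    class = c("segment_plan", "data.frame"))
  raw <- assemble_hourly(rec, plan)
  sm <- smooth_transitions(raw)
  b <- 100L * 24L + 1L                      # first hour of segment 2
  a <- b - 8L; z <- b + 8L
  k <- 1:15
  for (v in c("ta", "rh", "P", "o3"))
    expect_equal(sm[[v]][a + k],
                 raw[[v]][a] + (raw[[v]][z] - raw[[v]][a]) * k / 16,
                 tolerance = 1e-12)
  expect_equal(sm$rg, raw$rg)               # rg excluded by contract
  expect_equal(sm$ta[-(a + k)], raw$ta[-(a + k)])
  expect_true(all(sm$interpolated[a + k]))
  expect_equal(sum(sm$interpolated), 15L)

  # synthetic line: anchors 10 and 26 -> increments of exactly 1
  raw2 <- raw
  raw2$ta <- rep(0, 8760); raw2$ta[a] <- 10; raw2$ta[z] <- 26
  sm2 <- smooth_transitions(raw2)
  expect_equal(sm2$ta[a:z], seq(10, 26, by = 1))
  # equal anchors -> constant window
  raw3 <- raw; raw3$ta[a] <- 5; raw3$ta[z] <- 5
  expect_equal(smooth_transitions(raw3)$ta[a:z], rep(5, 17))
})

test_that("adjust_o3_scenario and build_co2_series hit target means exactly", {
  set.seed(30)
  o3 <- runif(8760, 5, 60)
  o3 <- o3 / mean(o3) * 29                  # annual mean 29 ppb
  adj <- adjust_o3_scenario(o3, longterm_mean = 30, factor = 0.75)
  expect_equal(mean(adj), 22.5, tolerance = 1e-9)
  expect_equal(unique(round(adj / o3, 12)), round(22.5 / 29, 12))  # pure scaling
  expect_equal(adjust_o3_scenario(o3, mean(o3), 1), o3, tolerance = 1e-12)
  expect_error(adjust_o3_scenario(rep(0, 10), 30, 1), "non-positive")

  co2 <- full_co2()
  s375 <- build_co2_series(co2, 375)
  s936 <- build_co2_series(co2, 936)
  expect_equal(mean(s375), 375, tolerance = 1e-9)
  expect_equal(mean(s936), 936, tolerance = 1e-9)
  expect_equal(s936 / 936, s375 / 375, tolerance = 1e-12)  # shape preserved

  const <- station_record(
    data.frame(timestamp = seq(as.POSIXct("2001-01-01 00:00", tz = "UTC"),
                               by = "hour", length.out = 8760),
               co2 = 400), vars = "co2")
  expect_equal(build_co2_series(to_standard_calendar(const), 936),
               rep(936, 8760))
})

test_that("build_try produces a valid, deterministic present-climate TRY", {
  try_pc <- full_try_pc()
  rec <- full_record()
  daily <- full_daily()
  plan <- attr(try_pc, "plan")

  # tiling invariant
  expect_equal(sum(plan$length_days), 365L)
  expect_true(all(plan$length_days[-nrow(plan)] >= 10L &
                    plan$length_days[-nrow(plan)] <= 30L))
  expect_true(all(plan$source_year %in% unique(daily$year)))

  # PC annual means within 1.5 SD-of-annual-means of the record means
  for (v in c("ta", "rh", "rg")) {
    ann <- tapply(rec[[v]], rec$year, mean)
    expect_lt(abs(mean(try_pc[[v]]) - mean(rec[[v]])), 1.5 * sd(ann))
  }

  # range containment (verbatim copies plus convex interpolation)
  for (v in c("ta", "rh", "P", "o3")) {
    expect_gte(min(try_pc[[v]]), min(rec[[v]]))
    expect_lte(max(try_pc[[v]]), max(rec[[v]]))
  }

  # determinism: identical inputs -> bit-identical TRY
  again <- build_try(full_record(), full_co2(), scenario = "pc")
  expect_identical(as.data.frame(again), as.data.frame(try_pc))
})

test_that("a warming signal shifts the TRY toward (but within) the signal", {
  cfg <- full_cfg()
  sig <- constant_signal(cfg$delta$rcp85$ta, cfg$delta$rcp85$rh)
  try_85 <- build_try(full_record(), full_co2(), signal = sig,
                      scenario = "rcp85")
  try_pc <- full_try_pc()
  shift <- mean(try_85$ta) - mean(try_pc$ta)
  # The rank-sum selection recovers only part of the prescribed mean shift:
  # the mean-ta criterion carries weight 0.3 of 3.7 and the SD/radiation/
  # continuity criteria are warmth-neutral, so the greedy compromise lands
  # well short of the full +3.3 (see the methods vignette).  Assert the
  # honest structural property: a positive shift bounded by the signal.
  expect_gt(shift, 0)
  expect_lt(shift, max(sig$delta_ta))
  expect_lt(mean(try_85$rh), mean(try_pc$rh))  # drier, consistent with signal
  # resampled variables still within the historical range
  rec <- full_record()
  for (v in c("ta", "rh", "P")) {
    expect_gte(min(try_85[[v]]), min(rec[[v]]))
    expect_lte(max(try_85[[v]]), max(rec[[v]]))
  }
  # scenario gas targets
  expect_equal(mean(try_85$o3), mean(rec$o3) * 1.115, tolerance = 1e-9)
  expect_equal(mean(try_85$co2), 936, tolerance = 1e-9)
  expect_error(build_try(full_record(), full_co2(), scenario = "rcp85"),
               "requires a climate signal")
})
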