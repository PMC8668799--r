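# Independent brute-force re-implementation of the segment scoring and
# greedy selection, used only as a test oracle.  Plain loops over data
# frames; no prefix sums, no shared code with the package internals.

oracle_segment_stats <- function(daily, year, s, L) {
  d <- daily[daily$year == year & daily$doy >= s & daily$doy <= s + L - 1L, ]
  list(mean_ta = mean(d$tmean),
       sd_ta = if (L > 1) stats::sd(d$tmean) else 0,
       mean_rh = mean(d$rh), mean_rg = mean(d$rg))
}

oracle_target_stats <- function(rc, s, L) {
  w <- rc[rc$doy >= s & rc$doy <= s + L - 1L, ]
  list(mean_ta = mean(w$ta), sd_ta = mean(w$sd_ta),
       mean_rh = mean(w$rh), mean_rg = mean(w$rg))
}

oracle_score <- function(daily, rc, years, s, min_len, max_len,
                         prev_mean_ta, weights) {
  remaining <- 365L - s + 1L
  lens <- if (remaining < min_len) remaining
          else seq.int(min_len, min(max_len, remaining))
  grid <- expand.grid(year = years, length = lens, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$year, grid$length), ]
  diffs <- t(vapply(seq_len(nrow(grid)), function(i) {
    cs <- oracle_segment_stats(daily, grid$year[i], s, grid$length[i])
    ts <- oracle_target_stats(rc, s, grid$length[i])
    c(d_ta = abs(cs$mean_ta - ts$mean_ta),
      d_sd = abs(cs$sd_ta - ts$sd_ta),
      d_rh = abs(cs$mean_rh - ts$mean_rh),
      d_rg = abs(cs$mean_rg - ts$mean_rg),
      d_ct = if (is.null(prev_mean_ta)) NA_real_
             else abs(cs$mean_ta - prev_mean_ta),
      mean_ta = cs$mean_ta)
  }, numeric(6)))
  rk <- function(x) rank(x, ties.method = "min") - 1L
  total <- weights$mean_ta * rk(diffs[, "d_ta"]) +
    weights$sd_ta * rk(diffs[, "d_sd"]) +
    weights$mean_rh * rk(diffs[, "d_rh"]) +
    weights$mean_rg * rk(diffs[, "d_rg"])
  if (!is.null(prev_mean_ta))
    total <- total + weights$continuity * rk(diffs[, "d_ct"])
  cbind(grid, total = total, d_ta = diffs[, "d_ta"],
        mean_ta = diffs[, "mean_ta"])
}

oracle_select <- function(daily, rc, min_len = 10L, max_len = 30L,
                          weights = score_weights()) {
  years <- sort(unique(daily$year[table(daily$year)[as.character(daily$year)] == 365L]))
  pos <- 1L
  prev <- NULL
  plan <- NULL
  while (pos <= 365L) {
    sc <- oracle_score(daily, rc, years, pos, min_len, max_len, prev, weights)
    sc <- sc[order(sc$total, sc$d_ta, sc$year, sc$length), ]
    best <- sc[1L, ]
    plan <- rbind(plan, data.frame(source_year = best$year, start_doy = pos,
                                   length_days = best$length,
                                   total_score = best$total))
    prev <- best$mean_ta
    pos <- pos + best$length
  }
  plan
}
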