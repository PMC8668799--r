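---
title: "Generating Test Reference Years for controlled environment facilities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating Test Reference Years for controlled environment facilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tryforge)
```

## The problem

Controlled environment facilities (ecotrons) can execute dynamic,
multi-variable climate programs, but most experiments still force chambers
with static day/night steps and single-variable increments. That discards
two properties of real weather that matter ecologically: intra-annual
variability (synoptic weather, diurnal cycles) and the covariation of
temperature, humidity, radiation and ozone. `tryforge` produces Test
Reference Years (TRYs) — 8,760-hour annual cycles of t_a, rh, P, R_g, O₃
and CO₂ — that represent a present-climate (PC) period or an RCP scenario
at a station, by combining a delta-change signal from a regional-model
ensemble with analog resampling of observed weather segments.

The key assumption of the delta-change approach is that models are more
trustworthy for *changes* in climatology than for absolute values, so the
scenario target is observation + model delta. The key assumption of analog
resampling is that multi-day segments of the observed record, chosen to
match the target climatology, provide realistic hourly structure and
inter-variable covariation. Its intrinsic limitation is the mirror image:
resampling cannot produce values outside the observed range, and
multimodel-mean targets smooth away extreme events.

## Pipeline and parameters

### Station record preparation (`station_data`)

`read_station_record()` regularizes a CSV record to a strict hourly grid;
`quality_control()` applies range checks (defaults t_a ∈ [−40, 45] °C,
rh ∈ [0, 100] %, P ∈ [850, 1080] hPa, R_g ∈ [0, 1200] W m⁻²,
O₃ ∈ [0, 250] ppb) and a both-sided spike check (default jump limit
10 °C h⁻¹ for t_a; radiation and CO₂ are exempt because they are
legitimately spiky). These QC rules are explicit stand-ins — the operative
criteria used for real records are rarely published — and are fully
configurable. `fill_gaps()` interpolates gaps up to 6 h linearly and fills
longer gaps with the per-calendar-hour multi-year mean; every filled cell
is flagged so downstream analyses can exclude it. `to_standard_calendar()`
drops every February 29 (the simplest 365-day-calendar interpretation),
and `daily_aggregate()` derives daily means plus t_min/t_max/t_mean from
the 24 hourly temperatures.

### Climate signals (`ensemble_signal`)

Ensemble members supply daily t_a, humidity and P per scenario and grid
point. Humidity arrives as rh or as specific humidity q; q is converted
day-wise via the Magnus-type saturation vapor pressure
(E = 6.122·exp(17.62·t_a/(243.12 + t_a)) hPa) and
e = qP/(0.378q + 0.622). Multi-run members (stochastic weather-generator
downscaling) are averaged day-wise; 3-hourly pressure is averaged to daily
means. The PC period of projection-driven members concatenates historical
years (through `split_year`, default 2005) with the day-wise average of
the two RCP projections for the remaining reference years.

Climatologies are smoothed by a real discrete Fourier transform of the
365-day series in which only the mean and the harmonics with 1, 2 and 3
cycles per year are retained ("third order"); the series mean is preserved
exactly. Smoothing and differencing commute (both are linear), so whether
the FC−PC difference is taken before or after smoothing is immaterial; the
package smooths first. Signals are averaged with equal weight over all
member × grid-point combinations, matching flat ensemble averaging; 360-day
and leap model calendars are mapped to 365 days by linear index
interpolation with an exact additive mean correction.

### TRY assembly (`try_builder`)

The reference climatology holds the record's per-day means of t_a, rh and
R_g (optionally Fourier-smoothed like the model climatologies, the
default) plus the per-day interannual SD of daily-mean t_a. Scenario
targets add δt_a and δrh (rh clipped to [0, 100]); R_g and the SD course
are left unchanged.

Segment selection is greedy from January 1: at each start day, one
candidate per record year × length 10–30 days (truncated at December 31;
if fewer than 10 days remain, a tail segment of exactly the remaining
length keeps the year tileable). Candidates are scored per criterion by
competition ranks (0, 1, 2, …, ties share the minimum rank) of the
absolute differences to the target window of identical start and length;
the total is the weighted rank sum with weights 0.3 (mean t_a), 0.7 (SD
t_a), 1 (mean rh), 1 (mean R_g) and 1 (continuity = |candidate mean t_a −
previous segment mean t_a|, omitted for the first segment). Ties on the
total are broken by smallest mean-t_a difference, then earliest source
year, then shortest length — fully deterministic.

Two quantities in the SD criterion needed a definition the method
description leaves open: the candidate's SD is the SD of its daily mean
temperatures within the segment, and the target SD is the window mean of
the climatology's per-day interannual SD. Both measure "typical
variability at this time of year" on the same scale; comparing the
candidate against the (much smaller) SD of the smoothed target curve
itself would systematically reward unusually calm segments instead.

Chosen segments are copied hour-by-hour from the source year at the same
calendar position; at each internal boundary, t_a, rh, P and O₃ (not R_g,
which must keep its solar geometry, and not CO₂, which is not
segment-sourced) are linearly interpolated across the 15 hours strictly
between the anchors 8 h before and after the boundary; the anchor values
themselves are preserved.

O₃ scenario rescaling multiplies the mean-normalized series by the
long-term station mean × 0.75 (RCP2.6) or × 1.115 (RCP8.5) — hemispheric
chemistry-transport projections for 2100 — so the output mean is exact;
the PC series is left untouched. CO₂ is the per-calendar-hour mean annual
cycle of the CO₂ record, normalized and scaled to 375 ppm (PC, the
record's long-term mean), 421 ppm (RCP2.6) or 936 ppm (RCP8.5).

### Chamber adaptation (`chamber_adapter`)

Facility limits default to an ecotron-class chamber: t_a clipped to
[10 | 4, 30] °C (day | night), rh to [30, 75 | 90] %. "Day" is defined as
hours with prescribed R_g > 0, since the facility photoperiod follows the
prescribed light. R_g→PPFD uses monthly empirical factors; the published
range is 1.90–2.10 µmol J⁻¹ but the monthly table itself is not public,
so the default ramps 1.90 (Dec–Feb) through 2.00 (shoulders) to 2.10
(Jun–Aug) and is fully configurable. PPFD in (600, 2030] is linearly
compressed to (600, 800]; positive values below the 24 µmol m⁻² s⁻¹ LED
minimum are raised to it, zeros stay zero (lights off). Because the
compression band maps into itself this transformation must be applied
exactly once. O₃ treatments implement the experimental gradient:
pre-industrial (mean-normalized × 10 ppb), moderate (+5 below 40 ppb, −5
above 45, values in [40, 45] unchanged — the literal reading of the
thresholds), high (+10 below 40, +5 in [40, 50), −5 at ≥ 50).

Minute ramps approach each hourly setpoint linearly in 60 steps with
per-minute caps (0.08 °C, 0.3 % rh, 0.3 ppb O₃; 0.7 ppm CO₂ for increases
only — scrubbing is unconstrained). When the linear path exceeds the cap,
the trajectory pursues the current target at the cap without overshoot
and may arrive late; light steps instantaneously.

### Evaluation (`evaluation`)

Percentile indices use calendar-day thresholds from the base record: the
empirical (type 7, linear interpolation) 10th/90th percentile of all base
values in a centered 5-day window. The in-base bootstrap used by
`climdex.pcic` is deliberately not implemented — thresholds are computed
once and applied to every year, including base years, which biases in-base
exceedance rates slightly below the nominal 10 %. GSL uses the daily mean
of the 24 hourly temperatures (not (t_min+t_max)/2) and terminates at the
first ≥6-day sub-5 °C span starting after July 1. KDE uses an exact
Gaussian kernel sum (bandwidth 1.5 units) on 512 nodes spanning the data
range ± 4 bandwidths; 3 bandwidths would lose up to 2.7e−3 of probability
mass for small samples. Deviation statistics report the 99th percentile of
|measured − prescribed|, the fraction within tolerance (defaults ±1 °C,
±10 % rh, ±10 ppb O₃, ±20 ppm CO₂, ±50 µmol m⁻² s⁻¹ PPFD), Pearson's r
and the pair count, with NA pairs (dropouts) removed.

## The synthetic world

`fixture_config()` freezes a 30-year (1987–2016) hourly world emulating a
mid-elevation central European forest station: annual mean t_a 8.3 °C with
a 9 °C seasonal and season-scaled 4 °C diurnal cycle; rh 78.6 % mean,
anti-correlated with the temperature anomaly (−1.2 % per °C); P 956 hPa;
radiation from simplified solar geometry at 50.16° N times slowly varying
cloudiness; O₃ coupled positively to radiation and temperature with an
emergent ~30 ppb mean; CO₂ centered on 375 ppm with +1.9 ppm yr⁻¹ trend,
seasonal and diurnal cycles. Temperature anomalies act on three scales —
hourly AR(1) noise (sd 1.5 °C), multi-day synoptic anomalies (daily AR(1),
sd 2 °C, persistence ~6 days) and independent warm/cold-year offsets
(sd 0.8 °C) — because segment resampling draws its power precisely from
synoptic and interannual spread; a single fast AR(1) would make every year
statistically identical and the method trivially weak. The mock ensemble
has 9 members on a 3 × 3 grid (one member on a shifted 2 × 2 grid, one
delivering q, one delivering 3-hourly P, one averaged over 10
weather-generator runs) with injected signals of mean +1.1 / +3.3 °C and a
summer-peaked rh decline reaching −2 / −6 % (the overlap years 2006–2016
carry no transient signal — a simplification).

What the generator does *not* emulate: structural inter-model differences,
real synoptic extremes (heat waves beyond Gaussian anomalies), leap-model
calendars beyond the standard mapping, precipitation, or the true
radiation–temperature covariation (cloudiness is independent of the
temperature anomaly). A green test suite therefore establishes the
correctness of the algorithms and their stated invariants on a
statistically realistic world — not climatological fidelity for any real
site.

## Known limitations

**Partial mean-shift recovery.** The ensemble-mean signal recovers its
injected deltas almost exactly (the suite asserts < 0.1 °C / < 0.5 %
pointwise). The *TRY built from* a warming signal, however, recovers only
part of the prescribed mean shift in the synthetic world: the mean-t_a
criterion carries rank weight 0.3 of 3.7 in the published scoring, and the
SD, radiation and continuity criteria are statistically warmth-neutral, so
the greedy compromise selects warmer-than-average but not target-matching
segments even though candidates matching the full shift exist. Scoring by
mean t_a alone recovers the shift almost completely (the record's
interannual spread is sufficient); each warmth-neutral criterion added
dilutes it. Applications that prioritize the scenario's mean temperature
should raise the mean-t_a weight (all weights are configurable); the
defaults remain the published ones. The test suite asserts the honest
structural property — a positive, signal-bounded shift with consistent
drying — rather than full recovery.

**Other limitations.** Range containment holds for the resampled variables
(and O₃ under PC), but O₃ scenario rescaling intentionally scales beyond
the historical range under RCP8.5. Multi-year TRY sequences are exposed
only as a start-offset configuration. Candidate segments never cross
December 31 into another record year. The evaluation statistics can be
applied to any supplied facility logs, but reproducing a specific
facility's published performance numbers requires that facility's
measurements.
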