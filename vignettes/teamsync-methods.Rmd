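---
title: "Methods: dyadic movement synchronization and time-motion analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dyadic movement synchronization and time-motion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teamsync)
```

## What the pipeline measures

`teamsync` quantifies two complementary aspects of a team's behaviour from
player tracking data sampled at 5 Hz:

* **Time-motion demands** — total distance covered per player per half, and
  distance split into four movement-intensity categories (km·h⁻¹): low
  [0, 3.6), moderate [3.6, 14.4), high [14.4, 19.8) and very high (≥ 19.8).
* **Intra-team movement synchronization** — for every unordered pair of
  outfield players (a *dyad*; 10 players give 45 dyads), the per-sample
  relative phase of their displacements along each pitch axis, and the
  percentage of time that relative phase lies in the *near-in-phase* band
  [−30°, 30°]. The percentage is reported for the whole half and stratified
  by the dyad's per-sample average speed, using the same intensity
  categories.

Dyads are then grouped by k-means into three synchronization-level clusters
per axis, and all outcomes are compared across the level of the opposing
team (first league, second league, amateur) with one-way ANOVAs (partial
η²), Fisher's LSD pairwise tests and Cohen's *d* with 95% confidence
intervals.

## Preprocessing model

Raw logs are per-player latitude/longitude samples with dropouts. The
pipeline:

1. **Synchronizes** all players of a match onto one uniform 5 Hz grid
   covering the *intersection* of their time coverage. The union is
   deliberately not used: dyadic statistics need simultaneous samples, and
   extrapolation is never performed. Interior gaps are filled by linear
   interpolation of each coordinate and flagged, so their influence is
   auditable. Linear filling is the simplest defensible choice at 5 Hz,
   where successive samples are 0.2 s apart and player acceleration bounds
   the interpolation error (the test suite checks the curvature bound
   explicitly).
2. **Projects** coordinates to metres with the standard WGS84 UTM
   transverse-Mercator projection (Karney–Krüger series through n⁶,
   sub-millimetre accuracy within a zone). A match straddling a zone
   boundary is an error rather than a silent re-projection, because planar
   distances across a seam are meaningless.
3. **Rotates** positions into the pitch frame. The pitch orientation θ is
   fitted from the four field vertices as the direction of the longer side
   pair, averaged on the doubled-angle circle and reduced mod 180°; the
   attacking direction is intentionally not encoded. A common axis flip
   applied to all players has no effect on any downstream statistic
   (distances and relative phase are invariant), so the sign ambiguity is
   harmless.
4. **Smooths** each axis with a zero-phase (forward–backward) second-order
   Butterworth low-pass filter, the de facto standard in movement science
   (effective fourth order, zero lag).

### The 3 Hz cutoff and the Nyquist limit

The nominal 3 Hz cutoff exceeds the 2.5 Hz Nyquist frequency of 5 Hz data
and is not realizable. The filter therefore clamps such cutoffs to
0.99 × Nyquist (2.475 Hz) and warns. This keeps the configured value as an
explicit parameter while producing a well-defined filter; at 2.475 Hz the
filter is nearly transparent for the ~0.05–0.1 Hz oscillations that carry
the phase information, so the choice of clamp policy has no practical
effect on the synchronization measures.

A near-Nyquist Butterworth has poles of radius ≈ 0.978, so edge transients
decay over hundreds of samples. The zero-phase implementation pads the
series by odd reflection until the slowest pole has decayed below 1e-9 and
starts each pass from steady-state initial conditions; a constant series
passes through bit-for-bit unchanged (DC gain 1), which the tests assert.

## Phase model

The instantaneous phase of a displacement series is the argument of its
analytic signal (discrete Hilbert transform via FFT), after removing the
series mean over the analysed half. No further detrending is applied by
default, mirroring the standard application of the technique to positional
oscillations; a configurable moving-average detrend is available because a
large slow team drift shifts the analytic signal's centre and can bias the
phase. The relative phase of a dyad is the per-sample wrapped difference of
the two players' phases, with the lexicographically smaller player id first
(swapping the order negates every sample; the symmetric band makes the
occupancy statistic order-invariant).

Band occupancy uses the closed interval [−30°, 30°]. Under independent
(uniform) phases the expected occupancy is 60/360 ≈ 16.7%, which is the
chance baseline against which synchronization percentages should be read.

**Dyad average speed** is interpreted per sample: the category of the
arithmetic mean of the two players' instantaneous speeds at that sample.
Match-level averaging would pin each dyad to a single category and could
not populate all categories within one half, whereas the stratified
percentages reported here are defined whenever a dyad spends any samples
in a category (an empty category yields a missing value with a zero
count). Because the categories partition the samples, the count-weighted
category percentages recombine exactly to the overall percentage — an
invariant the tests check.

Speeds are computed from the smoothed positions (filtering precedes
differentiation, since differentiating raw 5 Hz GPS amplifies noise), as
planar displacement per sample × rate, with the first sample replicating
the second so series lengths match. Category assignment is per sample; no
dwell-time minimum is imposed.

## Clustering and statistics

Each dyad contributes one feature per axis: its overall synchronization
percentage averaged over all matches. k-means (k = 3, 50 random restarts,
seeded) is run per axis; labels are mapped to higher/intermediate/lower by
descending centroid. On 1-D data of this size, restarted k-means attains
the global optimum — the tests verify equality with an exact
dynamic-programming clustering, which is kept as an oracle rather than the
production path. Fewer distinct values than k, or an empty cluster, is an
explicit error.

Comparisons across opposition levels use:

* one-way fixed-effects ANOVA; partial η² = SS_between / (SS_between +
  SS_within), identical to F·df_b / (F·df_b + df_w);
* Fisher's LSD: unadjusted pairwise t tests on the pooled error mean
  square with the ANOVA's error df;
* Cohen's d = (m_a − m_b)/s_pooled with
  se(d) = √((n_a+n_b)/(n_a n_b) + d²/(2(n_a+n_b−2))) and a 95% interval
  d ± 1.96·se (large-sample normal form).

The unit of analysis is dyad × match for synchronization outcomes
(45 × 6 = 270 observations; error df 267) and player × match for
time-motion outcomes (10 × 6 = 60; error df 57). **Caveat:** dyads and
players recur across matches, so these observations are not independent;
the layout reproduces the classical design this pipeline targets, and a
mixed-model re-analysis is deliberately out of scope. Pairwise contrasts
are ordered higher opposition level first, so positive effects mean
"greater against the stronger opponent".

## The synthetic-match generator

No tracking data ships with the package; the generator provides matches
with known ground truth so every stage is testable. Each player follows

x(t) = anchor_x + drift(t) + A_x sin(2π t / T_x + θ_x) + ε(t),
y(t) = anchor_y + A_y sin(2π t / T_y + θ_y) + ε(t),

with per-player phase offsets θ drawn from a von Mises distribution centred
at zero. The concentration κ per axis is the coupling dial: κ = 0 gives
independent phases (chance-level synchronization), large κ a team in
lockstep. A dyad's imposed phase difference is the wrapped difference of
the two offsets, recorded as ground truth. Paths are laid out on a pitch
rotated by a configurable angle, embedded in geographic coordinates by the
inverse of the preprocessing projection, and degraded by deleting a
configurable fraction of interior samples (endpoints always survive so
interpolation never extrapolates).

Default conditions (chosen once, as the study conditions the pipeline
emulates):

| parameter | default | rationale |
|---|---|---|
| players / duration / rate | 10, 2700 s, 5 Hz | one half, outfield team |
| amplitudes A_x, A_y | 15 m, 8 m | longitudinal dominance; speeds span all four categories |
| periods T_x, T_y | 20 s, 12 s | slow attack/defence sway vs faster lateral adjustment; combined peak speed crosses the very-high threshold |
| drift | 0.4 m·s⁻¹ triangular, 300 s period | bounded up-and-down-the-pitch team movement |
| noise | AR(1), sd 0.1 m, 1 s correlation | GPS error wanders slowly; white noise would inflate speeds unrealistically |
| gap fraction | 0.05 | typical dropout burden |
| κ presets | amateur 2, second league 6, first league 16 | encodes the design assumption that stronger opponents tighten coupling; overridable |

Formation anchors (4 defenders, 4 midfielders, 2 forwards) make the
cluster structure spatially interpretable but carry no phase information.

### What the generator does and does not emulate

It reproduces the statistical structure the pipeline measures: coupled
oscillatory displacement with controllable phase dispersion, realistic
speed ranges, GPS-like noise, dropouts, and an opposition-level effect by
construction. It is **not** a soccer model: there is no ball, no opponent
team, no tactical events, and the single-sinusoid-per-axis movement yields
total half distances (≈ 10–11 km in the default configuration) above
typical first-half values — a consequence of requiring sustained
oscillation that covers all four intensity categories. Passing tests
therefore demonstrate that the pipeline recovers imposed coordination
structure, not that real matches behave like the generator.

## Numerical choices and degenerate inputs

* Angles wrap to (−180°, 180°]; the in-phase band is closed on both ends.
* A constant (zero-variance) axis has no phase: explicit error.
* Empty speed-category masks yield missing percentages with zero counts.
* Zero total variance in an ANOVA, groups with fewer than two
  observations, zero pooled variance in d: explicit errors. The study
  driver skips degenerate outcomes rather than aborting a whole run.
* k-means ties are resolved by the seeded restarts; the exact DP optimum
  is the test reference.
* Phase accuracy tests exclude the first/last quarter of a series
  (analytic-signal edge effects); reported outputs use the whole half.

## Problem sizes used by the test suite

Unit tests run on 1–5 minute synthetic halves, where every property tested
is scale-free. The acceptance suite additionally runs the coupling-recovery
sweep (κ ∈ {0, 2, 8, 32}, 30 matches each, 9-minute halves) and one full
default study (six 45-minute halves); these sizes keep the whole suite in
the low minutes on one CPU while leaving every statistic's sampling noise
far below the margins being asserted.

## Known limitations

* Repeated dyads/matches are treated as independent observations (above).
* Linear interpolation understates curvature inside long gaps; gaps are
  flagged so sensitivity can be audited.
* The near-Nyquist clamp makes the nominal 3 Hz filter almost transparent;
  meaningful smoothing at 5 Hz requires a lower cutoff, available via
  `cutoff_hz`.
* Phase is meaningful for oscillatory displacement; for a player whose
  axis displacement is dominated by aperiodic drift, band occupancy is
  harder to interpret (the optional detrend mitigates but cannot remove
  this).
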