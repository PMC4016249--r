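# teamsync

Quantifying intra-team movement synchronization and time-motion demands
from player tracking data.

`teamsync` is an R package plus a scripted analysis workflow for sports
scientists working with GPS player tracking. From raw 5 Hz
latitude/longitude logs it computes, per match:

* **time-motion demands** — total distance per player and distance per
  movement-intensity category (low < 3.6, moderate 3.6–14.4, high
  14.4–19.8, very high ≥ 19.8 km·h⁻¹);
* **dyadic movement synchronization** — for each of the 45 unordered pairs
  of 10 outfield players and each pitch axis, the relative phase
  φ_a(t) − φ_b(t) of the two players' displacements (instantaneous phase
  from the analytic signal / Hilbert transform) and the percentage of time
  spent *near in-phase*, i.e. with relative phase in [−30°, 30°] — overall
  and stratified by the dyad's per-sample average speed category;
* **synchronization-level clusters** — k-means grouping of dyads into
  higher/intermediate/lower synchronization groups per axis;
* **opposition-level comparisons** — one-way ANOVA with partial η²,
  Fisher's LSD pairwise tests and Cohen's d (95% CI) across match
  categories (first league / second league / amateur opposition), with
  dyad × match and player × match observation layouts (error df 267 and
  57 for a 6-match, 3-level design).

Preprocessing follows standard tracking practice: synchronization of all
players onto a common 5 Hz time base (intersection of coverage), linear
filling of interior dropouts, UTM projection to metres, rotation into the
pitch-aligned frame fitted from the four field vertices, and zero-phase
Butterworth smoothing. Since no tracking data can be redistributed, the
package includes a synthetic-match generator — players as phase-coupled
oscillators with von Mises-distributed phase offsets (concentration κ per
axis), team drift, GPS-like AR(1) noise and dropouts — that provides
ground truth for every stage; see `vignette source in vignettes/` for the
model and its limits.

## Worked example

```r
library(teamsync)

cfg <- sim_config()                       # 10 players, 45-min half, 5 Hz
match <- generate_match(cfg, opposition_level = "first_league")
field <- generate_field_vertices(cfg)

traj <- preprocess_match(match$log, field, cutoff_hz = 3)
attr(traj, "theta_deg")                   # fitted pitch orientation
#> [1] 17

sync <- compute_dyad_sync(traj)           # 45 dyads x 2 axes x 5 categories
subset(sync, category == "overall" & axis == "x")[1:3, ]
```

Running the scripted study (`analysis/01` … `06`, six simulated matches,
two per opposition level) prints, among other tables:

```
Mean % time near-in-phase (overall), dyad x match observations:
 axis opposition_level  pct  n
    x          amateur 73.5 90
    x     first_league 96.8 90
    ...
Overall synchronization ANOVAs:
  x_overall : F(2, 267) = 54.46, p = 1.45e-20, eta2 = 0.290
  y_overall : F(2, 267) = 33.76, p = 8.48e-14, eta2 = 0.202
Headline effect sizes (first league vs amateur):
  x_overall: d = 1.20 [0.88, 1.51]
  y_overall: d = 1.28 [0.96, 1.60]
```

i.e. dyads of the simulated team spend more time near in-phase against the
stronger (more tightly coupled) opposition preset, on both the
longitudinal (x) and lateral (y) axes, with large positive effect sizes —
the qualitative pattern the pipeline is designed to detect. Chance-level
band occupancy for uncoupled players is 60/360 ≈ 16.7%.

## Analysis workflow

Numbered drivers under `analysis/` run the study end to end, writing all
tables under `results/`:

```sh
Rscript analysis/01_simulate.R       # raw position logs + ground truth
Rscript analysis/02_preprocess.R     # pitch-aligned smoothed trajectories
Rscript analysis/03_time_motion.R    # distances per intensity category
Rscript analysis/04_phase_sync.R     # dyadic near-in-phase percentages
Rscript analysis/05_cluster_dyads.R  # k-means synchronization groups
Rscript analysis/06_group_stats.R    # ANOVA / LSD / Cohen's d tables
```

`run_study()` performs the same pipeline in one call.

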