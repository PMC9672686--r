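---
title: "Cumulative pedestrian heat stress and walkable-route assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cumulative pedestrian heat stress and walkable-route assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatwalk)
```

## The model

Pedestrian thermal comfort during a walk is not a point-in-time property:
heat stress accumulates. **heatwalk** models a walk as an ordered sequence
of street segments, each summarized by its UTCI range (Universal Thermal
Climate Index, an equivalent temperature in °C that folds air temperature,
humidity, wind and radiation into one number). Three maps define the dose
model:

1. **Banding.** UTCI is banded into heat-stress levels
   $L_{HS} \in \{0, \dots, 4\}$ at breakpoints 26, 32, 38, 46 °C (no /
   moderate / strong / very strong / extreme heat stress). A segment whose
   UTCI range spans bands takes the level of its *maximum* UTCI — exposure
   is judged at the worst point of the street. A value exactly on a
   breakpoint maps to the higher level. Both are conservative choices: they
   can overstate, never understate, exposure.
2. **Dose.** Cumulative stress after segment $i$ is
   $S_t = \sum_{j \le i} L_{HS,j}\, t_j$ in *stress-minutes* — minutes
   weighted by level. Durations $t_j$ come from segment length at a walking
   speed (default 1 m/s) and are rounded **up** to a 0.1-minute quantum;
   up-rounding is the only rule consistent with treating the quantized
   duration as "time you cannot beat" (44.8 m at 1 m/s is 0.747 min,
   booked as 0.8).
3. **Budget.** The remaining tolerant heat discomfort is $R_t = H - S_t$
   against a tolerance budget $H$ (default 60 stress-minutes). At
   $R_t \le 0$ the pedestrian is expected to stop and rest. $R_t$ is the
   walkability currency throughout the package: higher is better.

Note the unit subtlety: $S_t$, $R_t$ and $H$ are stress-minutes
(level × minutes), not minutes. The two coincide only while walking at
level 1. We keep the distinction explicit in all documentation because a
60 stress-minute budget is exhausted in 15 minutes at level 4 but lasts
indefinitely at level 0.

```{r}
seg <- data.frame(
  segment_id = c("ab", "bc", "cd", "de", "ef", "fg", "gh"),
  utci_min   = c(34, 38, 33, 38, 37, 33, 32),
  utci_max   = c(36, 40, 34, 40, 40, 36, 36),
  length_m   = c(71.1, 171.7, 44.8, 51.0, 292.0, 12.0, 257.3))
evaluate_route(seg)
```

### Recovery

Stress-relief dynamics (alleviation while walking through cool, level-0
streets) are conceptually part of exposure physiology but are not
quantified by the applied model; `tolerance_params(recovery_rate = ...)`
exposes them as an explicit extension, defaulting to 0 (no recovery), in
which case $S_t$ is nondecreasing and $R_t$ nonincreasing along any route.
With a positive rate, level-0 segments credit `recovery_rate`
stress-minutes per minute and the running total is floored at zero.

## Route search

`best_tolerance_route()` finds, among simple paths between two nodes whose
total length fits a distance budget (default 900 m, the 15-minute walkshed
at 1 m/s), one maximizing terminal $R_t$. This is a resource-constrained
shortest-path problem: stress is the objective, distance the resource. The
search is Pareto label-setting over (stress, distance) states with
dominance pruning. Correctness of pruning under the simple-path restriction
follows from the cost structure: every edge has positive length and
non-negative stress, so deleting a cycle from a walk never worsens either
coordinate, and the Pareto frontier over walks equals the frontier over
simple paths. Ties in terminal $R_t$ break by shorter distance, then by
lexicographic node order, so results are deterministic. The test suite
cross-checks the search against exhaustive enumeration of all simple paths
on hundreds of random graphs, and against a standard shortest-path
computation on graphs where all edges share one stress level.

With `recovery_rate > 0` the cycle-deletion argument fails (walking a cool
loop could pay), so the search deliberately ignores recovery — it minimizes
the additive $\sum L\,t$ — and the selected route is then *evaluated* with
the full model. Routes returned under positive recovery are therefore
optimal for the additive dose, not necessarily for the recovered dose.

`walkability_map()` scores every edge of the network from one origin: the
best terminal $R_t$ attainable at the edge's far end over feasible routes
that end by traversing that edge. An edge is scored by the better of its
two traversal directions (`rule = "max"`); `rule = "min"` reports the worse
direction, each direction still via its best route — a per-direction
pessimum, chosen because a true minimum over *all* feasible routes is not
recoverable from a Pareto frontier and would require exhaustive
enumeration. Values bin into the display categories `45–60`, `30–45`,
`15–30`, `0–15` and `exhausted` (`bin_rt()`), boundaries going to the
upper bin like the level classifier.

## City-wide aggregation

For a fifteen-minute-city (FMC) assessment, per-neighborhood maps combine
into one score with population weights $k_i = P_i / \sum_j P_j$
(`population_weights()`; scale-free, so populations may be in persons or
thousands). The per-edge combination is the convex one,
$W(e) = \sum_i k_i R_{t,i}(e)$ over the neighborhoods whose 900-m walkshed
reaches $e$, with weights renormalized over that contributing subset. The
functional form of the weighting is our design choice — a convex
combination is the natural reading of "population-weighted adjustment" and
keeps $W(e)$ bounded by the contributing values. Renormalization over
reachable neighborhoods is likewise a choice: the alternative
(`unreachable = "zero"`), which counts an unreached edge as $R_t = 0$ for
that neighborhood, penalizes edges at the walkshed fringe and is offered
behind a flag. `service_siting()` then classifies edges for public-service
placement — frequently-used (top bin), often-used, occasionally-used,
unsuitable (below 15 or unscored). A fourth "indirectly-used" class
sometimes discussed in planning practice is intentionally not modelled.

## Calibrating H from walking surveys

The budget $H$ comes from a tolerance experiment: respondents walk 15
minutes at each heat-stress level and report an ordinal discomfort
category (1 slightly uncomfortable … 4 extremely uncomfortable) every
minute. `discomfort_timeline()` aggregates each minute across respondents
by the **median, ties to the severer category** — the aggregation rule is
our choice (group-level bands can equally come from modal or majority
rules, which are not reported in this literature); the median is robust
for ordinal data and the tie rule is conservative. Category onsets are the
first minute at or above each category; the tolerated duration is the last
minute before extreme discomfort. `estimate_H()` converts a tolerated
duration range at a level into an H range by the identity
$H = L_{HS} \times t$; a level-4 tolerance of 13–15 min gives
$H \in [52, 60]$. The chosen H defaults to the **upper** bound — an
aspirational budget appropriate for planning targets — with `lower` and
`midpoint` policies available.

```{r}
estimate_H(4, c(13, 15))
```

`cronbach_alpha()` provides the standard internal-consistency check on the
per-minute item series (`survey_reliability()` runs it per level). Note
that alpha measures consistency of *between-respondent differences*: a
panel in which all respondents share one response profile plus independent
noise has alpha near zero however clean the profile is, and a noiseless
homogeneous panel leaves it undefined (zero total variance). The synthetic
generator below produces exactly such homogeneous panels, so reported
reliability coefficients from real surveys are not reproducible from it —
the package instead tests alpha against its closed form and a null
simulation.

## Synthetic data

The generators make every other module testable without external data.

* `gen_utci_field()` draws Gaussian noise on a grid, smooths it with a
  separable Gaussian kernel (the `correlation_length`, default 40 m, plays
  the role of a correlation range; a formal variogram model would be
  overkill for fixtures), centers and rescales it to `amplitude` (default
  2 °C), adds feature effects on structured masks — a riverside band along
  the west edge (−3 °C), tree-shade blobs (−2 °C), periodic east–west
  canyon rows (+3 °C) — around a base of 36 °C, and clips to a 28–44 °C
  plausibility band. The defaults emulate the afternoon street-level
  pattern reported for hot-humid mid-rise cities: an overall range of
  roughly 31–41 °C, riverside corridors near 32–34 °C, east–west canyons
  at 36–40 °C. What it does **not** emulate: radiation geometry, diurnal
  cycles, building-height effects, or any physically consistent coupling —
  passing tests on these fields shows the *pipeline* is correct, not that
  any particular city is walkable.
* `sample_edge_utci()` samples a field along each edge at a configurable
  step and records the per-edge min/max, mirroring how segment tables are
  derived from microclimate rasters.
* `gen_network()` builds grid (including degenerate chains) and radial
  networks with optional edge-length jitter.
* `gen_survey()` builds ordinal panels from true per-level onset minutes
  (defaults: level 1 never beyond "slightly"; level 2 uncomfortable from
  minute 9; level 3 very uncomfortable from minute 12; level 4 extremely
  uncomfortable from minute 13), flipping each response by ±1 category
  with probability `noise` (default 0.1), clamped to 1–4. With 128
  respondents and 10 % noise the median aggregate recovers the true onsets
  in well over 95 % of seeds.

All generators are pure functions of their arguments and seed, and restore
the caller's RNG state.

## Numerical choices and degenerate inputs

* Duration quantization guards against binary-representation excess
  (`0.2/0.1` is slightly above 2 in floating point) with a 1e-9 slack
  before the ceiling; without it, exact quotients would round a quantum up.
* The route search compares stress and distance with 1e-9 tolerances;
  stress values are sums of (level × multiple of 0.1 min) and real
  differences are at least a few hundredths, so the tolerance only absorbs
  float noise.
* Zero-length segments are legal (duration 0, no stress); empty segment
  tables, empty feature collections, negative lengths, non-finite UTCI,
  inverted UTCI ranges, all-zero populations and incomplete survey cells
  are rejected with informative errors.
* A trajectory is always returned whole, past exhaustion, with
  `exhausted_at` flagging the first segment where $R_t \le 0$; `bin_rt()`
  treats only strictly negative values as `exhausted`, so a walker who
  lands exactly on $R_t = 0$ is binned `0–15`.
* GeoJSON I/O assumes planar meter coordinates (study areas of ~1 km do
  not need geodesy); endpoint snapping tolerance defaults to 0.5 m.

## Problem sizes in the test suite

The suite fuzzes the trajectory arithmetic on 1,000 random routes, the
route search against exhaustive simple-path enumeration on 200+ random
graphs of up to 10 nodes, the per-edge map oracle on 25 graphs, and the
survey onset recovery on 100 generator seeds of 128 respondents; the
end-to-end demonstration uses a 10×10-block network on a 120×120-cell
field. These sizes were chosen so the full suite exercises every dominance
and tie-break branch while staying comfortably interactive.

## Known limitations

* $H$ is a scalar: tolerance heterogeneity across demographic groups
  (age, health status) is not modelled — a single budget must be chosen
  per analysis.
* Edge-level UTCI summaries assume the worst point governs the whole edge;
  streets with strong within-edge gradients should be pre-split into
  separate features.
* No time-of-day dynamics: one field, one traversal, no UTCI change while
  walking.
* The search treats recovery as evaluation-only (see above).
* The aggregation's convex-combination form and the walkability map's
  directional `min` rule are this package's documented readings of
  otherwise under-specified practice conventions.
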