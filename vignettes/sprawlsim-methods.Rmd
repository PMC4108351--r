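---
title: "Methods: urban growth simulation, calibration and projection in sprawlsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: urban growth simulation, calibration and projection in sprawlsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sprawlsim)
```

# The model

`sprawlsim` implements a SLEUTH-style stochastic cellular automaton for
business-as-usual urban-sprawl projection on a north-up raster grid of
square cells (60 m by default, a resolution comparable to suburban lot
sizes). A cell is either urban or not; urbanization is irreversible. Four
input layers drive the automaton: the current urban extent, percent
slope, an exclusion/resistance weight in [0, 100] (100 = water and other
undevelopable land; intermediate values are per-attempt rejection
probabilities), and a rasterized street network.

Each simulated year applies four growth phases in a fixed order, each
governed by integer coefficients in [0, 100]:

1. **Spontaneous growth.** `round(0.005 * dispersion * sqrt(nrows^2 +
   ncols^2))` uniformly random cells are attempted (round half to even).
2. **New spreading centers.** Each cell just urbanized spontaneously
   becomes a nucleus with probability `breed/100` and attempts two
   distinct random Moore neighbors.
3. **Edge growth.** Every non-urban cell with at least 3 urban Moore
   neighbors (counted synchronously against the start-of-phase extent)
   urbanizes with probability `spread/100`.
4. **Road-influenced growth.** Each cell urbanized by the earlier phases
   is selected with probability `breed/100`; the nearest road cell within
   `road_gravity/100 * (nrows + ncols)/16` cells is found, a random walk
   of dispersion-value steps (scaled by the road cell's weight) moves
   along Moore-connected road cells, and a random neighbor of the
   terminus is attempted — a success founds a nucleus that attempts two
   further neighbors.

Every attempt passes one shared gate (`attempt_urbanize()`): already
urban or weight-100 cells never flip; otherwise the cell resists with
probability `exclusion/100`, then the slope test applies. Below the
critical slope (21% by default) a cell is rejected with probability
`(slope/critical)^(slope_resistance/25)`; at or above the critical slope
development is impossible, and zero resistance always accepts below it.
This power-law lookup is smooth, boundary-correct and monotone in both
arguments; the classic SLEUTH lookup differs in constants, and every
pinned constant here (phase order, Moore neighborhood, the edge threshold
of 3, the dispersion formula) is configurable.

**Self-modification.** After each year, if the annual growth rate
(percent of the start-of-year urban area) exceeds `critical_high`
(default 1.3%/yr) the dispersion, breed and spread coefficients are
multiplied by `boom` (1.1); below `critical_low` (0.97%/yr) by `bust`
(0.9). Results are rounded half-to-even and clamped to [0, 100], with a
floor of 1 for any coefficient that was positive — a coefficient can
shrink but cannot silently die. These are widely used scenario defaults;
all four constants are configurable.

**Determinism.** All randomness flows from R's RNG, so `set.seed()`
before a run fixes the whole trajectory; `run_simulation()` over `n`
years reproduces a manual loop of `growth_step()` + `self_modify()` draw
for draw. Within the edge phase, candidates are scanned in storage order:
because candidacy is evaluated synchronously against the start-of-phase
extent, scan order cannot bias which cells can grow, so a randomized
candidate order would only permute RNG draws at extra cost.

# Urban delineation from street networks

Where land-cover products under-map low-density residential development,
street-network density is the better proxy: new subdivisions arrive with
their streets. `compute_line_density()` clips every polyline exactly to
the grid (splitting segments at each grid line, so summed length is
conserved to numerical precision) and reports km of road per km². With a
positive window radius (default 300 m), per-cell lengths are summed over
the discrete disc of cells whose centers fall within the radius, divided
by the summed cell area; the disc truncates at the grid border.

`classify_urban_extent()` applies a two-threshold rule: a cell is urban
iff its density reaches `t_low` (default 4 km/km²) *and* the land cover
already calls it urban, *or* its density reaches `t_high` (default 8
km/km²) regardless of land cover — the second clause recovers suburbs
the land-cover product misses. The thresholds are plausible suburban
values, deliberately configurable: the pipeline's correctness is
threshold-independent, and the tests pin behavior on synthetic truth
rather than on any particular constants. Limited-access highways can be
excluded from the density signal (they do not indicate homes) while
remaining in the automaton's road layer.

A dated series of networks yields one classified extent per date;
`historic_series()` enforces irreversibility by OR-accumulating earlier
extents into later ones and logs the number of flipped cell-dates, since
digitization artifacts can make a street vanish between vintages.
`assess_accuracy()` summarizes agreement with labelled reference points
as commission/omission percentages, leaving empty denominators undefined
rather than zero.

# The synthetic study area

No real GIS stack ships with the package; `synth_landscape()` builds
study areas with the structural features the pipeline exercises:

* **Terrain** — smoothed Gaussian noise (correlation length ~6 cells,
  amplitude `50 * terrain_roughness` m) differentiated to percent slope.
  At roughness 1 this yields rolling terrain with median slopes near 10%
  and ridges past the 21% critical slope, so slope resistance has real
  work to do. Roughness 0 is perfectly flat.
* **Street network** — arterials connect the town centers by minimum
  spanning tree; grid-like collectors (4-cell spacing) surround each
  center; dendritic local streets and cul-de-sac spurs scatter around
  the centers with Gaussian falloff, giving the fractal-like suburban
  pattern whose density declines with distance from the cores. A dated
  series assigns construction order mostly by distance from the centers,
  so the network densifies outward through time.
* **Land cover** — class quotas follow the requested weights exactly
  (largest-remainder rounding): urban cells sit nearest the centers,
  water fills the low end of a smooth wetness field, wetlands prefer wet
  and flat cells, and forest/agriculture/grassland partition a second
  autocorrelated field into coherent patches.
* **Exclusion** — a per-class lookup (water 100, wetland 90 by default).

`generate_historic_series()` runs the automaton itself forward under
known coefficients and snapshots the requested dates, so calibration has
a well-defined truth; `generate_radial_series()` provides a deliberately
non-CA grower (stochastic Moore dilation) for studying calibration under
model mismatch. What the generator does *not* emulate — real road
topology, census geography, economically driven growth, class-dependent
development pressure — bounds what green tests can say about real data:
they demonstrate the pipeline's correctness and the calibrator's ability
to recover a known data-generating process, not regional realism.

# Calibration

`calibrate_subregion()` scores every coefficient combination on a coarse
grid ({0, 25, 50, 75, 100} per axis, 3125 combinations) with `n_mc`
Monte Carlo runs each, then optionally re-grids around the incumbent at
half the step per refinement round. Five fit statistics are combined by
product (the optimal-SLEUTH-metric family convention, configurable):

* `compare_pop` — min/max ratio of final urban counts;
* `r2_pop`, `r2_edges`, `r2_clusters` — squared Pearson correlations of
  the per-date urban, edge-cell and 8-connected patch counts, averaged
  over runs, computed over **all** dates of the series including the
  (shared) initial date. Anchoring at the initial date matters: with
  three or four observation dates, an unanchored correlation of a noisy
  statistic such as the patch count is close to random and would inject
  pure noise into the composite. A zero-variance simulated series scores
  0, not `NaN`, ranking degenerate runs last;
* `lee_sallee` — intersection-over-union of simulated and observed urban
  extents, averaged over runs and over all observed dates.

Ties in the composite break toward the lexicographically smaller
coefficient vector, making results deterministic and independent of
evaluation order.

**Seeding and the identical-twin protocol.** Evaluation run `r` draws
from stream `base_seed + r - 1`; every candidate reuses the same streams
(common random numbers), which sharpens ranking. Consequently, seeding an
evaluation with the seed that generated a synthetic history makes run 1
an exact replay when the candidate equals the truth — the self-consistency
property (`lee_sallee = 1` at `n_mc = 1`). The package's
parameter-recovery experiments use this common-random-forcing design,
standard for synthetic identifiability studies: under fully independent
forcing the coarse grid exhibits a genuine compensation ridge (a
less-stochastic, faster-spreading candidate can overlap a single observed
realization as well as the truth does), which is a property of
one-realization calibration generally, not of this implementation.
Recovery experiments run with self-modification disabled in both
generation and evaluation so the "true coefficients" are constants;
projection re-enables it.

Per-sub-region calibration (`calibrate_all()`) freezes growth outside
each mask by forcing exclusion to 100 there and computes all statistics
inside the mask; masks must be disjoint and non-empty.

# Projection and uncertainty

`run_ensemble()` launches `n_runs` (default 200) independent simulations,
run `r` seeded `base_seed + r`, with self-modification on, so individual
runs drift toward more or less aggressive growth while staying anchored
to the calibrated coefficients. Outputs: the per-cell count of runs urban
by the final year (divided by `n_runs` this is the urbanization
probability surface), per-run annual area series (km² = cells ×
(cell_size/1000)²), and per-run final extents for conversion accounting.
The "95% range" of any per-run quantity is the 2.5th-97.5th empirical
percentile interval under the standard linear-interpolation convention
(`stats::quantile()` type 7); percentiles were chosen over min/max
because they are stable in the ensemble size. Conversion fractions
denominate each land-cover class by its initially non-urban cells and
report classes with empty denominators as undefined.

# Fragmentation metrics

`patch_metrics()` reports, per class: total area, patch count, mean and
maximum patch area (km²). Patches are connected components under
8-connectivity by default, consistent with the automaton's Moore
neighborhood (4-connectivity is available); `NA` cells belong to no
patch and no total. `metric_change()` gives percent change per class and
metric, undefined (not zero) where the baseline is zero. Overlaying a
projected extent on a land-cover map reassigns exactly the flagged cells
to the urban class.

# Numerical choices and degenerate inputs

* Round half to even everywhere a rate becomes a count (R's `round()`
  and C++ `nearbyint` agree).
* Grids combine only when their specs match exactly; nothing resamples
  silently.
* Cell membership uses half-open squares (west/north edges inclusive);
  points on the far south/east boundary belong to the last cell.
* Empty road networks yield zero density; an empty urban union scores
  Lee-Sallee 1 (two empty extents are identical).
* The growth rate with zero initial urban area is defined as 0, so
  self-modification stays inert until something exists to grow.
* CA layers must be complete; missing data belongs in the exclusion
  layer as weight 100, and the constructor says so.

# Problem sizes

The test-suite experiments use grids from 7×7 fixtures to 100×100
synthetic study areas, 4-date histories spanning 9 years, `n_mc = 5`
calibration evaluations over the full 3125-combination coarse grid, and
projection ensembles up to 400 runs over 10-50 years; the acceptance
script calibrates 6 trial landscapes at 100×100 and projects a
200-member ensemble over 50 years. These sizes exercise every code path
at desk scale; the engine's compiled kernels handle the full grid scan
in microseconds per step, so regional grids are limited by memory rather
than the automaton.

# Known limitations

* One realization calibrates the model; as discussed above, coefficient
  identifiability under independent random forcing is intrinsically
  limited, and the coarse grid reports a ranked table rather than a
  confidence region.
* No economic, demographic or policy drivers; the automaton extrapolates
  the spatial pattern of past growth (that is what business-as-usual
  means here).
* No de-densification or urban abandonment; urbanization is absorbing.
* Raster I/O is ESRI ASCII grid and vector I/O is GeoJSON, both plain
  text; no reprojection — all layers must already share one projected
  grid.
* The road random walk treats all connected road cells alike except for
  a weight-scaled walk length; no congestion or capacity notion.
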