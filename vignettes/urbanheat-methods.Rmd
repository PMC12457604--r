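---
title: "Methods: city-scale heat screening, LCZ morphology and adaptation scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: city-scale heat screening, LCZ morphology and adaptation scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbanheat)
```

## The analysis in one paragraph

Chronic urban heat is summarized by mean annual temperature (MAT): unlike
single extreme events, MAT tracks the persistent background burden that
drives cooling demand, baseline health risk and labor productivity. The
human-climate-niche literature treats 29 °C MAT as the upper edge of the
historically inhabited temperature range, with 27 °C a conservative
sensitivity cut below which dangerous extremes already rise steeply.
`urbanheat` screens a set of morphologically delineated cities against
those thresholds under climate scenarios, quantifies the exposed
population, asks whether the cities that cross the edge are built
differently from those that do not (via Local Climate Zone composition),
translates city form into adaptation-measure priorities through an expert
weight matrix, and contrasts those priorities with each city's economic
capacity (gridded GDP PPP totals).

## Data model and the cell-inclusion rule

All layers are regular north-up lon/lat grids (`geo_grid`, `class_grid`);
city footprints are (multi)polygons with id, name and continent
(`city_boundary`). The single aggregation primitive is **cell-center
containment**: a cell belongs to a city iff its center lies inside, or
exactly on the edge of, the city polygon (`cell_centers_in_polygon()`).

Three consequences motivated this choice over area-weighted clipping:

* with non-overlapping boundaries each cell joins at most one city, so
  population and GDP zonal *sums* never double-count;
* the rule is exactly testable — a brute-force point-in-polygon scan over
  every cell is an independent oracle, and the test suite holds the
  implementation to it on random polygons;
* sub-cell area weighting buys little at ~1 km cells against multi-km
  city footprints.

Centers exactly on a polygon edge count as inside. This tie rule is
deliberate and tested; it matters only for boundaries snapped to cell
edges (as the synthetic generator produces), and such boundaries are laid
out with one-cell gaps so the edge rule still cannot double-assign a cell.
Mismatched coordinate systems are an error, never silently reprojected;
reprojection, rotated transforms and resampling are out of scope.

Zonal means over MAT are unweighted cell means. Across a single city the
cos(latitude) variation of cell areas is negligible at these scales; a
latitude-weighted mode (`zonal_mean(..., latitude_weighted = TRUE)`) is
available to check that insensitivity rather than as a default.

Rasters travel as ESRI ASCII grids (`.asc`) — a standard plain-text
raster format readable by GDAL, QGIS and ArcGIS — with a `.prj` sidecar
for the CRS id; boundaries travel as GeoJSON. Float grids are written with
17 significant digits so a write/read round trip reproduces values to
double precision; integer grids round-trip bit-exactly.

## Niche screening conventions

* **Strict exceedance.** "Above 29 °C" means `mat > 29`; a city exactly at
  the threshold is not an exceeder and the 27–29 band is half-open,
  `27 < mat <= 29`. The same strict rule drives the group split of the
  morphology comparison, so a threshold city lands in the *below* group
  everywhere — the two stages can never disagree about a boundary city.
* **One population year per period.** Exposure for 2011–2040 uses the 2025
  population, 2041–2070 the 2070 population, 2071–2100 the 2100
  population (`default_period_popmap()`); no within-period averaging.
* **ΔMAT** is the exact difference between a scenario-period zonal mean
  and the same city's 1981–2010 reference zonal mean. Continental
  summaries report median and quartiles with linear interpolation between
  order statistics (R quantile type 7).
* Cities whose footprint contains no usable cell are flagged, logged with
  their id and excluded from counts — never silently dropped.

## LCZ profiles and grouping

LCZ shares are computed over *classified* cells only: nodata cells shrink
the denominator rather than forming a pseudo-class, so every profile is a
probability vector over the 17 standard classes (built 1–10, natural A–G
coded 11–17). The grouping used for the exceeder comparison defaults to
standard LCZ semantics — compact = 1–3, open = 4–6, lightweight = 7,
large low-rise = 8, sparse = 9, industry = 10, green = A–C, low plants =
D, bare natural = E–F, water = G — and is overridable everywhere, because
the category *names* (compact, open, green, bare natural) are fixed in the
field while their exact memberships are a convention.

## The morphology comparison

Cities are split at the terminal-period 29 °C threshold and each LCZ
group's share distribution is compared between the two groups with
Welch's *t*-test (no equal-variance assumption, Welch–Satterthwaite
degrees of freedom, two-sided), per continent and pooled. Implementation
delegates to `stats::t.test`; the test suite holds it to an independent
explicit-formula reference at 1e-10. Degenerate strata are resolved ahead
of delegation: n < 2 in either group gives a missing result and no
significance star; two constant equal samples give t = 0, p = 1.

Significance flags use **raw p < 0.05** — the star-annotation convention
of exploratory morphology comparisons — with a Benjamini–Hochberg mode
(`correction = "BH"`) available for sensitivity analyses. The test is
two-sided since no direction is assumed at test time.

The median-position diagnostic ("the fraction of exceeders with bare
natural surface above their continent-specific median") compares each
exceeder to the median over *all* cities of its continent, exceeders
included; `median_population = "non_exceeders"` switches the reference
set, since either reading of "continent-specific median" is defensible.
Comparisons are strict and ties count as not satisfying them, so a
single-city continent (whose share equals its own median) never counts.

## Adaptation scoring

Each measure's score is the dot product of the city's LCZ share vector
with the measure's binary suitability column. The expert mapping covers
the six built classes LCZ 1, 2, 3, 4, 8, 10; all other classes carry
explicit weight 0 in the expanded matrix so the dot product is total and
every score lies in [0, 1]. Ten measures are implemented — the full
mapping — although summaries of this framework sometimes speak of eight
core interventions; dropping rows is a user decision via the CSV override
(`load_measure_matrix(path)`), not a package default. Scores are applied
to whole-city shares without renormalizing by built-area fraction: an
extensively vegetated city genuinely has less purchase for
built-form measures, and that is what the score should express.
Continental aggregation offers `sum` (total potential) and `mean`
(per-city potential), restricted by default to exceeding cities.

## What the synthetic world emulates — and what it does not

`generate_world()` plants a complete study region whose ground truth is
known exactly:

* **Geometry.** Axis-aligned rectangular cities (2–4 coarse cells per
  side, so every city contains ≥ 4 coarse centers) on a slot grid with
  one-cell gaps; the fine LCZ grid nests exactly inside the coarse grid
  (default 0.1° coarse, 0.02° fine). Realistic shapes are a non-goal:
  the analysis only consumes containment.
* **Climate.** Continent-specific baseline MAT (e.g. Africa 25 ± 2.5 °C,
  Europe 10 ± 3 °C) plus scenario × period warming increments rising from
  ~0.8 °C (low-emission, near term) to ~4.3 °C (high-emission, end of
  century) with 0.4 °C spread — magnitudes chosen to bracket published
  continental medians for these scenario families. City MAT is constant
  across the footprint; optional iid cell noise (`mat_noise_sd`, default
  0) exists for robustness tests. With `n_exceeders` set, exactly that
  many cities are planted strictly above 29 °C for the hot scenario's
  terminal period (their baselines re-derived so warming increments stay
  realistic) and all others strictly below — giving screening tests an
  exact expected answer.
* **Population and GDP.** Log-normal city populations (median ≈ 0.7 M,
  floored at 300 000 — the "large city" convention) with log-normal
  inter-year growth; gamma per-capita GDP with continent-specific scale.
  Totals are planted as whole units and allocated to cells
  integer-exactly (quotient to every cell, remainder to the first cell
  row-major), so zonal sums recover them *exactly*, with no
  rasterization slack in the tests.
* **Morphology.** Two Dirichlet LCZ regimes with total concentration 55
  (≈ 4 percentage-point spread on a 10% class): the hot regime carries
  more bare surface (E+F 17% vs 7%) and less vegetation than the cool
  regime. Cities planted above the threshold draw from the hot regime.
  Each drawn share vector is realized on the city's fine cells by
  deterministic largest-remainder allocation (ties to the lowest class
  index), so raster-derived shares equal the planted truth exactly; a
  multinomial mode (`lcz_mode = "multinomial"`) exists for stochastic
  tests. `perturb_group_shares()` shifts one class's hot-regime
  expectation while preserving total concentration, which is how the
  power studies plant exact effect sizes.

All draws flow from one seeded generator in a fixed documented order, so
generation is a pure function of the config; the caller's RNG state is
restored afterwards.

The generator deliberately does **not** emulate: spatially autocorrelated
climate fields, urban-heat-island structure (the gridded projections the
real analysis consumes do not resolve it either), coastlines or realistic
footprints, scenario-consistent demography beyond planted totals, or LCZ
change over time. Passing tests therefore demonstrate that the *pipeline
arithmetic* is exact and the *statistical machinery* is calibrated — not
that any particular real-world city crosses a threshold.

## Numerical choices

* Largest-remainder allocation guards its floor with a 1e-9 quota epsilon
  so quotas like 49.999999 do not lose a unit; ties break to the lowest
  index.
* Point-on-edge detection uses a relative 1e-12 collinearity tolerance;
  interior tests are even-odd ray casting over all rings, which handles
  holes without special-casing.
* Quantiles are type 7 (linear interpolation) throughout.
* `welch_t` returns p = 0 with infinite t for constant samples with
  different means, and p = 1 with t = 0 for identical constants.
* CSV outputs are written with fixed column order and no row names; a
  manifest records an md5 per file and an overall run hash, and equal
  inputs give byte-identical bundles.

## Validation problem sizes

The shipped tests and the acceptance script run: brute-force zonal oracles
on 50 random polygons over 20 × 20 grids; scoring oracles and
monotonicity on 1 000 random share vectors each; Welch calibration and
power at 100 replicates of 25 cities per group; planted-truth screening on
a 120-city world with 20 exceeders; and determinism on full
simulate-then-run round trips. These sizes give the oracle comparisons
exact or 1e-12 resolution and the binomial checks usable power while
keeping the whole suite fast.

## Known limitations

* MAT is a chronic indicator; humidity, wet-bulb extremes and
  within-city heterogeneity are out of scope.
* Cell-center containment under-represents cities smaller than a few
  cells; the generator enforces ≥ 4 coarse centers per city, and real
  inputs should respect the same floor.
* GDP (PPP) totals proxy adaptive capacity only coarsely — they capture
  neither institutional strength nor distribution; a per-capita column is
  provided but not used in defaults.
* The expert weight matrix is binary by design; graded suitability would
  need a different (non-0/1) override semantics.
* No reprojection: all layers must already share a geographic CRS.
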