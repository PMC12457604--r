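# urbanheat

Screening the world's large cities against the upper edge of the human
climate niche — and asking what their urban form lets them do about it.

`urbanheat` is an R implementation of a city-scale chronic-heat analysis
pipeline for researchers in urban climatology and spatial exposure
analytics. Given gridded mean annual temperature (MAT) projections under
emission scenarios, gridded population and GDP (PPP), a Local Climate Zone
(LCZ) map, and morphological city boundaries, it:

1. **aggregates** every grid layer to the city level by cell-center zonal
   statistics (mean for MAT, sum for population and GDP, class shares for
   LCZ);
2. **screens** each city per scenario × period against niche thresholds —
   29 °C MAT as the upper habitability benchmark, 27 °C as a conservative
   sensitivity cut — and accounts the exposed population, with each period
   represented by a single population mapping year (2011–2040 → 2025,
   2041–2070 → 2070, 2071–2100 → 2100);
3. **compares urban morphology** between cities above and below the 29 °C
   end-of-century threshold, per continent and pooled, using Welch's
   *t*-test on LCZ group shares (raw two-sided *p*, flags at α = 0.05),
   plus median-position diagnostics ("what fraction of exceeders have more
   bare surface than their continent's median city?");
4. **scores adaptation measures** per city as the dot product of LCZ
   shares with an expert binary suitability matrix,

   Score(m) = Σ_LCZ S_LCZ · w(LCZ, m) ∈ [0, 1],

   where S_LCZ is the share of each LCZ class of the classified city area
   and w is 0/1 over the built classes LCZ 1, 2, 3, 4, 8, 10 (ten measures,
   from densification control to reflective materials, greening and water
   bodies), aggregated per continent by sum (total potential) and mean
   (per-city potential);
5. **overlays economic capacity**: per-city GDP (PPP) totals joined to
   terminal-period MAT, with per-continent quartile summaries restricted to
   exceeders.

Because the original continental-scale gridded products are far too large
for a test bench, the package ships a first-class **synthetic world
generator** (`generate_world()`): non-overlapping city footprints on
nested coarse/fine grids, planted baseline MAT and scenario warming,
planted populations, GDP totals allocated integer-exactly to cells, and
LCZ compositions drawn from two regimes (hot cities: more bare surface,
less vegetation) realized exactly by largest-remainder allocation. Every
downstream number therefore has an exact planted truth to be checked
against.

## Worked example

```r
library(urbanheat)

cfg    <- world_config(n_cities = 60L, n_exceeders = 10L, seed = 42L)
world  <- generate_world(cfg)
tables <- run_pipeline(world, "demo_out")

subset(tables$exposure, scenario == "SSP5-8.5" & period == "2071-2100" &
                        continent == "ALL")
```

```
 scenario    period     band continent n_cities population
 SSP5-8.5 2071-2100 below_27       ALL       40   84304314
 SSP5-8.5 2071-2100 27_to_29       ALL       10   17877290
 SSP5-8.5 2071-2100 above_29       ALL       10   14584144
```

The three bands partition the 60 cities; the 10 planted exceeders are
recovered exactly, and their exposed population (here 14.58 million) is
exactly the sum of the planted 2100 populations of those 10 cities.

```r
tables$continental_delta[tables$continental_delta$scenario == "SSP5-8.5",
                         c("continent", "n", "q1", "median", "q3")]
```

```
     continent  n   q1 median   q3
        Africa 14 3.55   3.98 4.42
          Asia 15 3.82   4.06 4.37
        Europe  9 4.06   4.18 4.53
 North America  7 4.24   4.37 4.48
       Oceania  7 4.32   4.50 4.64
 South America  8 3.85   3.90 4.33
```

Median end-of-century warming vs. the 1981–2010 reference, per continent
(°C). The morphology contrast and its significance flags:

```r
subset(tables$comparison, continent == "ALL" &
       lcz_group %in% c("bare_natural", "green", "low_plants"))
```

```
    lcz_group n_below n_above mean_below mean_above        p significant
        green      50      10     0.1755     0.0884 8.58e-12        TRUE
   low_plants      50      10     0.1162     0.0819 8.40e-03        TRUE
 bare_natural      50      10     0.0661     0.1818 9.20e-06        TRUE
```

Exceeding cities carry about 18% bare natural surface against 7% for the
cooler group, and significantly less green cover — the planted regime
contrast, detected by the Welch comparison. The accompanying diagnostics
(`tables$median_diagnostics`) report that 100% of exceeders sit above
their continent-specific bare-surface median and 90% below the green-share
median, and the mean pervious-surface adaptation score over exceeders is
0.202 (`tables$scores`).

A thin command-line front end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/urbanheat.R", package = "urbanheat"))') \
    simulate --out world_dir --seed 42 --n-cities 60 --n-exceeders 10
Rscript ... run --in world_dir --out results_dir
Rscript ... report --in results_dir
```

## Vignette

`vignettes/urbanheat-methods.Rmd` documents the model and its conventions:
the cell-center containment rule, the strict exceedance convention, the
LCZ grouping defaults, what the synthetic generator does and does not
emulate, and the package's known limitations.
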