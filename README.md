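# pelagostat

Geostatistical analysis of small-pelagic-fish acoustic surveys.

Scientific acoustic surveys sample fish biomass along parallel vessel
transects, recording a biomass density per species for every 1-nm track
segment (EDSU). `pelagostat` turns a decade of such records into the
standard spatial-ecology answers: how aggregated each population is, how
stable its spatial structure and geography are across years, where its
persistent habitat lies, and how strongly species overlap at global,
intermediate and local scales. It is aimed at fisheries scientists and
spatial ecologists working with systematic transect surveys of shoaling
species (anchovy, sardine, sprat and relatives).

## What it computes

* **Aggregation** — presence area; concentration curves; the space
  selectivity index, twice the area between the concentration curve and
  the diagonal (a Gini-type coefficient: 0 = homogeneous, → 1 = all
  biomass in one sample).
* **Spatial structure** — bidirectional empirical variograms of
  log-biomass, γ(h) = ½ E[(Z(x) − Z(x+h))²], with weighted-least-squares
  fitting of nugget + nested anisotropic spherical models; the multi-year
  mean variogram (within-year pairs only); a turning-bands simulation
  envelope and a per-year stability test of the spatial structure.
* **Distribution** — centre of gravity, inertia and inertia ellipses;
  greedy anisotropic patch identification; EOF decomposition of annual
  maps; pointwise temporal CV of relative biomass.
* **Mapping** — ordinary kriging of log-biomass on a 1 × 1 nm grid with an
  anisotropic moving neighbourhood; mean/variability maps; classification
  of recurrent, occasional and unfavourable areas by median splits.
* **Collocation** — inertia-ellipse overlap (intersection-over-union),
  patch-ellipse-union overlap, co-occurrence, the local index of
  collocation (cosine of density vectors), the dominance index
  (z_i − z_j)/(z_i + z_j), and randomization tests.
* **Synthetic surveys** — a seeded generator emulating the survey design
  (9 transects 12 nm apart, ~280 EDSUs/year, 10 years) and the data's
  statistical structure (spatially clumped zeros, lognormal-type skew,
  coastal gradients, contrasting abundance trajectories), so the whole
  pipeline runs and is testable without survey data.

The methods vignette (`vignettes/pelagostat-methods.Rmd`) documents the
models, defaults and design choices in detail.

## Worked example

```r
library(pelagostat)

ds <- simulate_survey(simulation_spec(n_years = 10, seed = 1))
ds
#> Acoustic survey dataset: 2790 EDSU records, 10 year(s), 3 species
#>   species: anchovy, sardine, sprat
#>   years:   2003, 2004, 2005, 2006, 2007, 2008, 2009, 2010, 2011, 2012

s <- annual_summaries(ds)
head(subset(s, species == "sprat")[, c("year", "presence_area_pct",
                                       "total_biomass", "selectivity")], 4)
#>    year presence_area_pct total_biomass selectivity
#> 21 2003          29.03226           685   0.8742905
#> 22 2004          37.63441           786   0.9555068
#> 23 2005          48.38710          1955   0.8066286
#> 24 2006          39.06810           772   0.8355981

# does occupied area expand with abundance? (basin-hypothesis signal)
sp <- subset(s, species == "sprat")
r <- metric_vs_logbiomass(sp$presence_area_pct, sp$log_biomass)
#> slope 7.95, adj R2 0.96, p = 6.6e-07

# mean variogram of log-biomass, annually standardized
logb <- log_transform(ds$records$anchovy)          # ln(B + 0.05)
mv <- mean_variogram(ds$records$x, ds$records$y, logb, ds$records$year)
mv
#> Mean variogram (within-year pairs pooled over years)
#> Variogram model: nugget 0.2228 + 2 spherical component(s)
#>   sill 0.5843, range along 11.06 nm / across 9.694 nm
#>   sill 0.2854, range along 42.07 nm / across 61.34 nm
#>   total sill 1.093

# where the population sits and how spread it is
rec <- ds$records[ds$records$year == 2003, ]
inertia(rec$x, rec$y, rec$anchovy)
#> CG (57.06, 10.48) nm; inertia 731.5 nm^2 (RMS distance 27.0 nm)
#>   ellipse semi-axes 26.20 x 6.70 nm, orientation 179.1 deg

local_index_of_collocation(rec$anchovy, rec$sardine)
#> [1] 0.127
```

Reading the numbers: the sprat-like species occupies 29–77% of the sampled
points, and its presence area rises steeply and significantly with the log
total-biomass index (slope 7.95 percentage points per log-ton, adjusted
R² 0.96) — it spreads as it grows, while the anchovy-like preset shows no
such relation. The mean variogram says two anchovy log-densities 5 nm apart
are far more alike than two 40 nm apart (semivariance 0.5 vs ~1.0), with a
short-range structure around 10–11 nm on top of a longer one. The inertia
ellipse (26 × 7 nm at one sigma) summarises an along-shelf-elongated
population; the low LIC (0.13) despite broad co-occurrence means the two
species' biomass *peaks* sit in different places even where both are
present.

The full pipeline — aggregation, variography with stability testing,
indices, kriging, classification, collocation, CSV outputs and a JSON
manifest — runs from one call:

```r
res <- run_pipeline(pipeline_config(seed = 1, out_dir = "pelagostat_out"))
```

A thin CLI wrapper is installed at `inst/cli/pelagostat`
(`pelagostat simulate|run|validate`); an example YAML configuration is in
`inst/extdata/pipeline_example.yaml`.

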