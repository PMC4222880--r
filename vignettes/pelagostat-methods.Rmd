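---
title: "Methods: geostatistics of small-pelagic acoustic surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geostatistics of small-pelagic acoustic surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pelagostat analyses the spatial distribution of small pelagic fish (anchovy,
sardine, sprat and similar shoaling species) from systematic acoustic
surveys: a research vessel runs parallel transects and integrates acoustic
backscatter into a biomass density per Elementary Sampling Distance Unit
(EDSU), here 1 nautical mile (nm) of track. The package takes those per-EDSU
densities — one value per species, year and location — and answers three
questions: how aggregated is each population, how stable is its spatial
structure and its geography over years, and how much do species overlap at
different spatial scales.

This vignette explains the statistical machinery, the choices that were
genuinely open, and what the synthetic-data generator does and does not
emulate.

## Data model and transforms

Coordinates are projected from WGS84 degrees to planar nautical miles with a
local equirectangular projection about the dataset centroid
(`project_to_nm()`). Over a shelf-scale study area (roughly 2° × 1°) the
distortion is negligible, and the nm unit — in which transect spacing, lags,
ranges and search radii are naturally expressed — stays exact along the
reference parallel. No geodesic rigour is needed or attempted.

Acoustic biomass densities are extremely skewed: many zeros, a few very
large shoal detections, and a variance roughly proportional to the mean.
All variography and kriging therefore operate on `log(B + c)`
(`log_transform()`). The offset `c` defaults to 0.05 tons, a value of the
order of the smallest non-zero density such surveys record. It is a single
global constant rather than a per-species or per-year value: a shared
offset keeps log-biomass comparable across species and years, whereas a
per-stratum offset would silently shift level differences into the
transform. It is configurable where that trade-off is judged differently.

Every statistic in the package is tied to the 1-nm EDSU support; values are
treated as point measurements at EDSU centres, with no block-support
correction.

## Aggregation indicators

`presence_area()` is the percentage of sampled EDSUs where the species
occurs. `concentration_curve()` sorts samples by decreasing biomass and
cumulates: the curve shows the maximum biomass proportion recoverable from
a given proportion of samples, equalling the diagonal for a homogeneous
population. `space_selectivity_index()` is twice the area between curve and
diagonal — a Gini-type coefficient in `[0, 1 - 1/n]`, higher when biomass
concentrates in fewer samples.

Two numerical conventions here were open:

* **Integration rule.** The area under the curve is computed by exact
  trapezoidal integration of the curve vertices rather than as a step sum.
  The two differ by O(1/n), and the trapezoid choice makes the index
  *identical* to the Gini coefficient computed from mean absolute pairwise
  differences — the test suite asserts equality to 1e-10 against that
  independent formula.
* **Ties.** Equal biomass values may be sorted in any order; the cumulated
  curve is invariant to the choice, which is asserted rather than assumed.

The per-year coefficient of variation uses the sample standard deviation
(n − 1 denominator). Regressions of annual indicators on the log total
biomass index (`metric_vs_logbiomass()`) are ordinary least squares through
`lm()`; they are standard wrappers reported for convenience, not bespoke
method content.

## Variography

`empirical_variogram()` implements Matheron's estimator
\(\gamma(h) = \frac{1}{2N(h)}\sum_{|x_i-x_j| \in h}(z_i - z_j)^2\)
over unordered pairs, classed by lag and by direction. Because sampling is
dense along transects (1 nm) but sparse across them (12 nm), directions are
transect-relative: pairs within ±15° of the transect azimuth are "along",
within ±15° of the perpendicular "across". The angular half-width is not a
quantity the data dictate; 15° keeps the along class essentially
within-transect while admitting the slightly oblique cross-transect pairs
at long range. Defaults: 2-nm lag classes, capped at a 50-nm maximum lag —
half the typical domain width, beyond which pair geometry is dominated by
the domain shape. Each lag class also records the mean pair distance
(`dist_avg`): on gridded samplings the distances inside a class sit
asymmetrically about its centre, and fitting against the class centre
biases ranges upward by several percent, so the fit uses `dist_avg`.

`fit_variogram_model()` fits a nugget plus one or two spherical components
by weighted least squares with pair counts as weights — the simplest stable
weighting when nothing in the data argues for Cressie-type weights.
Anisotropy is geometric: each component has direction-specific ranges but a
single sill, so both directional curves converge to the same total sill.
Zonal anisotropy was rejected for parsimony: with two directions only,
direction-specific sills are barely identifiable. Optimisation is L-BFGS-B
with box constraints (non-negative nugget and sills, positive ranges) from
six deterministic starting points spanning short- and long-range, low- and
high-nugget configurations; the best local optimum is kept. A flat
empirical variogram correctly collapses to pure nugget (sills at the zero
boundary). On noise-free curves evaluated from a known two-structure model
the fit recovers all seven parameters to better than 1%.

`mean_variogram()` pools pairs over years — a pair contributes only if both
points belong to the same year, which is algebraically the pair-count-
weighted average of annual variograms — after standardizing each year to
mean 0, variance 1 (`standardize_by_year()`). Z-scoring is the
interpretation adopted for "annually standardized"; division by the annual
mean is a config alternative but couples the standardized level to presence
area, which confounds the structure comparison.

## The turning-bands simulator and the stability test

`simulate_gaussian_field()` simulates zero-mean Gaussian fields with a
given nested spherical variogram by turning bands. Each spherical
component of range *a* is built from one-dimensional moving-average
processes on lines: white noise convolved with the linear ramp kernel
\(f(u) = u\) on \(|u| \le a/2\), whose autocovariance is exactly the 1-D
turning-bands equivalent \(c_1(h) \propto 1 - 3h/a + 2(h/a)^3\) of the 3-D
spherical covariance. Averaging over line directions then yields the
spherical model; planar locations are embedded in the equatorial plane.
Directions are a Fibonacci lattice on the sphere (default 180 lines)
rotated by a seeded random rotation, so fields are deterministic given the
seed and the only approximation is direction discretisation — with 180
lines the simulated variogram matches the target within ~1% at interior
lags, and Monte-Carlo checks in the test suite hold it within 10% under
200-field averaging. The noise discretisation step is 1/50 of the
component range; the nugget is added as independent Gaussian noise.

`variogram_envelope()` simulates many fields (default 1000; the number of
simulations is configurable, and ~500 already gives stable bounds) from
the fitted mean model at one year's sampling locations, computes each
field's bidirectional variogram — z-scored first, matching the treatment
of the survey data — and returns pointwise 2.5%/97.5% quantiles.
`test_annual_stability()` flags a year unstable when more than
`tolerance_fraction` (default 0.05) of its populated lag classes fall
outside the envelope.

A calibration caveat, measured rather than assumed: the envelope is
*pointwise*, so each lag class individually has ~5% exceedance under the
model, but a survey has ~25 populated lag classes and their excursions are
only partially dependent. The familywise probability that a model-true
year exceeds the 5% lag-fraction tolerance is therefore well above 5% —
about 17–25% in simulation, stable across envelope sizes of 500–1000. The
default tolerance is kept at 0.05 for sensitivity; users who want a
calibrated ~5–10% false-alarm rate should raise `tolerance_fraction` to
about 0.15, and the stability table reports the raw outside fraction so
either reading is available.

## Distribution indicators

`centre_of_gravity()` and `inertia()` give the biomass-weighted mean
location and the weighted mean squared distance to it; the principal-axis
decomposition of the weighted covariance supplies an inertia ellipse. The
ellipse is drawn at one sigma (semi-axes = square roots of the principal
variances). Any fixed multiple would do as long as it is used
consistently — the overlap indices below depend only on that consistency —
and one sigma keeps `ellipse area = π·a·b` directly interpretable in
variance terms.

`identify_patches()` assembles patches of high biomass greedily: presence
samples in decreasing biomass order, the richest founding the first patch,
each next sample joining the nearest patch by the anisotropy-scaled
distance \(\sqrt{(\Delta_a/d_a)^2 + (\Delta_c/d_c)^2}\) to the patch's
*running biomass-weighted centre of gravity* (not to its nearest member)
if that distance is ≤ 1, else founding a new patch. Distance ties break
toward the earlier-created patch; equal-biomass samples keep input order.
The default thresholds — 6 nm along transects, 24 nm across — compensate
the 12-nm transect spacing; they sit in the regime where the patch count is
insensitive to the exact values, which is the criterion by which such
thresholds are chosen in practice. Patches under 10% of total biomass are
flagged non-retained instead of deleted, so the patch table always accounts
for 100% of presence biomass. An independent step-by-step reimplementation
of the recursion (in the test helpers) reproduces every assignment on
randomized small configurations.

`eof()` decomposes the year × location matrix by SVD after standardizing
rows (default: divide each year by its total, so maps are compared free of
abundance trends) and centring each row. Row-centring, rather than
location-centring, is what makes two identical years a rank-one matrix
with 100% of variance on axis 1 — the natural reading of "how persistent
is the spatial distribution". For independent random years the leading
axis carries roughly 1/n_years of the variance (plus a Marchenko–Pastur
excess when locations ≫ years), which is the null against which observed
axis-1 shares should be read. Year scores, spatial loadings and each
year's correlation with each loading are returned; the decomposition
reconstructs the centred matrix to numerical precision.

`pointwise_cv()` computes, at each location, the temporal CV of *relative*
biomass (each year divided by its total), so the result reflects
relocation rather than overall abundance change; locations never occupied
are returned `NA`, and a CV above 1 marks overdispersion.

## Kriging and area classification

`krige()` performs ordinary kriging of log-biomass on a 1 × 1 nm grid
masked to the convex hull of the samples intersected with the design
polygon. The neighbourhood search is anisotropic — default radii 12 nm
along, 30 nm across, minimum 4 and maximum 32 neighbours ranked by scaled
distance — chosen so every node reaches data on at least two transects;
with an isotropic 12-nm radius most inter-transect nodes would see only
one. The OK system is solved in covariance form per node; weights sum to
one by construction and the implementation is checked against an
independent semivariance-form dense solve to 1e-8. Nodes with too few
neighbours or a singular system are flagged and left `NA` rather than
failing the map. Kriging with a zero-nugget model reproduces data values
exactly at data locations. Maps are produced and analysed on the log
scale; no lognormal back-transform is applied, so maps are medians-like
indicators of level, not unbiased biomass estimates.

`classify_areas()` combines the node-wise mean and standard deviation of
the annual maps: high variability (sd ≥ its median) → *occasional*; low
variability and high mean (≥ its median) → *recurrent*; low variability
and low mean → *unfavourable*. Ties at either median count as "high", a
convention the tests pin down (an all-identical stack of maps classifies
everywhere as occasional, since zero sd ties its own median).

## Collocation at three scales

* **Global** — `ellipse_overlap()`: intersection-over-union of the two
  populations' inertia ellipses. The IoU form is adopted because it is
  symmetric and meets both endpoint requirements (0 for disjoint ellipses,
  1 for identical ones). Areas come from 720-vertex polygonal
  approximations (relative area error < 1e-4) with Sutherland–Hodgman
  clipping for the intersection.
* **Intermediate** — `patch_overlap()`: the same IoU applied to the
  *unions* of the two species' retained patch ellipses. Unions of ellipses
  are not convex, so here membership is evaluated analytically
  (point-in-ellipse quadratic form) on a 400 × 400 grid over the joint
  bounding box; the approximation error is well below 0.01 on the test
  geometries and the computation is deterministic.
* **Local** — `cooccurrence_index()` (shared presence among points where
  at least one species occurs), `local_index_of_collocation()` (the cosine
  of the two density vectors: 1 iff proportional densities, 0 iff disjoint
  supports, invariant to rescaling either species) and
  `dominance_index()` \((z_i - z_j)/(z_i + z_j)\), antisymmetric, `NA`
  where both species are absent.

`randomization_test()` evaluates a local index against a null built by
resampling the second species across locations — bootstrap with
replacement by default, permutation as an option, since either reading of
"non-parametric bootstrap" is defensible; the first species' pattern is
held fixed. The two-sided p-value uses the add-one estimator, so the
smallest attainable p is 1/(B + 1); p-values over pairs and years are
reported raw, with no multiplicity correction.

## The synthetic survey generator

Because per-EDSU acoustic data of this kind are not publicly deposited,
the package carries a generator (`simulate_survey()`) that emulates the
*design* and the *statistical structure* such data exhibit, so the whole
pipeline is exercisable and testable. The emulated design is 9 parallel
north–south transects 12 nm apart, 31 1-nm EDSUs per transect (279 per
year), 10 annual surveys. Per species and year the generator draws a
latent Gaussian field with a nested spherical variogram (turning bands),
adds a linear coast–offshore trend and, optionally, an abundance-coupled
mean shift, zeroes everything under an absolute latent cutoff,
exponentiates the rest and rescales so the yearly sum matches the
scenario's annual total exactly.

Choices worth recording:

* **Zero inflation by latent thresholding**, not independent Bernoulli
  zeros: absences come out spatially clumped, as for shoaling fish, and
  presence area inherits the field's autocorrelation.
* **The cutoff is an absolute latent level** (the `zero_threshold`
  quantile of the baseline latent distribution), not a per-year empirical
  quantile. With a per-year quantile, presence area would be constant by
  construction and could not covary with abundance; with an absolute
  cutoff, the `abundance_coupling` parameter shifts the latent mean with
  log total biomass, producing basin-hypothesis behaviour (densification
  plus range expansion) in the presets that enable it.
* **Preset calibration.** The three presets bundled in
  `default_scenarios()` were fixed once against the published magnitudes
  for this guild: annual totals follow decade-long acoustic stock series
  (stable ~15–40 kt; fluctuating 45–265 kt; growing 0.7–70 kt); latent
  ranges ~15 nm plus a long component for the two broad-range species and
  4/12 nm nested for the short-range one; zero thresholds giving ~90%,
  ~87% and ~50% baseline presence; skews 1.8/2.2/1.9 giving per-EDSU
  biomass CVs near 2.5/3.8/3.3 with the right ordering; coupling 0.2 for
  the expanding species so its presence area spans roughly 15–80% over its
  trajectory. These are study conditions, not tuning knobs.

What the generator does *not* emulate: physical acoustics (no target
strength-to-energy chain), bathymetry beyond a linear across-shelf trend,
within-EDSU shoal microstructure, vessel avoidance, or inter-species
dependence in the latent fields (species are simulated independently, so
observed collocation arises only from shared gradients). Tests passing on
synthetic data therefore demonstrate the correctness and calibration of
the *methods* under known truth — not that real surveys satisfy the
generator's assumptions.

## Problem sizes and determinism

The test suite and the acceptance script size their simulations to run on
a single CPU in minutes: 150–1000 turning-bands simulations for envelopes,
200 fields for coverage and fidelity checks, 30–50 replicate years for
parameter-recovery medians, 50 replicate decades for the qualitative
contrast between expanding and stable presets. Every stochastic routine
takes an explicit seed and restores the caller's RNG state, and the
pipeline's manifest records seeds and output checksums so a rerun with the
same configuration is bit-for-bit identical.

## Known limitations

* Range estimates from single survey years on a bounded, elongated domain
  are upward-biased (median ~+15% at a 15-nm range on this design); the
  package reports medians over replicates where calibration matters.
* The stability test's default tolerance is sensitive rather than
  calibrated; see the variography section.
* Kriged log-biomass maps are not back-transformed; comparisons between
  maps are ordinal, not additive in tons.
* The local projection and the transect-relative direction classes assume
  a common azimuth for all transects; surveys with bent or radial designs
  would need per-stratum azimuths.
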