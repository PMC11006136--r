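---
title: "Dual-isotope isoscapes and geographic assignment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-isotope isoscapes and geographic assignment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(isorigin)
library(dplyr)
```

## The problem

Where did an animal live, given the isotopic composition of its tissues?
Bioavailable strontium (⁸⁷Sr/⁸⁶Sr) enters food webs from weathering bedrock
and varies with geology; the δ¹⁸O of precipitation varies with latitude,
elevation and climate and is recorded (via drinking water) in skeletal
carbonate. If both quantities can be mapped as *isoscapes* — rasters
predicting the isotope value at every cell — then a tissue measurement can
be compared against the map at the recovery site ("is this individual local?")
and, for non-locals, inverted into a probability surface of origin.

`isorigin` implements that workflow end to end for a dual Sr–O system with
an auxiliary δ¹³C diet axis: tissue-isotope conversions, a random-forest Sr
isoscape with quantile-forest uncertainty, buffered sample-vs-isoscape
deltas, a 1σ local/non-local rule, linear isoscape calibration, Bayesian
continuous-surface assignment, and distance-of-origin densities. A
synthetic-landscape generator with known ground truth makes every stage
testable.

## Tissue conversions

Skeletal δ¹⁸O is measured on the carbonate moiety (VSMOW scale after the
standard IAEA inter-scale conversion, δ¹⁸O~VSMOW~ = 1.03091·δ¹⁸O~VPDB~ +
30.91). Two affine maps take it to the scale the precipitation isoscape
lives on:

1. carbonate → phosphate: inverts δ¹⁸O~c~ = 1.037·δ¹⁸O~PO₄~ + 8.57
   (mammal bioapatite);
2. phosphate → drinking water: the cervid relation δ¹⁸O~w~ =
   1.23·δ¹⁸O~PO₄~ − 27.76.

All constants live in `iso_constants()` with citation strings rather than
inside the operations, because published calibrations differ between taxa
and laboratories; swapping a constant set never touches code. Because every
conversion is affine, conversions commute with averaging — a property the
test suite asserts to 1e−10.

Tissue δ¹³C declines with the industrial-era drop in atmospheric CO₂ δ¹³C
(the Suess effect), so values from different death years are not comparable
until reported to a common reference year. `suess_correct()` subtracts
L(year of death) − L(reference year), where L is a LOESS trend (span 0.3,
degree 2, annual resolution) through the atmospheric record. The span was
chosen to follow the secular decline without chasing interannual noise; the
default reference year is 1994, with 1800 supported as the pre-industrial
alternative. Beyond the record's span the fit is, by default, not
extrapolated (an explicit flag enables constant continuation of the
terminal value); silent trend extrapolation is the failure mode we refuse.

## The Sr isoscape

`fit_isoscape()` regresses point training values on a stack of co-registered
environmental predictor rasters with a random forest (1000 trees,
`mtry = ⌈p/3⌉`, the common regression-forest convention). Geographic
coordinates are deliberately **not** predictors: the model should transfer
through environmental similarity, not spatial proximity. Candidate
predictors can be screened by `select_predictors()`, which keeps those with
permutation importance at least 5% of the maximum — a simple, transparent
stand-in for heavier wrapper-based selection procedures.

Skill is estimated by 10-fold cross-validation (`cross_validate()`): a
random partition by seed, every point out-of-fold exactly once, pooled RMSE
and R² = 1 − SS~res~/SS~tot~ over out-of-fold predictions. Random rather
than spatially blocked folds match the headline use case (interpolation over
a sampled region); spatial blocking would be the natural extension for
extrapolation claims.

The uncertainty map comes from the forest's quantile mode
(`uncertainty_surface()`): per cell, half the distance between the 0.16 and
0.84 quantiles of the terminal-node response distribution — an estimate of
the central ~68% interval, which for homoscedastic Normal noise approximates
the noise SD. Two numerical details matter: quantile-mode node values are
drawn through R's RNG, so fits pin that seed too (otherwise re-running a
pipeline changes the error map bit-for-bit); and the map is clamped by
construction to be nonnegative.

The precipitation δ¹⁸O isoscape is ingested, not modelled:
`load_oxygen_isoscape()` attaches a constant, conservative 1‰ per-cell
uncertainty (an order of magnitude above typical model median errors).

## Local or not: buffered deltas and the 1σ rule

`compute_deltas()` compares each sample with the isoscapes around its
recovery site: Δ = sample − buffered isoscape mean, where the buffer is the
unweighted mean of cells whose centers lie within `radius_km` (great-circle,
6371-km sphere; center-in-circle selection keeps results bit-stable). If no
center falls inside, the containing cell is used. The radius can be chosen
by `scan_buffer_radius()`, which maximizes the OLS R² of sample vs buffered
isoscape values over a candidate list, breaking ties toward the smallest
radius; 10 km is the default, consistent with large-herbivore home ranges.

`classify_local()` computes the mean and SD of each Δ distribution once,
over all samples (no iterative re-trimming), and flags a sample non-local
if it falls outside `sigma` SDs (default 1) on **either** axis. Mean ± SD
was chosen over median ± SD as the centering statistic; the choice matters
little for roughly symmetric Δ distributions but is stated explicitly
because the rule is single-pass. `group_difference_test()` (Mann–Whitney U;
exhaustive enumeration of tie-averaged ranks when both groups have ≤ 8
observations, tie-corrected normal approximation otherwise) backs the
sex and tissue contrasts of `group_comparisons()`.

## Calibration

Tissue values need not sit on the isoscape scale (diet integrates sources
differently than the training materials), so `fit_calibration()` fits
sample = intercept + slope·isoscape on the local samples — classical
calibration, applied forward to the raster by `apply_calibration()`.
`calibrated_uncertainty()` propagates the spatial error through the slope
and adds the calibration residual SD in quadrature:
√((slope·sd)² + residual_sd²). Folding the residual scatter into the
assignment error is a deliberate choice: without it, a poorly calibrated
isoscape would claim the same assignment precision as a good one.

## Bayesian assignment

For a non-local sample with observed value *y*, `posterior_surface()`
evaluates the Normal density φ(y; mean~cell~, sd~cell~) at every non-nodata
cell and normalizes to unit mass — a flat prior over the raster footprint.
Computation is in log space so an observation far from the mapped range
cannot underflow to an all-zero surface. Sr and O posteriors are combined
by `joint_posterior()` as a renormalized per-cell product (conditional
independence given origin). Masses are per cell by default; a cos(latitude)
area weighting is an explicit switch because at high latitudes cell areas
differ materially and the choice should be visible, not implicit.

`top_quantile_region(q)` marks the ⌈qN⌉ most probable cells (area-based
top-q; a cumulative-probability mode is provided since both conventions are
in circulation, and ties at the threshold are always included).
`distance_density()` accumulates posterior mass into half-open great-circle
distance bins from the death site, giving the "how far from where it died
did it likely live" summary.

## The synthetic landscape

`make_landscape()` generates the ground truth every test leans on:

* **Geology**: a smoothed Gaussian field quantized into `n_geo_units`
  equal-frequency classes; patches inherit the kernel's spatial scale. Each
  unit gets a base ⁸⁷Sr/⁸⁶Sr spread evenly over 0.712–0.742, spanning
  old-shield to younger-terrane values.
* **Sr field**: unit base + spatially correlated noise (Gaussian-smoothed
  white noise, marginal SD `sr_noise_sd`, default 0.002) + a coastal
  "sea-salt" pull toward the seawater ratio 0.7092 decaying with an 80-km
  e-folding distance from the western margin.
* **δ¹⁸O field**: declines with latitude (default 0.7‰ per degree, matching
  high-latitude precipitation gradients) and elevation (0.28‰ per 100 m).
* **Predictors**: an informative proxy (Sr field + small smoothed error),
  elevation, coast distance, a temperature surface, and a pure-noise layer
  that predictor selection should discard.
* **Individuals** (`simulate_individuals()`): origins uniform over land;
  tissue Sr = field at origin + Normal noise (default SD 0.002, matching
  the field noise); tissue δ¹⁸O = field + tissue offset + Normal noise
  (default SD 0.3‰ — analytical reproducibility plus drinking-water
  scatter for a resident herbivore averaging over seasons). Antlers carry a
  +1‰ δ¹⁸O offset over bone, reflecting spring–summer antler growth. A
  fraction of individuals have their death site displaced by a fixed
  distance (default 3× the landscape correlation length, ~250 km) along a
  uniform random bearing resampled to stay on land.
* **Atmosphere** (`make_atmosphere_record()`): δ¹³C~atm~ = base −
  decline·t², a smooth monotone fall (slow early, fast late) of 1.5‰ over
  1800–1994 — the magnitude of the industrial-era record. Because the curve
  is globally quadratic, the LOESS trend reproduces it exactly, which turns
  the Suess correction's by-construction examples into sharp tests.

What the generator does **not** emulate: real Scandinavian geology,
spatially clustered training compilations, inter-laboratory offsets,
diagenesis, individual-level physiological random effects, or any movement
model richer than a single displacement distance. Passing the recovery
tests therefore demonstrates that the *machinery* is correct and
well-calibrated under its stated assumptions — not that any particular
real-world isoscape is accurate.

## Validation scale and known limitations

The test suite's full-scale experiment uses a 100×100 grid, 4 geology
units, 400 training points and cohorts of 200 individuals, replicated 10–20
times — sizes at which the forests resolve the field well while a full
replicate stays in seconds. On those conditions the suite checks CV R² ≥
0.6, truth-RMSE ≤ 0.004, an uncertainty-map median within [0.7σ, 1.3σ] of
the injected noise, 1σ-classifier sensitivity ≥ 0.6 and specificity ≥ 0.8,
and ≥ 80% of detected non-locals recovering their true origin inside the
top-10% joint posterior region.

One of these is structurally tight: classifier specificity. The +1‰ antler
offset places antler locals well off the pooled ΔO mean, so their 1σ
coverage is low and the cohort-level specificity sits at ≈ 0.79–0.81
depending on seed. This mirrors a real property of the 1σ rule on mixed
bone/antler cohorts rather than a defect of the implementation; a
tissue-stratified rule would fix it but would be a different classifier
than the one specified.

Other limitations worth naming: the forest cannot extrapolate beyond the
training response range (assignments for values outside it concentrate on
the range boundary); the Sr–O independence assumption in the joint
posterior ignores any shared environmental driver; the flat prior ignores
habitat; and exact-coordinate site grouping in
`site_variability_diagnostics()` uses a 1e−6 degree tolerance, which is a
float round-trip guard, not a spatial clustering method.
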