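---
title: "Minimum density and habitat selection from mountain transect surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum density and habitat selection from mountain transect surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bharal)
```

## The problem

Total counts along walked transects are the workhorse of mountain-ungulate
monitoring: observers scan the terrain around ridgeline and valley routes
and record every group of animals they see, with the distance from the
transect, the group size, and a sex/age breakdown where possible. Two
questions follow from such data:

1. **How many animals are there?** A conservative *minimum density* is the
   number of individuals counted divided by the surface that was actually
   visible to the observers — not the full buffer around the routes, since
   mountain terrain hides much of it.
2. **Which habitats do the animals select?** A *used-available* design
   contrasts the covariates at sighting locations with those at available
   locations sampled from the same surveyed area, fitted here with a
   weighted binomial generalized additive model (GAM).

`bharal` implements both estimators together with everything they need:
terrain covariates from a DEM, line-of-sight viewsheds, NDVI-based
land-cover calibration, distance-weighted pseudo-absence sampling, and
permutation-based variable importance. A synthetic-landscape generator with
known ground truth makes the whole chain testable without any field data.

## Minimum density

For each buffer radius $r$ (1,000 m and 1,500 m, the maximum sighting
distances used in the field), the visible surface $A_r$ is the union of
single-point viewsheds from observer positions sampled along each transect,
clipped to the Euclidean buffer. With $N_r$ the individuals counted at
locations inside the viewshed,

$$\hat D_r = N_r / A_r .$$

The smaller radius gives the upper bound (smaller, better-scanned area), the
larger radius the lower bound. Because no correction for imperfect
detection is applied, $\hat D_r$ can only undercount: on synthetic data it
equals the realized density exactly under full detection and stays below it
under any detection loss — both properties are exercised in the test suite.

Sight lines are rasterised with Bresenham's algorithm; a target cell is
visible when no intermediate cell rises strictly above the straight line
from the observer's eye (1.7 m above ground) to the target's ground level.
No earth-curvature or refraction correction is applied — at ranges below
1.5 km the curvature drop (< 0.2 m) is far below DEM noise. Observer
spacing defaults to one cell size, approximating continuous movement along
the route. Each observer's sight disk extends two cells beyond the buffer
radius so that cell-centre discretisation never truncates the clipped
union; the result is identical to brute-force per-cell line-of-sight, which
the acceptance suite verifies.

Reported densities are rounded to one decimal with halves up, the
convention of the survey literature this package follows.

## Terrain covariates

All DEM operators use the classical definitions: Horn's 1-2-1 kernel for
slope and aspect (aspect is folded to *deviation from south*,
$\min(|a-180|, 360-|a-180|)$, so a circular variable never meets a smooth
term), Riley's terrain ruggedness index, strict cliff rules (slope > 45°,
8-connected component area > 90 m²), and D8 hydrology (sink filling,
steepest-descent flow directions with deterministic lowest-code
tie-breaking, upstream-cell accumulation, threshold stream extraction with
a default drainage area of 0.5 km²). Flats left by sink filling are
resolved by a breadth-first sweep from spill and border cells, which is the
logical equivalent of filling with an infinitesimal gradient toward the
spill but avoids floating-point epsilons. Distance surfaces are exact
Euclidean distances from cell centres to the nearest feature geometry
(points and polylines) or, for rasterised features such as cliffs and
streams, an exact two-pass distance transform.

## The used-available design

* **Availability region.** Available points live in the 1,500-m viewshed —
  the same surface the observers scanned.
* **Distance weighting.** Sightings decline with distance from the
  transect. To keep availability comparable, 50,000 uniform candidate
  points are thinned *without replacement* with probability
  $\propto e^{-\lambda d}$, where $\lambda$ is the maximum-likelihood rate
  $1/\bar d$ of the observed distances. 100 available points are drawn per
  observation. Without-replacement sampling reproduces the exponential law
  when the sampling fraction is small; at large fractions the inclusion
  probabilities flatten slightly, which is inherent to the design.
* **Group-size attribution.** If group size is uncorrelated with distance
  (two-sided Pearson test, $p \ge 0.05$) observed sizes are attributed to
  available points by resampling; otherwise an OLS fit of size on distance
  supplies them, rounded to the nearest integer (halves up) and floored
  at 1 — the model is silent on non-integer predictions, so the nearest
  whole animal is used.
* **Adult weighting.** Each observation is weighted by its adult count,
  rescaled so presence weights sum to the number of observations (weighting
  must not inflate the sample size). Unclassified individuals contribute
  via the dataset-level ratio of adults among classified individuals; the
  ratio is global rather than per-group because single-group ratios are
  unstable at small sizes. Pseudo-absence weights are proportional to their
  attributed adult counts and rescaled to the same total.
* **Collinearity screen.** Variables are walked in retention priority
  order; a variable is dropped when its absolute Pearson correlation with
  an already-kept variable reaches 0.7. Slope takes priority over terrain
  ruggedness and distance-to-settlement over livestock presence, matching
  the comparability and completeness arguments usual in this literature.
* **Forest exclusion.** Presences classified as forest are dropped by
  default (sighting probability under canopy is not comparable); the
  toggle reproduces the corresponding sensitivity variant.

The GAM is binomial with logit link, one penalized thin-plate smooth per
continuous covariate (basis dimension 10 by default) and a linear term for
binary covariates such as livestock presence. Smoothness is selected by
REML — a config choice; GCV is available through the `method` argument.
Fitting is delegated to mgcv; the summary surface reports per-smooth edf,
reference df, chi-square and p, per-categorical coefficient/SE/z/p,
deviance explained and adjusted R².

## Variable importance

Importance follows the randomization idea common in species-distribution
modelling: permute one covariate's column, predict, and correlate the
perturbed predictions with the originals; raw importance is one minus the
mean correlation over 100 permutations, and raw values are standardized to
sum to one. The model is *not* refitted by default — the phrase
"predictions made by the randomized model" is read as predictions under
randomized inputs — but a refit mode exists because the alternative reading
is defensible; the choice is recorded in the result's metadata.
Correlations are computed on the probability scale (link scale available).

## The synthetic landscape and what it does (not) show

The generator emulates a dry Trans-Himalayan study area:

* DEM: planar north-south ramp + oriented Gaussian ridges + smoothed noise,
  rescaled to 2,870–6,150 m; with no ridges and no noise it degenerates to
  an analytic ramp used to validate the terrain operators.
* NDVI: piecewise-linear in elevation (forest ≈ 0.65 below ~4,000 m,
  grass/shrub 0.45→0.28 to 4,800 m, barren/snow below 0.14 above) plus
  Gaussian noise (sd 0.03), clamped to [−1, 1].
* Population: groups placed by an inhomogeneous point process with
  log-intensity peaked on the preferred elevation band [4,250, 4,550] m
  (coefficient 3) and the grass/shrub NDVI band (coefficient 1.5); true
  density 7 individuals/km²; zero-truncated negative-binomial group sizes
  (mean 14.4, dispersion 0.92 — derived from a reported standard error of
  1.3 at 143 groups — maximum 113); class mix 25/45/30 % adult male/adult
  female/subadult with 15 % of individuals masked as unclassified.
* Survey: 60 ridge/valley transects of ~2.1 km; per-group detection
  $e^{-0.0035 d}$ truncated at 1,500 m, optionally gated by line-of-sight.

The model-recovery replicates run on a 14.4 × 14.4 km landscape at 90-m
resolution (the terrain operators are resolution-general; 30 m is the
default elsewhere), sized so that a replicate finishes in seconds while
still yielding a realistic 20–50 sightings. What passing recovery tests
show is that the estimation chain finds the truth *it generated*: smooth
unimodal selection, exponential detection, closed viewsheds. Real data add
observer heterogeneity, double counting, spatial autocorrelation of groups,
NDVI seasonality and DEM error, none of which the generator emulates — so
the tests validate the implementation, not the field design.

## Numerical choices and edge cases

* Smooth-term maxima ("preferred elevations") are evaluated over the
  central 90 % of the presence-supported covariate range: penalized splines
  are unreliable under extrapolation, a preference statement only makes
  sense where animals were actually observed, and a single stray sighting
  does not extend that support.
* Rank-sum tests (land-cover NDVI separation) use midranks with exact
  enumeration up to a combined n of 20 (valid under ties) and a tie- and
  continuity-corrected normal approximation beyond.
* Cell membership uses half-open intervals; points on a cell's west/north
  edge belong to that cell.
* D8 ties go to the lowest direction code; tests pin this convention.
* Degenerate inputs error early and loudly: empty observation tables, zero
  adult totals, all-forest presences, constraint bands outside the DEM,
  candidate pools smaller than the requested pseudo-absence sample.
* `fill_sinks` is the identity on sink-free inputs including flats, and
  idempotent always.

## Known limitations

* No detection-probability correction (by design: the estimator is a
  minimum) and no distance-sampling machinery.
* No spatial autocorrelation terms in the GAM; observations are treated as
  independent, as fission–fusion group dynamics are usually argued to
  justify.
* Planar metric coordinates only; reprojection and geodesy are out of
  scope.
* The stream network is purely accumulation-derived; real networks need
  ground-truthing.

## A worked miniature

```{r example, eval = FALSE}
st <- simulate_study(seed = 1)
cfg <- pipeline_config(dem = st$dem, ndvi = st$ndvi,
                       transects = st$transects, observations = st$obs,
                       features = st$features,
                       params = list(n_reps = 25), seed = 1)
res <- run_pipeline(cfg)
res$density          # minimum-density bounds at 1,000 / 1,500 m
res$fit              # GAM summary: edf / chi-square / p per smooth
res$importance       # standardized permutation importance
smooth_peak(res$fit, "elevation",
            range = range(res$frame$elevation[res$frame$response == 1]))
```

The same quantities, measured over many seeded replicates, are what
`scripts/acceptance.R` reports.
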