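# bharal

Minimum-density estimation and habitat-selection modelling for total-count
transect surveys of mountain ungulates — built around the blue sheep
(*Pseudois nayaur*, "bharal"), the Himalayan caprid that sustains snow
leopard populations, but applicable to any species surveyed by walked
transects in open terrain.

## What it computes

**Minimum density.** Counts from transects only cover what observers could
see. The package computes line-of-sight viewsheds around the transects on a
DEM, clips them to the 1,000-m and 1,500-m sighting buffers, and estimates

> density = individuals counted inside the viewshed / visible area (km²),

a deliberately conservative bound (no detection correction), reported to
one decimal with halves rounding up. The two radii give the upper and lower
limits.

**Habitat selection.** A used-available design contrasted with a weighted
binomial GAM (mgcv):

- available points: 50,000 uniform candidates in the 1,500-m viewshed,
  thinned without replacement with probability ∝ exp(−λ·distance), λ the
  maximum-likelihood exponential rate (1/mean) of the observed sighting
  distances; 100 points per observation;
- group sizes attributed to available points by resampling, or by an OLS
  fit on distance when the size–distance correlation is significant;
- observations weighted by adult counts (unclassified individuals imputed
  via the dataset-level adult ratio), presence and pseudo-absence weights
  both summing to the number of observations;
- collinearity screen at |r| ≥ 0.7 with explicit retention priorities
  (slope over ruggedness, distance-to-settlement over livestock);
- one penalized smooth per continuous covariate, linear terms for binary
  ones, REML smoothness selection;
- permutation variable importance: 1 − mean correlation between original
  and permuted-input predictions over 100 permutations, standardized to
  sum to 1.

Everything upstream is included: Horn slope/aspect, deviation from south,
Riley's terrain ruggedness, cliff components, D8 sink filling / flow
direction / accumulation / stream extraction, exact Euclidean distance
surfaces, NDVI land-cover calibration with rank-sum class separation, and a
synthetic mountain-landscape generator with known ground truth (selection
function, group sizes, detection law) that makes the entire chain testable
offline.

## Worked example

```r
library(bharal)

st <- simulate_study(seed = 1)          # landscape + population + survey
cfg <- pipeline_config(dem = st$dem, ndvi = st$ndvi,
                       transects = st$transects, observations = st$obs,
                       features = st$features,
                       params = list(n_reps = 25), seed = 1)
res <- run_pipeline(cfg)

res$density
#>   season buffer_radius_m individuals_counted visible_area_km2 density_ind_per_km2 density_reported
#> 1 spring            1000                 310         124.4241            2.491479              2.5
#> 2 spring            1500                 324         145.2249            2.231022              2.2

res$fit
#> habitat_gam: n = 2762 (27 presences), deviance explained 46.6%, adj. R2 = 0.450
#>                     term  edf ref_df  chi_sq      p
#> 1           s(elevation) 3.23   4.04 8.22397 0.0838
#> 2           s(slope_deg) 2.22   2.82 2.35671 0.4608
#> 3 s(south_deviation_deg) 1.00   1.00 1.25190 0.2632
#> 4   s(dist_settlement_m) 1.00   1.00 0.00106 0.9741
#> 5       s(dist_stream_m) 1.00   1.00 0.01677 0.8970
#>                 term coefficient       se         z     p
#> 1        (Intercept)       -2.13 1.10e+00 -1.94e+00 0.052
#> 2 livestock_presence      -64.04 5.19e+07 -1.23e-06 1.000

head(as.data.frame(res$importance), 3)
#>              variable        raw standardized
#> 1           elevation 0.81961381   0.75859628
#> 2           slope_deg 0.15895361   0.14712004
#> 3 south_deviation_deg 0.05336647   0.04939352

pe <- res$frame$elevation[res$frame$response == 1]
smooth_peak(res$fit, "elevation", range = quantile(pe, c(.05, .95)))
#> [1] 4397.852
```

The density rows are the upper (1,000 m) and lower (1,500 m) minimum-density
bounds for the simulated survey — deliberately below the generating
7 ind/km² because detection declines with distance. The GAM summary mirrors
the usual habitat-selection table (edf / reference df / chi-square / p per
smooth, coefficient / SE / z / p for the binary livestock term, whose huge
SE here flags complete separation: none of these 27 sightings fell inside a
livestock buffer). The importance table says which covariate drives the
fitted selection — elevation, exactly how the population was generated —
and the elevation smooth peaks at 4,398 m, inside the generating
preference band of 4,250–4,550 m.

The published Manang 2019 survey totals ship with the package:

```r
sv <- manang_survey_summary()
with(sv[sv$season == "spring", ],
     density_estimate(individuals_1000m, visible_area_1000m_km2))
#>   season buffer_radius_m individuals_counted visible_area_km2 density_ind_per_km2 density_reported
#> 1   <NA>              NA                1387              180            7.705556              7.7
```

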