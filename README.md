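# craneRSF

Habitat-selection analysis for wintering sandhill cranes — and, more
generally, for any telemetry study using a matched used–available
(case-control) design with cluster-robust inference. The package implements
the complete pipeline from raw GPS fixes to fitted selection models,
cross-validated predictive scores and prediction surfaces, together with
synthetic landscape / river / telemetry / multispectral generators whose
data-generating process matches the selection model, so every estimator
property is testable end to end without field data.

## Who this is for

Quantitative ecologists analysing fourth-order (per-relocation) habitat
selection: which field a bird forages in among those it could have reached,
and which river reach it roosts in, as functions of land use, ownership,
human disturbance, and channel morphology (width, water/sandbar mixture,
bank vegetation height, bridge distance).

## The model

Each used location is matched to 50 available locations drawn uniformly on
the availability disc (radius 6.7 km — the mean maximum movement distance
between successive fixes ≤ 3 h apart, after removing migratory steps
≥ 10 km) intersected with the period mask. With one used row per matched
set (stratum) *s*, conditional logistic regression maximizes

ℓ(β) = Σₛ [ x'ᵤ₍ₛ₎β − log Σⱼ∈ₛ exp(x'ⱼβ) ]

under the GEE independence working model; inference uses the
cluster-robust sandwich A⁻¹BA⁻¹ with per-bird score sums and a g/(g−1)
small-sample factor; model ranking uses QIC = −2Q + 2·tr(ÂV̂ᵣ); predictive
accuracy uses stratum-intact 80/20 case-control k-fold cross-validation
with a rank-binning Spearman statistic r_s. River surface composition per
bi-monthly winter period comes from fully constrained spectral unmixing
(proportions ≥ 0, summing to 1) with NDWI-extracted water endmembers.

## Worked example

```r
library(craneRSF)

landscape <- generate_landscape()                       # 12 x 16 km valley, 88% alfalfa/hay
river     <- generate_river(extent_m = landscape$config$extent_m)
truth     <- true_model()                               # the fitted winter coefficients

tracks <- simulate_tracks(landscape, river, truth,
                          n_individuals = 38, n_days = 20, seed = 42)
ground <- tracks[tracks$altitude <= 50, ]               # flight filter
availability_radius(ground)
#> Availability radius: 6.65 km (SE 0.01 km) over 38 individuals

## matched 1:50 strata straight from the selection model (for telemetry,
## use partition_diel() + build_strata() on the diurnal fixes instead)
strata <- simulate_strata(landscape, truth = truth, period = "diurnal",
                          n_clusters = 38, strata_per_cluster = 150, seed = 7)
fit <- fit_clogit(strata, ~ landuse + ownership + dens500)
fit
#> Conditional logistic fit: 5700 strata, 38 clusters, converged in 8 iterations
#>                    estimate robust_se      z        p
#> landusecorn          0.7874    0.0576  13.67 1.53e-42
#> landusefallow       -0.4736    0.1227  -3.86 1.14e-04
#> landusesmall_grain  -0.6861    0.1107  -6.20 5.74e-10
#> landusewetland      -2.5725    0.1966 -13.09 3.99e-39
#> landuseother        -3.9207    1.0088  -3.89 1.02e-04
#> ownershippublic      3.3682    0.0366  92.09 0.00e+00
#> dens500             -0.3704    0.0180 -20.53 1.25e-93
#> Quasi-loglik -17591.617, QIC 35195.815

kfold_cc(strata, ~ landuse + ownership + dens500, reps = 50, seed = 1)
#> Case-control k-fold CV: mean r_s = 0.83 (range 0.71-0.91) over 50 replicates

surf <- predict_surface(fit, diurnal_covariate_table(landscape))
write_ascii_grid(surf$surface, "diurnal_use.asc")
```

Positive coefficients mean selection relative to the reference categories
(alfalfa/hay fields, private ownership): cranes select corn and public
land, avoid structure-dense surroundings — the estimates recover the
generator's true coefficients (corn 0.773, ownership 3.373, density
−0.377) within their robust standard errors. The surface maps exp(x'β̂)
rescaled to [0, 1] over the eligible layer. The track generator is a step
process while the design samples availability around used locations, so
coefficients refit from raw tracks are mildly attenuated relative to the
generator truth (see the methods vignette); `simulate_strata()` is the
design-matched generator and reproduces the coefficients without bias.

Candidate-set selection and the roosting-period model work the same way:

```r
specs <- candidate_models("diurnal")
fits  <- fit_candidates(strata, specs)     # per-model VIF screen at 5
rank_models(fits)                          # QIC, delta, weights
```

## Package layout

- `R/synthetic-*.R` — landscape, river, spectra, tracks and strata generators
- `R/telemetry.R`, `R/design.R` — diel partition, availability radius, strata
- `R/clogit.R` — conditional likelihood, Newton fitter, sandwich, QIC, VIF
- `R/model-selection.R`, `R/crossval.R`, `R/prediction.R` — candidate sets,
  QIC ranking, case-control k-fold CV, use surfaces
- `R/sma.R` — NDWI, endmember extraction, constrained unmixing, composites
- `vignettes/habitat-selection-methods.Rmd` — the full methods account
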