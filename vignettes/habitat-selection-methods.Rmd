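---
title: "Methods: matched used-available habitat selection for wintering cranes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched used-available habitat selection for wintering cranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

Wintering sandhill cranes partition their day sharply: daylight hours are
spent foraging and loafing on agricultural fields and wetlands, and nights
are spent standing in the shallow, braided channel of a river. `craneRSF`
implements the complete fourth-order habitat-selection analysis for this
system from GPS telemetry: which fields a crane chooses among those it could
have reached, and which river reaches it chooses to roost in, as functions
of land use, land ownership, human disturbance, and channel morphology.

The design is a matched case-control (used-available) design. Each GPS fix
(the *used* location) is matched to 50 *available* locations drawn uniformly
from the disc of the availability radius around it, intersected with the
period's habitat mask -- any agricultural field, pasture or wetland for the
diurnal period, the river's active channel for the roosting period. Each
matched set is a *stratum*; each bird is a *cluster*.

## Diel partitioning and the flight filter

Fixes between 07:00 and 18:00 (exclusive) are diurnal; fixes inside the
channel at or after 18:00 or at or before 07:00 are roost fixes. A 07:00
fix inside the channel is a bird that has not yet left its roost, and is
assigned to the roosting period. Fixes with altitude above ground exceeding
50 m are excluded as in-flight records. The transmitters' altitudinal
accuracy is about ±22 m, so 50 m is a little over twice the accuracy band;
the threshold is a package default (`study_constants()$flight_alt_m`), not
a value inherited from the field study, which screened spurious altitudes
against aerial imagery. Fixes with missing altitude cannot be screened and
are routed to a needs-review set rather than silently kept.

## Availability radius

The radius is the mean, over birds, of each bird's maximum movement
distance between successive fixes, after discarding steps of 10 km or more
(migratory arrivals and departures) and steps whose elapsed time exceeds
3 h (movement paths too uncertain between sparse fixes). On the study's
telemetry this gives 6.7 km (the `longer_gaps = TRUE` variant,
complementary steps, gives 5.8 km); 6.7 km is the package default
(`study_constants(radius_m = 6700)`). In the synthetic generator every step
is a single draw within a 6.7 km disc, so the measured radius on simulated
tracks comes out slightly below the design constant (about 6.6 km -- the
maximum of a few hundred disc draws), and the `longer_gaps` variant is not
meaningfully smaller, because the generator does not model time-scaled
diffusion between fixes.

## Covariates and their units

Diurnal rows carry the land-use class (reference level: alfalfa/hay),
ownership (reference: private), distance to the nearest human structure
(km), and the count of structures within 100, 500 and 1000 m
(boundary-inclusive). Roost rows carry the active-channel width at the
nearest centerline station (no interpolation -- the stations sit at the
~30 m sampling resolution, so interpolating would manufacture precision),
the water / sandbar / vegetation proportions of the 30 m pixel from the
period-matched composites, the mean bank-vegetation height over 10 m bank
cells (within 50 m of the channel) inside along-channel windows of ±50,
±250 and ±500 m around the point's centerline projection, and distances to
the nearest bridge and structure (km).

Continuous covariates are expressed in fixed commensurate units -- channel
width in units of 100 m, distances in km, proportions and heights on their
natural scales -- so that coefficients are of comparable magnitude without
any data-dependent rescaling. Z-scoring (`build_strata(standardize = TRUE)`)
is available and stores its transform for prediction, but it is off by
default: the synthetic data-generating process and the fitted model must
share a single covariate scale for parameter-recovery testing, and with
interaction terms a row-statistic z-score is an affine reparameterization
that breaks the direct coefficient comparison.

With no structures on the map, the distance-to-structure covariate takes
the landscape diagonal as a finite sentinel (recorded in the annotation's
attributes) so fits remain defined.

## The conditional likelihood, GEE inference and QIC

Within stratum $s$ the probability that the used row is the observed one is
the softmax of the linear predictors, giving the conditional log-likelihood

$$\ell(\beta) = \sum_s \Big[ x_{u(s)}'\beta - \log \sum_{j \in s}
  \exp(x_j'\beta) \Big].$$

Stratum intercepts cancel, so anything constant within all strata is not
identified (the fitter rejects such columns with a diagnostic).
Newton-Raphson with step-halving maximizes $\ell$; convergence is declared
when the maximum absolute score falls below `tol` (default 1e-8, at most 50
iterations, up to 10 halvings). The step-acceptance comparison is
scale-aware (`(|l| + 1) * 1e-10`), because near the optimum the true
improvement falls below the floating-point resolution of a log-likelihood
in the tens of thousands. Rank-deficient designs and separation are
reported as errors; separation is detected both from diverging coefficients
and from saturated fits that predict every used row perfectly, where the
score vanishes numerically although the MLE does not exist.

Estimation runs under the GEE independence working model (the conditional
likelihood treating strata as independent); inference corrects for
within-bird dependence with the cluster sandwich
$A^{-1} B A^{-1}$, $B = \frac{g}{g-1} \sum_c U_c U_c'$, where $U_c$ sums
per-stratum scores over the strata of bird $c$ and $g$ is the number of
birds. No working-correlation matrix is iterated. Model comparison uses the
Quasi-likelihood under Independence Criterion in the Pan (2001) form,
$QIC = -2\,Q(\hat\beta) + 2\,\mathrm{tr}(\hat A \hat V_r)$ with $Q$ the
independence conditional log-likelihood; the variant is recorded in the fit
metadata because other QIC variants exist and the criterion's absolute
values are variant-specific. Candidate models are screened per model with
variance inflation factors on the one-hot design columns
($VIF_k = 1/(1-R_k^2)$, exclusion at 5); a generalized VIF for factor
blocks is out of scope.

## Cross-validation

Predictive accuracy uses case-control k-fold cross-validation: 80% of
strata (kept intact) train the model, the rest validate it; within each
validation stratum all 51 rows are ranked by linear predictor (ascending,
ties broken uniformly at random with the replicate RNG) and the used row's
rank is recorded; ranks are tallied into 51 bins and the replicate
statistic $r_s$ is the Spearman correlation (average ranks for ties)
between bin index and bin frequency. Ascending rank direction means a
predictive model loads the high bins and $r_s$ is positive. Replicates
whose training fit fails to converge are skipped and counted.

Two properties of this statistic matter for interpreting it. First, its
per-replicate null standard deviation is about $1/\sqrt{S-1}$ (it is a rank
correlation over $S$ bin pairs), independent of how many validation strata
fill the bins. Second, replicates on one dataset share that dataset's
sampling noise, so the mean over replicates converges to a dataset-level
value, not to the population value; null-behavior checks therefore average
the whole procedure over independent synthetic datasets.

## Prediction surfaces

`predict_surface()` evaluates $\exp(x'\hat\beta)$ per grid cell over the
period's domain (eligible mask, or active channel with period-matched
proportion rasters). Relative probability of use is defined only up to a
positive factor in a used-available design, so the raw exp-scores are
returned alongside a min-max rescale to [0, 1] chosen for display
comparability (the rescale is invariant to the positive factor). An
all-equal surface rescales to 0 by convention; cells outside the domain are
NA.

## Spectral mixture analysis

River surface composition comes from fully constrained linear unmixing of
each 30 m pixel into water, sandbar and riparian vegetation proportions:
minimize $\|E'p - s\|^2$ subject to $p \ge 0$, $\sum p = 1$. With three
endmembers the exact optimum is found by support enumeration -- solving the
sum-to-one equality-constrained least-squares problem on each non-empty
endmember subset and keeping the feasible solution with the smallest
residual -- which is verified against a two-stage simplex grid search in the
tests. Water endmembers are extracted from pixels at or above the 98th
percentile of NDWI $(G - NIR)/(G + NIR)$ (linear-interpolation quantile,
declared because percentile conventions differ); sandbar and vegetation
endmembers from static monotypic regions. Bi-monthly composites are
per-pixel means over cloud-mask-valid observations.

## The synthetic study system

The generator reproduces the analysis-relevant structure of the study
system, with all randomness a pure function of (config, seed):

* **Landscape** -- a 12 x 16 km valley gridded at 30 m; axis-aligned
  rectangular fields (mean edge 400 m, which doubles as the mosaic's
  spatial autocorrelation scale) filled by greedy area quotas to the target
  composition of 88% alfalfa/hay with corn, fallow, small-grain, wetland
  and other patches; a western public-ownership band holding 20% of the
  area, into which wetland fields are preferentially placed; clustered
  human structures from a Thomas process (20 parents, mean 8 points,
  150 m dispersion). The 12 km cross-valley width keeps every field within
  commuting reach of the river, matching the elongated floodplain geometry
  of the study area; on a wider landscape, birds foraging at the far edge
  would have no channel pixel within the availability radius at dusk.
* **River** -- a sinuous north-south centerline with stations every 30 m;
  smoothly varying active-channel width in 40-220 m; per-period
  water/sandbar/vegetation fields with sum-to-one closure (water in the
  thalweg, sandbars mid-lateral, vegetation toward the banks, independent
  smooth perturbations per bi-monthly period); a 10 m bank-height raster
  within 50 m of the channel whose heights fall with channel width (narrow
  incised reaches carry tall woody vegetation); bridges every 6 km.
* **Tracks** -- seven fixes per bird-day at 07:00, 08:00, 10:00, 14:00,
  16:00, 18:00 and 24:00; 38 birds and 58 days reproduce the ~406 fixes
  per bird of the study data. Diurnal fixes are drawn from eligible cells
  within 6.7 km of the previous fix with probability proportional to
  $\exp(x'\beta)$; evening, midnight and (with probability 0.5) 07:00
  fixes come from channel pixels under the roost coefficients. Two percent
  of fixes are in-flight records with altitudes of 60-300 m and a hidden
  truth flag, so the flight filter is testable.
* **Strata** -- `simulate_strata()` generates matched sets directly: 51
  candidate locations uniform on disc-and-mask, the used one chosen by
  softmax. This *is* the conditional-logit data-generating process, so
  estimator properties (recovery, coverage, QIC selection) are tested
  against it exactly.
* **Spectra** -- Dirichlet proportions times Landsat-8-like endmember
  spectra over six reflective bands plus Gaussian noise.

One distinction deserves emphasis. The track generator is a *step*
process: each fix is selected from the disc around the previous fix. The
matched design, following standard practice for this kind of analysis,
samples availability around the *used* location. These two availability
definitions differ wherever covariates are spatially clustered, so
coefficients refit from tracks through the used-centered design are mildly
attenuated relative to the step-process truth (about 20% for the strongest
coefficient, ownership). This is a property of used-centered availability
under movement constraint, not an estimator defect -- the design-matched
generator recovers the same coefficients without bias. Coefficient-
reproduction checks therefore run against `simulate_strata()`; the track
pipeline is validated for its qualitative selection behavior, the diel
partition, and the availability radius.

What passing these tests does *not* show about real data: the generator
has no GPS positional error, no habitat boundaries crossing a 30 m cell,
no temporal autocorrelation beyond the step constraint, no crop rotation
or hydrological change within a winter, and its covariate fields are
smoother than real landscapes. Results on synthetic data certify the
estimator and the pipeline plumbing, not ecological conclusions.

## Simulation-study sizes

Replicated studies are sized to keep the whole verification suite within a
desktop run while preserving estimator regularity (rare land-use classes
need enough used events for a finite MLE; at the chosen sizes the "other"
class averages 4+ events per replicate):

* parameter recovery: 100 replicates of 38 clusters x 150 strata;
* robust-Wald coverage: 200 replicates of 38 x 10 under the
  ownership + density model (regular at small n);
* QIC selection: 100 replicates of 38 x 30, generating model vs an
  over-parameterized alternative with three spurious covariates;
* cross-validation: null behavior averaged over 5 independent datasets
  (38 x 4 strata, 40 replicates each); strong-selection behavior on
  38 x 40 strata with 200 replicates;
* coefficient reproduction: 5 independent datasets per period (38 x 150
  diurnal, 38 x 40 roost), each published coefficient within 2 robust SE
  in a majority of datasets. A joint one-draw check over 17 coefficients
  would fail about half the time even for a perfectly calibrated
  estimator, which is why the majority rule is used.

With 38 clusters, a "2 robust SE" interval behaves like a t-interval with
about 37 degrees of freedom (per-replicate hit rate near 94.7%, not the
Gaussian 95.45%); the recovery thresholds account for this.

## Known limitations

* The availability radius variants coincide on synthetic tracks (no
  time-scaled movement model).
* Bank-height cells are attributed to their nearest centerline station, so
  along-channel windows are resolved at station spacing (~30 m).
* The VIF screen treats one-hot columns individually.
* The roost model's interaction block (width x sandbar x water with the
  sum-to-one closure of the proportions) is strongly collinear by
  construction; its robust Wald intervals are mildly liberal in finite
  samples, visible in the coverage studies.
* No model averaging is provided, by design: the candidate sets are
  non-orthogonal and contain interactions.
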