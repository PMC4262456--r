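---
title: "From tracks and transects to multi-taxa hotspot maps: methods"
author: "hotspotr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From tracks and transects to multi-taxa hotspot maps: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotspotr)
```

## The problem

Marine predators in tropical waters concentrate around patchy, dynamic
oceanographic features. Identifying the areas that several predator taxa
share — candidate conservation hotspots — requires reconciling very
different data sources: satellite tracking of a focal central-place
forager, and vessel- or aircraft-based strip-transect counts of several
taxa. `hotspotr` implements one complete, reproducible path from those raw
inputs to model-averaged presence-probability maps, per-taxon suitability
layers, a multi-taxa suitability index, and pairwise overlap statistics.

All data are standardized onto a common 0.25° monthly grid, the coarsest
resolution among typical satellite covariates, so that heterogeneous
observations become comparable cell/month records.

## The statistical model

The response is binary presence/absence per grid cell and month. For each
taxon we fit random-intercept binomial GLMMs

$$\mathrm{logit}\, \Pr(y_{ij} = 1) = \beta_0 + \mathbf{x}_{ij}^\top
\boldsymbol\beta + b_j, \qquad b_j \sim \mathcal N(0, \sigma^2),$$

where $j$ indexes the grouping unit — a foraging trip for tracking data, a
survey campaign for at-sea observations — and $\mathbf{x}$ holds
z-scored environmental covariates: chlorophyll-a concentration (mg m⁻³),
sea surface temperature (°C), sea level anomaly (cm), bathymetry (m),
distance to the colony (km), and the spatial gradients of the field
variables (Horn 3×3 slope, per-km units, with the zonal cell size
corrected for latitude). Fitting uses maximum likelihood with adaptive
Gauss–Hermite quadrature (15 nodes by default, configurable) via
`lme4::glmer`; the random-effect variance counts as one parameter in the
AIC penalty, so `AIC = -2 logLik + 2 (p + 1)`.

Model building follows an information-theoretic strategy:

1. **Normalization.** Covariates are centered and scaled (mean 0, SD 1);
   the constants are stored and reapplied at prediction time.
2. **Collinearity screen.** Variable pairs with Spearman |r| > 0.6 are
   resolved in decreasing |r| order by keeping the member whose univariate
   GLMM has the lower AIC.
3. **Shape screen.** A quadratic effect replaces the linear one only when
   it improves the univariate AIC by at least 2 points; otherwise the
   simplest effect is kept (boundary inclusive).
4. **All-subsets fitting.** Every subset of the retained variables is
   fitted (2^k models including the intercept-only model, capped at
   k = 12), ranked by AIC, and given Akaike weights
   $A_w = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$.
5. **Confidence set and averaging.** If the best model's weight reaches
   0.90 it is used alone; otherwise the smallest AIC-ordered prefix with
   cumulative weight above 0.95 forms the confidence set, weights are
   renormalized, and coefficients are averaged with zero substitution
   (a variable absent from a model contributes 0), which deliberately
   shrinks rarely selected effects toward zero. Conditional averaging is
   not offered because zero substitution is the conservative choice for
   prediction, which is how the averaged model is used downstream.
   Presence probability is $P_r = \mathrm{logit}^{-1}(\hat\beta_0 +
   \mathbf{z}^\top \hat{\boldsymbol\beta})$.

AIC rather than AICc is the default criterion (an `aicc` flag is
available); with thousands of cell/month records per model the difference
is negligible.

## Data preparation

**Tracking data.** ARGOS-grade positions are cleaned with an iterative
forward/backward speed filter: while any consecutive pair implies a
great-circle speed above 65 km h⁻¹, the position adjacent to a violating
segment with the largest combined backward + forward speed is removed
(first on ties; the first fix never). This removal rule is one
deterministic, idempotent reading of the classic iterative filter, whose
published description leaves the removal order open. Trips are maximal
runs of fixes farther than 5 km (configurable) from the colony; fixes
after the last colony return are non-breeding, the rest breeding. Dense
GPS tracks can be randomly thinned to the 1.57 h mean ARGOS cadence so
device types are comparable. Kernel utilization distributions use a
bivariate Gaussian kernel with `h` = 0.5, interpreted as degrees on the
lon/lat plane since no unit convention is attached to the smoothing
parameter in common usage; contour masks at 25/50/75/95% are the smallest
sets of highest-density cells reaching each mass.

**Presence and pseudo-absence.** Each inter-fix interval is allocated to
the cell of its midpoint; any cell with positive occupancy time is a
presence for that trip. We deliberately use *any* positive time rather
than a minimum-dwell threshold — the choice is exposed, not hidden, and a
threshold can be imposed upstream by filtering the occupancy table. Per
trip, an equal number of pseudo-absences is sampled uniformly without
replacement from cells within 1000 km of the colony that the trip did not
cross; pool exhaustion falls back to the whole pool with a warning.

**Survey data.** Strip-transect bins (10 min at 10 kn over a 500 m band,
about 1.54 km² of effort each) are aggregated per cell, month, year and
campaign: density is total count over total effort, and the binary
response records whether at least one individual was seen. Aggregation
retains the campaign key so the random intercept remains defined when two
campaigns cross the same cell in the same month. Only September–December
records feed the models by default (the breeding window), via a
configuration filter rather than hard-coding.

**Covariates** are read from the monthly layer matching each row's
month/year at the cell center; rows with any missing covariate (e.g.
cloud-masked chlorophyll) are dropped with a logged count. Distances are
great-circle (haversine, Earth radius 6371 km) throughout.

## Evaluation and mapping

Discrimination is measured by the rank-based AUC (Mann–Whitney with ties
counted ½) with the usual qualitative bins (≥0.9 excellent, ≥0.8 good,
≥0.7 moderate, ≥0.6 poor, else unsuccessful). Cross-validation refits
every confidence-set model on a random 70% of the occurrence table
(stratified by response so both classes appear on both sides),
re-averages with weights recomputed from the training AICs, and scores
AUC on both parts; the default is 1000 replicates, summarized by mean, SD
and a percentile 95% CI (2.5/97.5 quantiles — the CI construction is a
package choice; a normal-approximation interval would be similarly
defensible). A model is *transferable* when the lower CI limit of the
test AUC excludes 0.5. The split is applied to the model-building table;
evaluation against a fully independent table (e.g. non-breeding trips or
held-out years) is available by passing that table instead.

The ROC threshold `P_th` maximizes sensitivity + specificity over all
distinct score values (ties to the lowest threshold, `≥` counting as
presence). Yearly suitability layers binarize each taxon's seasonal
(September–December) mean probability — strictly *above* `P_th` counts as
suitable, a wording-level choice documented because many ROC tools use
`≥`. The multi-taxa index is the cell-wise sum of the four binary layers
(0–4); its across-year mean and SD, and the cell-wise SD of monthly
predictions (the habitat-stability index), quantify persistence.
Pairwise overlap defaults to the literal shared-cell convention
$|A \cap B| / (|A| + |B|)$, which is bounded by 0.5 and equals 0.5 for
identical ranges; a Jaccard variant $|A \cap B| / |A \cup B|$ is
available by flag because the verbal definition ("cells where both taxa
were present divided by the sum of cells where these taxa were present")
admits both readings.

## The synthetic seascape and its limits

The generator emulates just enough structure for the pipeline's
assumptions to be exercised with known truth:

- smooth spatially autocorrelated fields (white noise filtered with a
  separable Gaussian kernel, then re-standardized) rather than a
  geostatistical simulator — autocorrelation is what matters, not the
  variogram family;
- SST with a monotone latitudinal trend, SLA with ≥2 closed mesoscale
  (eddy-like) anomalies per month, strictly positive log-normal
  chlorophyll, and a time-invariant bathymetry with a shallow shelf
  margin decaying to a ~4000 m interior;
- central-place-forager tracks with a commute–forage–return trip
  structure: each trip targets a remembered foraging site drawn with
  probability proportional to suitability among reachable cells (these
  birds are documented memory-based foragers), commutes toward it at
  5–25 km h⁻¹ with persistent headings, then switches to area-restricted
  search (low persistence, 3–12 km h⁻¹) before a directed return to the
  colony; every realized step is additionally selected among candidate
  steps with probability proportional to the inverse-logit of the true
  coefficients at the candidate's cell. Fix intervals are truncated-gamma
  with mean 1.57 h. The literature fixes no movement model for this
  system; this stand-in is the simplest process whose per-cell occupancy
  demonstrably tracks suitability despite the central-place constraint
  (transit in and out of the colony is habitat-blind, which otherwise
  swamps the selection signal with a distance-to-colony gradient).
  Optional ARGOS-like outliers are displaced ≥700 km so both
  adjacent segments exceed 65 km h⁻¹, while staying within the foraging
  range;
- strip-transect surveys whose per-bin presence is Bernoulli with a
  campaign random intercept; covariates are z-scored over the realized
  bins, so the recorded truth coefficients live on exactly the scale the
  models estimate. Counts given presence are 1 + Geometric (mean 3),
  cosmetic since only presence/absence is modelled.

What the generator does *not* emulate — location error ellipses,
detection failure on transects, spatial autocorrelation of the response
beyond what covariates induce, tides, wind, diel behaviour — bounds what
passing tests demonstrate: parameter recovery shows the estimation
machinery is correct under its own assumptions, not that those
assumptions hold for any particular field dataset.

## Recovery study design and problem sizes

The package's recovery benchmark simulates 20 surveys of 3000 bins (10
campaigns × 300 bins, campaign σ = 0.5) over a 40 × 40-cell seascape with
six candidate covariates, three of them informative (standardized effects
0.8, −0.7, 0.5). Bins are spaced ~40 km so each occupies its own 0.25°
cell, keeping the bin-level generative model identical to the cell-level
estimand; with contiguous 10-min bins several bins share a cell and the
aggregated response follows a complementary-log-type inflation of the
per-bin model, which is a property of aggregation, not an estimation
error. The benchmark fits linear effects throughout — the generating
model is linear, mirroring the simplest-effects outcome of the shape
screen, which has its own dedicated tests on curved and straight
simulated responses. Mean bias on each standardized coefficient and per-replicate sign
recovery are the reported quantities, alongside cross-validated test AUC
(50 replicates on one study dataset) and null studies with
intercept-only truth. Desk-scale demonstration runs
(`demo_config()`) use smaller sizes — two years, four campaigns of 120
bins, 25 cross-validation replicates — chosen so the whole pipeline,
including four taxon models and the overlap matrix, completes in a few
minutes on one core.

## Numerical choices and degenerate inputs

- `glmer` runs with the `nloptwrap` (BOBYQA) optimizer and derivative
  checks off, which reproduces the default AICs to well below the 2-point
  resolution the selection rules use while being several times faster;
  non-convergence and |coefficient| > 15 (a separation guard) flag a
  model, and flagged models are excluded from ranking with a warning
  rather than aborting a run.
- Zero-variance covariates, single-class responses, single groups, empty
  position sets, degenerate bounding boxes and zero-effort cells all
  raise immediate, named errors.
- Ties: ROC thresholds take the lowest tying threshold; the speed filter
  removes the first of tying violators; UD contours break density ties by
  cell id. Weights are renormalized exactly (sums checked to 1e-9 in
  tests).
- Cell membership is half-open `[west, east) × [south, north)`, so edge
  points belong to exactly one cell; cells are indexed 1-based row-major
  from the south-west corner, the natural R convention.
- All stochastic stages take explicit seeds; `run_pipeline` derives
  per-stage seeds from the single configured seed, so runs are bit-wise
  reproducible.

## Known limitations

Interaction terms, spatial-autocorrelation error structures, Bayesian
fitting, distance-sampling detection functions, state-space filtering of
ARGOS errors and conservation-prioritization algorithms are out of scope.
The all-subsets strategy is exponential in the number of variables and
deliberately capped at 12. Layer I/O is plain long-format CSV; no
NetCDF/GeoTIFF bindings are shipped.
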