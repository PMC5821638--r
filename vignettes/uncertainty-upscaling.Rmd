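---
title: "Monte-Carlo uncertainty in two-stage biomass upscaling"
author: "agbUpscale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte-Carlo uncertainty in two-stage biomass upscaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agbUpscale)
```

## The problem

National maps of forest aboveground biomass (AGB, t/ha) are usually built by
calibrating wall-to-wall satellite layers against ground reference data. Two
calibration routes are common. In the *direct* route, the reference is the
national forest inventory (NFI): a sparse network of 1 ha plots, each
measured through four 0.04 ha sub-plots. In the *two-stage* route, the plots
first calibrate airborne-LiDAR canopy metrics along flight strips; the
LiDAR-predicted AGB along the strips — orders of magnitude more "samples"
than there are plots — then calibrates the satellite layers. The second
route is attractive because it multiplies the reference data, but every
LiDAR-AGB sample carries both the field error *and* the stage-1 model
error, and that compounded error propagates into the final map.

`agbUpscale` implements both routes with full Monte-Carlo error
propagation and per-pixel uncertainty surfaces, together with a synthetic
scene generator that emulates the joint structure of the three data sources
so that the whole pipeline is testable end-to-end without any external
data.

## The field-error budget

The relative error of a plot-level AGB estimate is modelled as three
independent random components combined in quadrature:

$$\varepsilon_{field} = \left(\varepsilon_{meas}^2 + \varepsilon_{allom}^2 +
\varepsilon_{samp}^2\right)^{1/2}.$$

Defaults are 10% for stand-level tree measurement and 11% for the
allometric models. The sampling component follows from sub-plot geometry:
160 sub-plots of 0.04 ha are needed to know a 50 ha stand to ±10%, a
sampling intensity of $100 \cdot 160 \cdot 0.04 / 50 = 12.8\%$; at the same
intensity a 1 ha pixel would need $3.2$ sub-plots, so four measured
sub-plots give $10\sqrt{3.2/4} = 8.9\%$. The quadrature total is ≈17%:

```{r budget}
errorBudget()
```

Monte-Carlo realizations of the reference AGB follow the multiplicative
normal model $\widehat{AGB}^{(r)} = AGB \cdot (1 + \varepsilon_{field}
X^{(r)})$, $X \sim N(0,1)$, clipped at zero (at 17% the clip is a ~6-sigma
event, so it is inert at the default settings but guards high-error
configurations). Each realization is drawn from a counter-derived seed
(`deriveSeed(master, "realization:r")`), so realization $r$ is reproducible
in isolation and the ensemble can be generated in any order or in
parallel.

## The learner

The regression engine at both stages is a rule-based model tree in the
M5/Cubist family: recursive binary splitting on SD reduction, a
multivariate linear model at every node, pruning of subtrees that fail to
beat their node's model under a pessimistic $(n+v)/(n-v)$ error
adjustment, and Quinlan smoothing at prediction time — each leaf
prediction is blended with its ancestors' models,
$p \leftarrow (n_{child}\,p_{child} + k\,p_{node})/(n_{child}+k)$ with
$k = 15$. Committee members (off by default) are fitted on
residual-adjusted responses $2y - \hat y$ and averaged. Predictions are
clamped to the training response range extended by 10%, guarding linear
leaves against extrapolation.

The exact internals of the commercial rule-based learners used in the
mapping literature are not published in detail; the M5-with-smoothing
construction here is the documented, deterministic member of that family,
and it sits behind a single `modelTree()`/`predict()` interface so another
learner can be substituted. Design defaults worth knowing:

* `minLeafSize = 8`. Rule-based regression practice lets rules cover few
  cases; small leaves on small calibration sets are also the mechanism
  that makes per-realization fits genuinely diverse, which is exactly what
  the Monte-Carlo ensemble is supposed to expose. Stiffer, fully
  determined leaf models can be had with `minLeafSize = 2 * (p + 1)`.
* Split ties are broken toward the lowest predictor index and lowest
  threshold, so fits are bit-reproducible.
* On noiseless linear data the tree collapses to (effectively) the global
  least-squares model and recovery is exact to rounding; the suite asserts
  hold-out $R^2 \ge 0.999$.
* A split-based learner locates a discontinuity only to the training-point
  spacing. The piecewise tests therefore assert the break location and the
  off-break noise-floor RMSE separately rather than sampling the
  vanishing sliver between the estimated and true break.

## Monte-Carlo upscaling and the uncertainty surfaces

For realization $r$, the learner is fitted on (predictors, response$^{(r)}$)
and applied to the full grid; the $n = 100$ maps form a
`PredictionStack`. Per pixel, the package reports the ensemble mean, the
CI95 half-width $(q_{97.5} - q_{2.5})/2$ from linear-interpolation
empirical quantiles, and the relative uncertainty
$100 \cdot \mathrm{CI95} / \mathrm{mean}$. Pixels whose ensemble mean
falls below 1 t/ha get no relative uncertainty (the ratio degenerates as
the mean approaches zero; observed uncertainties above 200% at low biomass
are exactly this instability). With a pass-through learner the relative
uncertainty converges to $1.96\,\varepsilon_{field}$ — ≈33% at 17% — which
the acceptance suite verifies at $n = 10^4$ and at the study-scale
$n = 100$.

Three scenarios are wired end-to-end in `runScenario()`:

* **`nfi_direct`** — stratified 67% of the slope-filtered plots (ten
  30 t/ha classes) calibrate the satellite layers per realization.
* **`lidar_two_stage`** — plots lying fully inside the LiDAR strips are
  screened for residual outliers (|residual| > 2 SD against a reference
  fit on the un-noised response, the guard against land-cover change
  between acquisitions), then each realization is upscaled to the LiDAR
  metrics (stage 1) and each stage-1 strip map calibrates the satellite
  layers using all strip pixels (stage 2). Realization $r$ of stage 2
  consumes realization $r$ of stage 1 — the composition propagates, it
  does not re-sample.
* **`lidar_two_stage_screened`** — identical, except only strip pixels
  with stage-1 relative uncertainty strictly below 50% train stage 2.

Plots on slopes above 15° never enter any training set, and final surfaces
are masked to forest (tree cover strictly above 10%). Carbon totals use
the 0.48 biomass-to-carbon fraction. Strict inequalities in both masks are
deliberate and tested.

## The synthetic scene

The generator produces a 200 × 200 grid of 1 ha pixels (a 20 × 20 km
scene) whose layers share one master seed through per-component child
seeds; adding a layer never changes another layer's draws, and an
identical `SceneConfig` yields a bit-identical scene.

* **True AGB** — a Gaussian random field with exponential covariance
  (spectral synthesis, correlation length 2 km), rescaled to mean
  45 t/ha, SD 35 t/ha and clipped to [0, 160] t/ha: the regime of a
  mixed dry/tropical forest landscape where histograms peak well below
  the SAR/optical saturation level.
* **Plots** — a 700 m grid (400 plots) with 10 m Gaussian geolocation
  jitter; each plot's four sub-plots sample the true field at the
  (possibly mis-located) plot pixel with independent 10% measurement
  noise, and plot AGB is their mean. At 1 ha pixels the 56.42 m plot
  footprint is sub-pixel, so sub-plot scatter is measurement noise, not
  field variation; a zero-noise, zero-jitter configuration reproduces the
  true pixel value exactly.
* **LiDAR strips** — vertical strips 4 pixels (400 m, an airborne swath)
  wide covering 6% of the scene, as sparse as the scene tolerates while
  keeping at least two strips and a few dozen plots fully inside them.
  Twelve plot-aggregated metrics follow per-metric power laws of AGB with
  noise at 0.8 of the signal SD, i.e. per-metric correlations with AGB of
  roughly 0.75–0.85 — the regime of real canopy metrics. These two
  choices reproduce the structural asymmetry of the real design: a
  few-hundred-strong NFI against a handful of strip plots, and strip
  pixels that outnumber the strip plots by two orders of magnitude.
* **SAR** — HH/HV gamma-nought following
  $A + B(1 - e^{-\alpha\,AGB})$ dB (HV: −22 dB, +10 dB, 0.04 per t/ha,
  saturating near 100 t/ha), multiplied in *linear power* by unit-mean
  gamma speckle with 4 looks and returned in dB. Speckle is never applied
  in the dB domain.
* **Optical** — four bands decaying/saturating exponentially in AGB with
  additive noise; NDVI derived from red/NIR; tree cover a noiseless
  logistic of AGB scaled to [0, 100] (strictly increasing, so the forest
  mask is well defined); altitude from an independent random field with
  slope as its gradient, its 120 m amplitude chosen so that roughly half
  the landscape exceeds the 15° exclusion slope, as in rugged national
  inventories.

What the generator does **not** emulate: temporal mismatch between
acquisitions, spatially correlated field error, allometric-model bias
(only its variance), waveform LiDAR physics, terrain effects on
backscatter, and real geodesy (the grid is planar). Passing tests
therefore demonstrate that the *statistical machinery* — error budget,
propagation, screening, validation — behaves as designed under the stated
data structure, not that any particular real landscape would yield the
same numbers.

## What the simulation reproduces

On the default scene with 100 realizations the three scenarios reproduce
the qualitative findings that motivate the method (timings are minutes on
one core; the problem sizes — 200 × 200 pixels, 400 plots, 100
realizations — are the package's chosen defaults):

* the two-stage map carries substantially higher mean relative
  uncertainty than the direct NFI map (the compounded stage-1 error
  dominates);
* screening the stage-2 training pixels at 50% uncertainty lowers the
  final uncertainty but cannot beat the direct route;
* because the discarded pixels are mostly low-AGB (where relative
  uncertainty blows up), the screened map's AGB histogram shifts toward
  higher biomass, and its carbon total rises accordingly;
* tree-ensemble predictions compress the histogram tails: held-out
  extreme plots are pulled toward the training mean in both directions.

The absolute uncertainty levels depend on the synthetic study conditions
(plot density, metric strength, strip coverage) and are not estimates for
any real landscape; the *ordering* and the order-of-magnitude contrast are
the reproducible content.

```{r scenario, eval = FALSE}
scene <- simulateScene(SceneConfig(seed = 1))
nfi <- runScenario(scene, "nfi_direct", n = 100, seed = 1)
two <- runScenario(scene, "lidar_two_stage", n = 100, seed = 1)
scr <- runScenario(scene, "lidar_two_stage_screened", n = 100, seed = 1)
c(nfi = nfi$report$mean_rel_uncertainty_pct,
  two = two$report$mean_rel_uncertainty_pct,
  scr = scr$report$mean_rel_uncertainty_pct)
```

## SAR preprocessing

`queganFilter()` implements the canonical M-channel multi-temporal
speckle filter in linear power,
$J_k = \frac{\langle I_k\rangle_w}{M}\sum_i I_i / \langle I_i\rangle_w$,
with 7 × 7 local means and mirror-padded edges; pixels with degenerate
local means pass through unfiltered, and the single-image case collapses
to the identity. Speckle strength is diagnosed with the empirical
equivalent number of looks, $\mathrm{ENL} = \mu^2/\sigma^2$ over a
homogeneous region; on an 8-date 4-look stack the filter raises the
per-date ENL by well over the factor 2 observed on real dual-pol mosaics.
`blockAggregate()` provides the 100 m block-mean / nearest-neighbour
resampling (nearest anchors on the block's top-left pixel — fixed so the
operation is bit-testable), and `ndvi()` the usual index with nodata where
both bands are zero.

## Validation

`stratifiedSplit()` bins plots into ten 30 t/ha classes (last open-ended)
and draws round-half-up 67% of each class for calibration. `fitStats()`
returns $R^2$ (squared Pearson correlation), RMSE and bias.
`hexMesh()` tessellates the scene with flat-topped hexagons of 650 km²
(cells clipped at the scene bounds), and `zonalWeightedValidation()`
pairs, per zone, the map mean over forest pixels with the mean in-zone
plot AGB, both multiplied by the zone's forest fraction. The forest
fraction comes from the scene's own tree-cover mask; weighting both
members of the pair follows the area-weighting convention, and the
per-zone table is returned so a weighted-regression alternative can be
compared. Zones without plots, forest or valid map pixels are dropped and
counted. With one pixel per zone and plots at those pixels the zonal
statistics degenerate to the pixel-level ones, which the suite checks.

## Numerical conventions

* Rasters are plain numeric matrices on a planar grid with `NA` nodata;
  scene and map I/O is plain text (TSV layers, CSV plot tables, YAML
  configs, GeoJSON zones), and dB conversion floors at −50 dB for zero
  power.
* Empirical quantiles are type-7 (linear interpolation).
* Ensemble surfaces are invariant to the order of realizations and to
  rescaling the stack, which the suite asserts.
* All randomness flows from one master seed through stable name-hashed
  child seeds; no function touches the global RNG state without restoring
  it.

## Limitations

The learner is a documented approximation to the proprietary rule-based
systems used in the mapping literature; committee behaviour and rule
simplification differ in detail. The scene generator fixes one campaign
(no repeated NFI measurements) and one LiDAR acquisition; uncertainty
from temporal mismatch is represented only through the residual-outlier
screen, not simulated. Hexagon and region validation use planar geometry.
Bias correction of ensemble predictions is deliberately out of scope: the
mean-reversion of extremes is reported, not corrected.
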