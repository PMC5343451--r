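---
title: "Multimodel inference for global population-density models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodel inference for global population-density models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(densmmi)
```

## The problem

`densmmi` models how the population density of a wide-ranging species —
the motivating case is the wild pig (*Sus scrofa*), an invasive large
mammal with a near-global distribution — responds to biotic and abiotic
landscape factors, and turns the fitted relationship into a map of
potential density. The data are site-level density estimates
(animals/km²) compiled across the species' native and non-native range,
augmented with zero-density pseudo-absence ("background") locations, and
a set of landscape covariate rasters: vegetation (agriculture, forest
canopy, unvegetated area), predation (large-carnivore richness) and
climate (potential evapotranspiration, seasonal precipitation).

## The model

The response is natural-log density. For sites $i = 1,\dots,n$ and
standardised covariates $z_{ij}$,

$$\ln(d_i + c) \;=\; \beta_0 + \sum_j \beta_j z_{ij} \;(+\; \beta_{jq}\, z^2_{ij,\text{std}}) \;+\; \varepsilon_i, \qquad \varepsilon_i \sim N(0, \sigma^2),$$

fitted by ordinary least squares. Covariates whose hypothesised response
is curvilinear (potential evapotranspiration, agriculture) carry a linked
quadratic term: the square of the standardised main column,
re-standardised. A covariate and its quadratic term form a *block* that
enters or leaves candidate models as a unit, preserving marginality.

Rather than picking one model, every subset of the blocks is fitted
($2^B$ models; the seven-block default gives 128) and ranked by the
small-sample-corrected Akaike information criterion,

$$\mathrm{AICc} = -2\log L + 2K + \frac{2K(K+1)}{n - K - 1},$$

where $K$ counts the intercept, every slope coefficient and the residual
variance. (This convention reproduces the published selection table of
the motivating analysis: its top model with eight slope coefficients has
$K = 10$ and, at $n = 183$, $\log L = -108.33$ gives
$\mathrm{AICc} = 237.94$.) Akaike differences
$\Delta_i = \mathrm{AICc}_i - \min \mathrm{AICc}$ yield model weights
$w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$, computed with a
max-shift so that the enormous spreads that arise in practice (the
abiotic-only model family sits about 73 AICc units above the best
combined model, an evidence ratio above $10^{15}$) cannot underflow.

Inference then averages over the whole set. *Full* (zero-substitution)
averaging is used: a block absent from model $i$ contributes
$\hat\beta_i = 0$, so

$$\bar\beta = \sum_i w_i \hat\beta_i, \qquad
\widehat{\mathrm{SE}}(\bar\beta) = \sum_i w_i \sqrt{\widehat{\mathrm{var}}_i + (\hat\beta_i - \bar\beta)^2},$$

with $\widehat{\mathrm{var}}_i = 0$ where the term is absent. The
unconditional SE combines within-model sampling variance and
between-model spread; the square-root-of-weighted-sum variant is
available through `model_average(se_variant = "sqrt_sum")`. The
importance of a block is the total weight of models containing it.
Two remarks on this choice:

* The standard multimodel-inference literature defines both the
  "conditional" (average over containing models only) and the full
  estimator; the shrinkage toward zero of rarely selected terms under
  full averaging matches the near-zero forest coefficient at importance
  0.25 reported by the motivating analysis, which is why full averaging
  is the default. Conditional behaviour can be recovered by dividing by
  the importance.
* Both unconditional-SE formulas appear in that literature; the
  weighted-sum-of-roots form is the default because it is the more
  conservative of the two.

## Data preparation

**Repeated estimates** at one study area are averaged (arithmetic mean)
before analysis; `aggregate_records()` is idempotent and refuses groups
with contradictory island flags, regions or coordinates.

**Islands vs mainland.** Island populations run denser than mainland
ones; `compare_island_mainland()` applies Welch's unequal-variance
t-test (the Welch–Satterthwaite degrees of freedom match the fractional
df reported in the motivating study) on either the raw or the log scale.
Because the two scales give visibly different statistics (the published
untransformed summaries imply $|t| = 3.78$), both are exposed and the
pipeline reports both. Island records are excluded from the regression.

**Background points.** To sample available-but-unoccupied conditions,
zero-density locations are drawn uniformly from the ring between 100 and
1000 km outside the native-range polygon, with a count proportional to
the native-range estimate count scaled by the ring/native area ratio
(rounded half up; the proportionality rule is exercised in the tests by
fixtures whose ring/native ratio is constructed exactly). Geometry is
planar: polygon areas by the shoelace formula, ring areas by the Steiner
formula for convex polygons ($P\,\Delta r + \pi\,\Delta r^2$ terms) and
by numerical integration of the membership predicate otherwise or when
the ring is clipped to the raster extent.

**Covariate engineering.** Each covariate is summarised by a
moving-window (focal) mean at candidate radii of 10/20/40 km — disc
membership is by cell-centre distance, radius inclusive, missing cells
excluded — and the best radius and form (linear vs quadratic) per
covariate are chosen by AICc on univariate fits, ties toward the
smaller radius, quadratic accepted iff its AICc beats the linear fit.
Columns are then centred and scaled (the scaling is stored for
prediction) and pruned greedily until no pair exceeds $|r| = 0.70$; the
lower-priority member of each offending pair is dropped, with priority
defaulting to the absolute univariate t-statistic against the response —
a deterministic, mechanisable stand-in for the expert judgement such
analyses also lean on. The pruning log records every (dropped, kept, r)
decision.

**The log offset.** Background zeros make a pure log transform
impossible; `log_offset` (default 1.0, so that zero density maps to
response 0) is added before the log and subtracted after
back-transforming predictions. The offset is configurable and recorded
in the run manifest, never silently applied.

## Prediction and classification

`predict_map()` applies the averaged coefficients cellwise to covariate
rasters: focal-summarise at each covariate's chosen radius, standardise
with the *training* centring/scale (so prediction is equivariant under a
covariate shift absorbed by the scaling), form block terms, add the
intercept, back-transform with $\exp(\cdot) - c$ and floor at zero.
Missing cells propagate. The plain exponential back-transform is the
default, reading the map as *maximal potential* density; a log-normal
smearing correction ($+\sigma^2/2$ on the log scale) is available by
flag. `classify_density()` bins the map into low/moderate/high classes.
The published legend anchors the classes at point densities 1, 6 and
≥ 11 animals/km² without stating bin edges; the package reads the
anchors as class centres and bins by their midpoints (low $[0, 3.5)$,
moderate $[3.5, 8.5)$, high $\ge 8.5$), which honours all three anchors
and keeps classification monotone in density.

## Validation

`cross_validate()` performs k-fold cross-validation on the model (log)
scale, with k chosen by Huberty's rule of thumb,
$k = \lceil 1 + \sqrt{p - 1}\rceil$ from the held-out fraction
$1/(1 + \sqrt{p-1})$ — $k = 4$ at the seven retained predictors. Folds
are a balanced random partition. By default the model set and Akaike
weights from the full-data fit are held fixed and each candidate model's
coefficients are refit on the training fold ("fixed averaged
structure"); `refit_selection = TRUE` reruns the entire enumeration and
weighting within each fold. The default is the lighter interpretation —
nothing suggests the motivating analysis repeated model selection per
fold — and both are available. Reported: pooled MSPE, per-fold MSPE,
and the Pearson correlation between observed and predicted held-out
values with $t = r\sqrt{n-2}/\sqrt{1-r^2}$.

## The synthetic world

Because the compiled global dataset and covariate rasters are not
shipped, the package carries a generator that emulates the statistical
structure the analysis assumes, making every stage testable end to end.

* **Surfaces.** Each covariate is smoothed white noise: an i.i.d.
  standard-normal field convolved (circularly, via FFT) with a Gaussian
  kernel normalised to unit $L^2$ norm — so the latent field keeps unit
  variance at every smoothness, and infinite smoothness tends to a
  constant surface — then mapped through the Gaussian CDF into the
  covariate's declared range. Carnivore richness is rounded to whole
  species counts in 0–6.
* **Geography.** The native range is a polygon over the western third of
  a 3000 × 3000 km landscape at 30 km resolution; islands are small
  disjoint disc patches away from it. An *arid belt* coincident with the
  100–1000 km buffer ring shifts the precipitation/vegetation surfaces
  toward hostile values (a smooth bump in distance-from-range, not a
  monotone gradient: a monotone trend makes the covariates mutually
  correlated beyond the 0.70 pruning threshold and would knock true
  predictors out of the analysis, and real deserts ring the species'
  native range rather than covering everything beyond it). The belt
  makes the zero-density background locations sit in genuinely
  unfavourable covariate space, as they do in reality.
* **True model.** Log density is linear in the per-grid standardised
  covariates (quadratic terms use the re-standardised square, matching
  the downstream design construction), with the default coefficient
  pattern taken from the published averaged estimates (PET 0.443 with
  quadratic −0.226; carnivore richness −0.243; wet-season precipitation
  0.233; unvegetated −0.203; agriculture 0.236 with quadratic −0.118;
  dry-season precipitation 0.100; forest −0.001). In the pipeline the
  true surface is built on the buffer-mean covariates at each
  covariate's native radius, since the analysis defines its landscape
  variables as buffer means. Island cells are multiplied by 7 on the
  density scale (≈ the published island/mainland mean ratio
  18.52/2.75). The residual SD defaults to 0.44 — the residual ML
  standard deviation implied by the published top model's
  log-likelihood ($\log L = -108.33$ at $n = 183$) — and under it the
  fitted top model's adjusted R² lands in the 0.45–0.65 range across
  seeds, bracketing the published 0.55, with cross-validated MSPE
  around 0.2–0.35 on the log scale.
* **Records.** 118 mainland and 11 island sites drawn uniformly without
  replacement (densities read off the surface), plus the proportional
  background sample clipped to the raster extent.

What the generator does *not* emulate: real geography and coastlines,
geodesic distance, temporally averaged data sources, spatially
autocorrelated *residuals* (noise is i.i.d. per cell, so tests cannot
detect the consequences of residual spatial structure the analysis also
ignores), and observation error in the compiled density estimates.
Passing tests therefore certify the statistical machinery under the
model's own assumptions, not the field validity of those assumptions.

## Numerical choices and degenerate inputs

* OLS via QR; rank-deficient subsets are excluded from the enumeration
  and logged rather than silently refitted.
* A perfectly fitting model (RSS = 0 with varying response) has no
  Gaussian ML likelihood and raises an error; a constant response
  returns the trivial fit with R² defined as 0.
* AICc requires $n > K + 1$ and errors otherwise; the enumeration guard
  refuses more than $2^{20}$ subsets.
* Weights use the max-shift softmax; weights sum to 1 to $10^{-12}$ on
  every run, and adding a constant to all AICc values leaves them
  unchanged.
* Scale-selection ties break toward the smaller radius; focal radii
  smaller than the cell size mean the raw surface.
* Quadratic blocks store their centring/scale so maps and new-data
  predictions reproduce training-site fitted values exactly (asserted to
  1e-8 in the tests).

## Problem sizes used by the test-suite

The suite runs the full pipeline on reduced worlds (1800 km extent) and
the parameter-recovery study on 50 replicate seeds at $n = 183$ with
weakly autocorrelated surfaces (smoothness 40 km), chosen so the
per-grid and per-sample standardisations nearly coincide; recovery is
judged against the true noise-free log-density surface projected onto
the fitted design basis, which expresses the generator's coefficients
and the estimates on one scale. These sizes keep the whole suite around
a minute on one CPU while leaving every statistical property
identifiable.

## Known limitations

* Planar geometry throughout; buffering and areas are not geodesic.
* The correlation-pruning priority is a statistical proxy for expert
  choice; with strongly collinear candidate sets, different priorities
  can retain different (statistically equivalent) variable subsets.
* Full-averaged coefficients are shrunken estimators; they are the right
  object for the prediction map but should not be read as unbiased
  effect sizes for weakly supported blocks.
* The background procedure assigns *exact* zeros; a measurement model
  for "absence" is out of scope.
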