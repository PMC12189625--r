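---
title: "Methods: presence-background habitat modelling and scenario projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-background habitat modelling and scenario projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sargassdm)
```

## The problem

Canopy-forming *Sargassum* species structure temperate rocky-shore
ecosystems, and their coastal habitat is reshaped by ocean warming. Given
presence-only occurrence records and gridded marine environmental layers
(0.05° resolution), the package estimates a habitat suitability index
(HSI), projects it onto climate-scenario layers (SSP1-1.9, SSP2-4.5,
SSP5-8.5 for the 2030s/2060s/2090s), and summarizes range change:
suitable-habitat area and percent trends, change categories, HSI-weighted
latitudinal centroids, multi-species richness, and overlap with marine
protected areas (MPAs).

## The MaxEnt model

With presence cells \(x_1,\dots,x_m\) and a background sample of \(n\)
valid cells, the model is the Gibbs distribution over the background,
\(P(x) = \exp(\lambda' f(x)) / Z(\lambda)\), whose weights minimize the
convex penalized objective

\[
-\frac1m \sum_{i} \lambda' f(x_i) \;+\; \log Z(\lambda)
\;+\; \sum_j \beta_j |\lambda_j| .
\]

**Features.** Variables are min–max scaled on the background. We use
linear and quadratic features plus, per variable, five pairs of forward
and reverse hinge features at equally spaced interior knots. Product and
threshold features are omitted: hinges already span thresholds, and the
three-to-four-variable models this workflow targets, fitted to a few
hundred presences, favour a restrained basis.

**Penalties.** \(\beta_j = \beta \cdot c_j \cdot s_j/\sqrt m\), with
\(\beta\) the global beta multiplier, \(s_j\) the feature sd over
presences (floored at 0.01), and \(c_j = 1\) for linear/quadratic and
\(0.5\) for hinge features — mirroring the structure (not the
interpolation tables) of the canonical MaxEnt defaults.

**Optimization.** Deterministic orthant-wise proximal Newton on the
working set: exact Hessian of \(\log Z\), backtracking line search with
orthant projection, and a proximal-gradient fallback. Convergence is a
KKT residual below `tol` (default 1e-6) with a 10,000-iteration cap; a
cap hit raises a convergence error carrying the residual. The recorded
objective trace is non-increasing, and fits are bit-reproducible given
their inputs.

**Outputs.** `raw` is the Gibbs density (sums to 1 over the training
background). With \(c = e^H\), where \(H\) is the entropy of the fitted
background distribution, `logistic` is \(c\,r/(1+c\,r)\) and `cloglog`
is \(1 - e^{-c r}\). The HSI used throughout is the logistic output: a
null model then scores exactly 0.5 everywhere, a convenient fixed
reference. The cloglog transform is exposed for comparison
(`output_transform` in the run configuration); which transform the
workflow's antecedents used is not documented, so this choice is ours.

**Contribution.** Native MaxEnt "percent contribution" is path-dependent
on a particular implementation's training trajectory and cannot be
reproduced outside it. We use seeded permutation importance instead
(default 10 permutations): the mean drop in training AUC when a
variable's values are permuted jointly across presence + background rows,
floored at 0 and normalized to percentages summing to 100. This is a
deliberate surrogate, documented as such.

## Variable selection and beta tuning

The procedure runs in the order (1) screening, (2) beta sweep,
(3) VIF gate:

1. **Screening loop.** Fit 10 replicate 70/30 models on the current
   variables and average their contributions. Drop variables with mean
   contribution strictly below 5%. Then, while any retained pair has
   background Pearson \(|r| > 0.7\), drop the lower-contribution member
   of the strongest pair (ties: lexicographically later name). Repeat
   until stable. Correlation is measured on background cells — the
   larger sample characterizing environmental space — rather than at
   presences.
2. **Beta sweep.** For each \(\beta \in \{1, 1.5, \dots, 10\}\) (19
   values), 10 replicate 70/30 fits; choose the \(\beta\) with the
   highest mean test AUC (ties: smallest \(\beta\)).
3. **VIF gate.** Variance inflation factors \(1/(1-R^2)\) from OLS on
   background cells must be below 5; if not, the worst offender is
   removed and the procedure re-screens without it.

Replicate seeds are `base_seed + replicate`, recorded in the run log, so
every report is reproducible.

## Evaluation

Training uses a uniform random 70% of the present-era presences
(`round(0.7 n)`); the background sample doubles as pseudo-absence, as no
true absences exist. AUC is the Mann–Whitney probability that a presence
outscores a background point (ties half). TSS is maximized over all
observed score thresholds — the standard convention where no fixed
threshold is documented. Replicates aggregate as mean ± sample sd
(printed to 4 decimals).

## Projection and classification

Replicate predictions are averaged per 0.05° cell first; cells then pool
into 0.2° blocks (4×4 cells) by the mean over unmasked cells, so blocks
with a single valid cell remain defined. Because all replicates share
the block geometry, the order of the two averages is immaterial for
valid cells. Block HSI classifies into Unsuitability [0, 0.2), Low
[0.2, 0.4), Moderate [0.4, 0.6), High [0.6, 0.8) and Optimal [0.8, 1];
the 0.4 boundary is assigned upward so the class rule and the binary
"suitable = HSI ≥ 0.4" rule agree exactly at the boundary.

## Change analytics

Per scenario × period, valid blocks fall into Absence / Constriction /
Expansion / Stability by the present-vs-future truth table. Block areas
are spherical rectangles, \((0.2 \cdot 111.195)^2 \cos\varphi\) km² at
block-centre latitude \(\varphi\) (111.195 km/degree, authalic radius);
the identity "Stability + Constriction = present suitable area" (and its
future counterpart) is asserted on every summary. The latitudinal
centroid weights *all* valid blocks by HSI, not only suitable ones —
the reading that moves smoothly under gradual change. Richness counts
species with a set suitable flag; a block is inside an MPA when any of
its 16 constituent cells is flagged (MPAs are small relative to 0.2°
blocks); the protected fraction is Protected area over
Protected + Unprotected area.

## The synthetic world

The generator replaces external data with a world whose truth is known:

* **Layers.** Nine variables (temperature and salinity mean/ltmin/ltmax,
  current velocity, primary productivity, nitrate) are smooth gradients
  plus spatially autocorrelated noise (Gaussian smoothing of white
  noise, kernel sd 3 cells — enough for realistic inter-variable
  correlation while staying seed-stable). Temperature declines 0.5 °C
  per degree latitude; ltmin/ltmax bracket the mean by construction.
  Productivity and nitrate share part of their noise with temperature
  and salinity so screening has collinearity to resolve.
* **Scenarios.** Additive offsets; warming grows with emission severity
  and period (0.6 °C for SSP1-1.9/2030s up to 4.3 °C for
  SSP5-8.5/2090s, CMIP6-like sea-surface magnitudes), with mild
  freshening and productivity/nitrate declines.
* **Bathymetry.** Depth grows with distance from the western "coast",
  so the 20 m rule (5 m inside a flagged high-turbidity subregion,
  emulating a turbid marginal sea) carves a coastal ribbon like a real
  shelf study area.
* **Truth and occurrences.** True suitability is a logistic function of
  a quadratic form in two drivers: winter temperature (`temp_ltmin`,
  optimum 12 °C) and current velocity, increasing to a 0.7 m s⁻¹
  saturation. The default coefficients (intercept −2.5, curvature 1.0,
  velocity effect 8 logits) were fixed once so that suitable habitat
  covers ≈12% of the valid domain — a restricted coastal niche — and
  the *ideal* presence-background AUC (sampling straight from the
  truth) is ≈0.90, matching the performance band reported for real
  *Sargassum* models. Records sample cells proportionally to truth,
  jitter uniformly within the cell, and span both eras (past < 2000,
  present ≥ 2000, about 1:3).
* **MPA.** Random rectangular patches accumulate until a target
  coverage fraction of valid cells is met (realized within ±20%
  relative); the rectangles also serialize to GeoJSON.

What a green test does *not* establish: the generator has no real
coastline geometry, currents, sampling bias, or observation error, so
passing recovery tests demonstrates the correctness of the machinery,
not the ecological validity of any real-data analysis.

## Numerical conventions and edge cases

* Cell membership is half-open ([west, west+Δ) × [south, south+Δ)),
  outer north/east boundary closed; a 1e-6-cell epsilon absorbs
  floating-point round-off at boundaries. Deduplication keeps the first
  record (file order) per species × era × 0.05° cell and is idempotent.
* Prediction clamps variables to their background range (the MaxEnt
  transfer convention); clamping warns on direct calls and is silent
  inside scenario projection, where it is routine.
* Constant background variables carry no information and are dropped
  from feature expansion with a warning; perfect collinearity reports
  infinite VIF; an all-zero suitability surface, an empty design after
  masking, and a sub-5-presence split raise typed errors.
* Areas use a spherical Earth; coordinates are WGS84 degrees with no
  projection — areas are comparative, not cadastral.

## Limitations

Single-species models are fitted independently (no joint occupancy);
background bias correction, spatial cross-validation, and MESS-style
extrapolation diagnostics are out of scope; raster I/O is CSV/GeoJSON
(matrices in memory) rather than GeoTIFF/NetCDF, reflecting the
text-only toolchain this package is built against.
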