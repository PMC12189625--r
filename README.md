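# sargassdm

Presence-background species distribution modelling for canopy-forming
coastal macroalgae (*Sargassum*), with climate-scenario projection and
range-change analytics — built as a fully synthetic-testable pipeline.

## What it does

Canopy-forming *Sargassum* beds are a backbone of temperate rocky-shore
ecosystems and are reshaped by ocean warming. Starting from presence-only
occurrence records (CSV: `species,lon,lat,year`) and 0.05° gridded marine
environmental layers (temperature, salinity, current velocity, primary
productivity, nitrate — mean and long-term min/max where relevant), the
package:

1. masks the study area by bathymetry (≤ 20 m, ≤ 5 m in a flagged
   high-turbidity subregion) and thins records to one per 0.05° cell per
   species and era (past < 2000 / present ≥ 2000);
2. fits a from-scratch **MaxEnt** model — the Gibbs distribution
   `P(x) = exp(λ·f(x))/Z` over background cells minimizing the
   L1-penalized objective `−mean_pres(λ·f) + log Z + Σ βⱼ|λⱼ|`, with
   linear + quadratic + hinge features and per-feature penalties
   `βⱼ = β·cⱼ·sⱼ/√m`;
3. screens variables (permutation contribution < 5% out, background
   Pearson |r| > 0.7 resolved by contribution, VIF < 5 enforced) and
   tunes the beta multiplier β over 1–10 by 0.5 on mean replicate test
   AUC;
4. evaluates 10 replicate 70/30 splits by AUC (Mann–Whitney) and TSS
   (max over thresholds);
5. projects the habitat suitability index (HSI = logistic output) onto
   present and SSP1-1.9 / SSP2-4.5 / SSP5-8.5 layers for the
   2030s/2060s/2090s, averages to 0.2° blocks, classifies into five
   levels and a binary `HSI ≥ 0.4` suitability flag;
6. summarizes change: Absence/Constriction/Expansion/Stability maps,
   cosine-weighted suitable areas (10³ km²) and percent trends,
   HSI-weighted latitudinal centroids, multi-species richness, and
   marine-protected-area overlap (Absence/Unprotected/Protected with a
   protected-fraction percentage).

A first-class synthetic-data module generates autocorrelated layers with
a latitudinal temperature gradient, scenario warming offsets, shelf
bathymetry, occurrences sampled from a known suitability surface, and
polygonal MPA masks — so every stage is testable without external data.
See `vignettes/habitat-projection-methods.Rmd` for the model, every
tunable default, and the design rationale.

## Worked example

```r
library(sargassdm)

g     <- grid_spec(124, 32, 0.05, nrow = 96, ncol = 64)
bathy <- generate_bathymetry_and_mask(g, seed = 1)
stack <- generate_env_stack(g, seed = 1, mask = bathy$mask)
surf  <- true_surface()                       # known truth: ltmin + velocity
occ   <- dedup_to_grid(sample_occurrences(surf, stack, 250, seed = 1))
occ_now <- occurrence_set(subset(as.data.frame(occ), era == "present"),
                          dedup = TRUE)

vars <- c("temp_ltmin", "vel_mean", "temp_ltmax", "sal_mean",
          "pp_mean", "no3_mean")
pres <- extract_at_points(stack, occ_now, vars)
bg   <- stack_design(stack, vars)

sel <- select_model(pres, bg, reps = 5, betas = c(1, 2, 5), base_seed = 1)
#> <selection_report>
#>  retained: temp_ltmin, vel_mean
#>  excluded: sal_mean (low-contribution), pp_mean (low-contribution),
#>            no3_mean (low-contribution), temp_ltmax (correlated)
#>  beta multiplier: 1

rf  <- replicate_fits(pres[, sel$retained], bg[, sel$retained],
                      beta_multiplier = sel$beta, reps = 5, base_seed = 1)
aggregate_replicates(rf$results)[c("auc", "tss")]
#> $auc  "0.8887 ± 0.0131"     $tss  "0.6798 ± 0.0566"

sg_now <- block_average(project_hsi(rf$models, stack), g)
fut    <- apply_scenario(stack, scenario_spec("SSP5-8.5", "2090s"))
sg_fut <- block_average(project_hsi(rf$models, fut), g)
change_summary(sg_now, sg_fut, "demo", "SSP5-8.5", "2090s")
#> <change_summary> demo SSP5-8.5 2090s: 7.31 -> 0.00 (10^3 km^2),
#>   trend -100.00%, centroid 34.76 -> 32.50 N
```

The selection recovers exactly the two variables that generated the
data (the correlated `temp_ltmax` and the nuisance layers are screened
out); replicate test AUC ≈ 0.89. Under the +4.3 °C end-of-century
high-emission offset the demo species' suitable habitat (7.31 × 10³ km²
at present) disappears from this small demo domain — winter temperatures
move past its 12 °C optimum everywhere.

The full pipeline (4 species × 9 scenario-period combinations, richness
and MPA accounting, CSV/JSON outputs) runs via:

```r
run_pipeline(default_config(base_seed = 1, outdir = "run1"))
```

or from the command line:

```sh
Rscript inst/scripts/sargassdm-cli.R run-all --seed 1 --outdir run1
```

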