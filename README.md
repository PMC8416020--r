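# hydrana

Quantitative hydration analysis for membrane receptors, built around three
complementary data sources:

* **Fluorescent-probe spectra.** A 7-hydroxycoumarin fluorophore inserted at
  a transmembrane position emits from three species (neutral, anionic,
  tautomer); local water shifts emission from the neutral band toward the
  anion/tautomer bands. hydrana deconvolutes the 340–600 nm emission
  spectrum into those bands by bounded nonlinear least squares and reports a
  **hydration parameter** — the summed fractional band area of the anionic
  and tautomer species,

  `H = f_anionic + f_tautomer ∈ [0, 1]`,

  higher H meaning a more hydrated probe site — then compares H across
  ligand or lipid conditions by one-way ANOVA with Dunnett's many-to-one
  test (multiplicity-adjusted p-values vs a reference such as apo).
* **Trajectory water maps.** Volmap-style occupancy grids (per-voxel
  probability that a water oxygen occupies the voxel across frames),
  isoprobability masks at the conventional 0.3 threshold, state-difference
  maps, OpenDX import/export, and per-probe first-shell contact fractions
  with increase/decrease/none calls between inactive and active states.
* **Structure-ensemble PCA.** Curation of a C-alpha coordinate ensemble by
  the two missing-residue rules (sole-offender structures deleted, columns
  missing in ≥ 2 structures deleted), iterative-mean Kabsch superposition,
  covariance PCA with a deterministic sign convention, and projection of
  simulation conformers into the experimental PC space.

A seeded synthetic-data module (`gen_spectrum`, `gen_two_state_trajectory`,
`gen_structure_ensemble`, `gen_h_replicates`) generates inputs with recorded
ground truth for every stage, and a YAML-driven pipeline (`run_config`)
orchestrates all three analyses with full parameter echo.

Intended users: spectroscopists quantifying probe hydration, and
simulation/structural groups mapping water distributions and activation
motions in GPCR-like receptors.

## Worked example

```r
library(hydrana)

## 1. deconvolute a synthetic spectrum with known truth H = 0.60
tr  <- spectrum_truth(c(neutral = 0.4, anionic = 0.25, tautomer = 0.35),
                      noise_sd = 0.01, seed = 1)
fit <- fit_band_model(gen_spectrum(tr)$spectrum)
fit
#> <deconvolution> R^2 = 0.999016, H = 0.5947 (fractional areas)
#>   species center width amplitude fraction
#>   neutral  380.3 28.27    0.9784   0.4053
#>   anionic  450.0 25.29    0.6506   0.2411
#>  tautomer  509.7 29.97    0.8050   0.3536
```

The fitted H of 0.595 recovers the injected truth of 0.60 to < 0.01 under
1% peak noise; the three bands land at their generating centres.

```r
## 2. compare H across conditions (triplicates, Dunnett vs apo)
h <- gen_h_replicates(c(apo = 0.33, ghrelin = 0.60, SPA = 0.22),
                      noise_sd = 0.03, seed = 2)
compare_hydration_groups(h, reference = "apo")
#> <hydration_comparison> 3 groups vs reference 'apo'; ANOVA p = 2.66e-05
#>    group   mean      sd n
#>      apo 0.3388 0.03738 3
#>  ghrelin 0.5892 0.02028 3
#>      SPA 0.2445 0.03348 3
#> Dunnett-adjusted p vs reference:
#>    group estimate p_adjusted
#>  ghrelin  0.25046   0.000117
#>      SPA -0.09423   0.018018
```

Both ligands shift H away from apo in opposite directions, and both survive
the multiplicity adjustment.

```r
## 3. two-state water-contact analysis on toy trajectories
ei <- superpose_frames(gen_two_state_trajectory(state = "inactive", seed = 10))
ea <- superpose_frames(gen_two_state_trajectory(state = "active",   seed = 11))
lab <- c("232" = "5.58", "272" = "6.44", "268" = "6.40")
compare_states(
  lapply(c(232, 272, 268), \(r) probe_hydration(ei, r, bw_label = lab[as.character(r)])),
  lapply(c(232, 272, 268), \(r) probe_hydration(ea, r, bw_label = lab[as.character(r)])))
#>  probe resid fraction_inactive fraction_active  delta     call
#>   5.58   232             0.108           0.900  0.792 increase
#>   6.44   272             0.900           0.106 -0.794 decrease
#>   6.40   268             0.506           0.510  0.004     none
```

The direction calls recover the generator's activation pattern: water
gained at 5.58, lost at 6.44, unchanged at the control site. Occupancy
grids for the same ensembles come from `occupancy_grid()` and go to any
molecular viewer via `write_dx()`.

```r
## 4. ensemble PCA on a two-cluster synthetic C-alpha ensemble
ge <- gen_structure_ensemble(ensemble_truth(hinge = 10, noise_sd = 0.5, seed = 1))
fit_pca(superpose_ensemble(curate_ensemble(ge$entries)))
#> <pca_model> 19 components; PC1 75.8%, PC2 2.7% of variance
```

PC1 carries the hinge displacement separating the inactive-like and
active-like clusters; `project_conformers()` places external conformers in
the same coordinate system. The curation constants for the published
class-A GPCR ensemble are shipped as `ghsr_conserved_intervals` (expanding
to 164 positions via `expand_interval_list()`) and
`ghsr_pca_discarded_ids` (6 of 268 structures, leaving 262).

A ready-to-run pipeline wrapper lives at
`inst/scripts/hydrana-pipeline.R --config run.yaml`; see the vignette
(`vignettes/hydration-analysis.Rmd`) for the model details, parameter
defaults and design rationale.

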