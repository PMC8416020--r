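---
title: "Quantifying receptor hydration: spectra, water maps, and ensemble PCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying receptor hydration: spectra, water maps, and ensemble PCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrana)
```

# The scientific problem

Water inside a membrane receptor is not a passive solvent: the hydration of
specific transmembrane positions changes as a G-protein-coupled receptor
(GPCR) moves between inactive and active conformations, and ligands of
different pharmacology shift that pattern in opposite directions. hydrana
implements three complementary, quantitative views of this phenomenon:

1. **Spectral deconvolution.** A 7-hydroxycoumarin (7H4MC) fluorophore
   placed at a transmembrane position emits from three species — neutral,
   anionic and excited-state tautomer. Water in the probe's
   microenvironment shifts emission from the neutral band toward the
   anion/tautomer bands, so the summed contribution of those two species is
   a *hydration parameter* `H`. hydrana fits the emission spectrum as a sum
   of peak functions, integrates the bands, and compares `H` across
   conditions by one-way ANOVA with Dunnett's many-to-one test.
2. **Water-occupancy maps.** Given a trajectory ensemble, hydrana
   accumulates volmap-style occupancy grids: each voxel holds the fraction
   of frames in which a water oxygen sits inside it. Isoprobability masks
   (conventionally at probability 0.3), per-probe water-contact fractions
   and two-state difference maps localise where hydration changes.
3. **Ensemble PCA.** Collective motions encoded by a large set of
   experimental structures are extracted by principal component analysis of
   superposed C-alpha coordinates, after a curation step that handles
   missing residues; simulation conformers are then projected into that
   space to check their compatibility with the experimental ensemble.

# The band model and the hydration parameter

The normalised emission intensity over the 340–600 nm window (excitation at
320 nm, which excites the neutral form) is modelled as

$$ I(\lambda) = b_0 + \sum_{k \in \{\mathrm{n,a,t}\}} A_k\,
   f_k(\lambda; c_k, w_k), $$

a constant baseline plus one peak function per species, peak-height
parameterised so that $f_k(c_k) = 1$. Two shapes are provided: a gaussian
in wavelength (default) and an asymmetric lognormal with the width mapped
through $s_k = w_k / c_k$ so that both shapes keep nm units and peak at
$c_k$ with height $A_k$. The literature this kind of deconvolution comes
from does not pin a unique peak-function family, so the shape is an
explicit, isolated configuration choice (`band_component(shape = ...)`)
rather than a hard-wired assumption.

Band areas are integrated analytically
($A_k w_k \sqrt{2\pi}$ for a gaussian;
$A_k c_k s_k \sqrt{2\pi}\, e^{s_k^2/2}$ for the lognormal) and expressed as
fractions $f_k$ of the total area. The hydration parameter is

$$ H = f_\mathrm{anionic} + f_\mathrm{tautomer} \in [0, 1], $$

higher `H` meaning a more hydrated probe site. Reading the "summed
contribution" as *fractional* areas makes `H` dimensionless and comparable
across spectra of different absolute intensity (and makes the fit invariant
to overall scaling); the raw-area alternative remains available via
`h_mode = "raw"` for users who want instrument-scale numbers.

## Fitting choices

* **Exactly three bands.** With excitation selecting the neutral form, the
  emitting species are neutral, anionic and tautomer; a configurable band
  count would leave `H` ill-defined, so it is rejected by design.
* **Ordering by bounds.** Centre windows (340–425, 425–485, 485–600 nm by
  default) keep neutral < anionic < tautomer, preventing label swapping
  during optimisation. Starting values (380/450/510 nm, 30 nm widths) are
  starting values only.
* **Multi-start robustness.** `fit_band_model()` runs bounded
  Levenberg–Marquardt from the given init plus nine seeded jitters and
  keeps the best sum of squares; convergence tolerances are $10^{-10}$ on
  the residual. Goodness of fit is the usual $R^2 = 1 - SS_{res}/SS_{tot}$.
* **Baseline.** Fixed at zero for normalised spectra by default; a fitted
  constant offset is available (`baseline = "constant"`).
* **Replicates.** `H` is estimated per replicate spectrum and summarised as
  mean ± SD (triplicates being the field's norm); replicates are never
  pooled before fitting. `compare_hydration_groups()` then runs one-way
  ANOVA plus Dunnett's test against a reference condition (typically apo),
  reporting multiplicity-adjusted p-values. The Dunnett adjustment
  integrates a multivariate-t distribution by quasi-random methods; the
  function pins an internal seed (and restores the caller's RNG) so results
  are reproducible.

```{r spectra-example}
tr <- spectrum_truth(c(neutral = 0.4, anionic = 0.25, tautomer = 0.35),
                     noise_sd = 0.01, seed = 1)
fit <- fit_band_model(gen_spectrum(tr)$spectrum)
fit
```

# Occupancy grids and probe hydration

`occupancy_grid()` re-implements the occupancy semantics of the classic
volmap tool with choices made for exact testability:

* **Atom centres, not van der Waals volumes.** A voxel is occupied in a
  frame iff at least one selected atom centre lies in its half-open cube
  `[origin + i*spacing, origin + (i+1)*spacing)`. Half-open boundaries mean
  no atom can be double-counted; centre counting means a brute-force
  per-voxel, per-frame, per-atom oracle can verify the grid *exactly*,
  which the test suite does on hundreds of randomized systems.
* **Geometry.** The grid covers the padded bounding box of the selection
  over all frames (defaults: 1.0 Å spacing, 3.0 Å padding, matching common
  volumetric-map practice); an explicit `bounds` argument fixes the
  geometry when two grids must be compared voxel-by-voxel
  (`difference_grid()` refuses mismatched geometry rather than resampling).
* **Frame of reference.** Frames must be superposed on the receptor before
  gridding; `superpose_frames()` performs least-squares rigid-body
  (Kabsch) superposition onto frame 1 over the receptor C-alpha selection.
* **Periodicity.** Trajectories are assumed pre-imaged (solute whole,
  waters wrapped). No minimum-image correction is applied anywhere — maps
  from unwrapped trajectories will be wrong.

Grids are written and read as OpenDX scalar fields (`write_dx()` /
`read_dx()`), the lingua franca of molecular viewers, with the 0.3
isoprobability threshold as the default for `threshold_mask()`.

`probe_hydration()` reports, per probe residue, the fraction of frames with
at least one water oxygen within 3.5 Å (first hydration shell) of any
side-chain heavy atom (C-alpha fallback for glycine-like residues), plus the
mean number of such waters. `classify_hydration_change()` turns two state
profiles into a direction call — increase / decrease / none — with a default
contact-fraction threshold of 0.1; the threshold encodes a direction call,
not an effect-size estimate, since the phenomenon being reproduced is a
qualitative two-state pattern (e.g. position 5.58 gains water upon
activation while 6.44 loses it).

# Ensemble PCA with missing-residue curation

Experimental structure sets are ragged: residues unresolved in some
structures would leave holes in the coordinate matrix. `curate_ensemble()`
applies two rules in a single pass, both assessed on the initial set:

1. a structure is discarded if it is the *only* one missing a residue at
   some alignment column (deleting it rescues the column);
2. a column is discarded if it is missing in at least two structures.

Applied to the published 268-structure class-A GPCR ensemble these rules
delete six structures and leave 262 structures over 164 conserved
positions (`ghsr_pca_discarded_ids`, `ghsr_conserved_intervals`). The
single-pass order reproduces that arithmetic — columns with exactly one
missing structure survive through structure deletion; an `iterate` flag
reapplies the rules to a fixed point for users who prefer that semantics.

The retained matrix is superposed by iterative mean fitting (fit all to the
running mean, recompute, repeat until the mean moves < 1e-6 Å); no
"invariant core" detection is attempted, keeping the procedure simple and
fully testable. `fit_pca()` then eigendecomposes the covariance of the raw
Å coordinates (via SVD of the centred matrix — numerically stabler than
forming the covariance), sorts eigenvalues descending, and fixes each
eigenvector's sign so its largest-magnitude loading is positive, making
projections deterministic. `project_conformers()` optionally Kabsch-fits
external conformers onto the model mean before scoring, which is required
for conformers from an independently aligned trajectory.

# What the synthetic generators emulate — and what they do not

The `gen_*` family produces seeded inputs with recorded ground truth for
every stage; all generators are pure functions of (parameters, seed) and
restore the caller's RNG stream.

* `gen_spectrum()` realises exact fractional band areas, scales to unit
  peak and adds gaussian noise (clipping negatives at zero). It emulates
  band overlap and detector noise; it does not emulate instrument spectral
  response, scatter or baseline drift.
* `gen_two_state_trajectory()` builds a rigid toy receptor with one probe
  residue per site; each site holds a water with a state-dependent
  per-frame Bernoulli probability, placed uniformly in a 2.5 Å sphere
  around the anchor (always within the 3.5 Å cutoff). To keep the atom
  count constant across frames, a site's water is parked at a fixed
  reservoir ≥ 10 Å from every anchor in frames where the site is dry — a
  standard toy-system device. Bulk waters are rejection-sampled ≥ 6 Å from
  all anchors so they cannot contaminate site statistics. Only the
  *statistical* structure (site-wise presence probabilities, two states)
  is claimed; there is no structural realism, no water dynamics, no
  membrane. The default of 500 frames gives the per-site occupancy
  estimate a standard error of at most ~0.022, an order of magnitude below
  the 0.1 direction-call threshold.
* `gen_structure_ensemble()` displaces a terminal quarter of an idealised
  helical chain by the hinge magnitude (default 10 Å) in the active-like
  cluster and adds isotropic coordinate noise (default 0.5 Å). At those
  defaults PC1 separates the clusters essentially perfectly but holds only
  ~76% of the variance, because the hinge moves a quarter of the chain and
  rigid-body superposition redistributes variance across modes; the
  dominant-PC1 regime (> 90%) is reached when noise drops to ~0.25 Å.
  Passing tests on these ensembles therefore demonstrates the machinery —
  curation, superposition, eigenstructure, projection — not the noise
  spectrum of real crystallographic ensembles.

# Numerical and degenerate-input policy

* All-zero spectra cannot be normalised or fitted (error, not NaN).
* Rank-0 PCA input (all structures identical) is an error.
* `curate_ensemble()` errors when fewer than 2 structures or 0 columns
  survive.
* Grid values are exact multiples of `1/n_frames` by construction; the DX
  writer prints 10 significant digits, so round-trips agree to better than
  1e-6.
* Superposition needs ≥ 3 reference atoms (Kabsch is underdetermined
  below that); ties in the PCA sign convention are broken by the first
  maximal loading.
* XTC trajectories are rejected with a clear message; use DCD or
  multi-model PDB.

# Problem sizes used in the shipped checks

The test suite and the acceptance script regenerate everything they check:
100 seeded spectra for `H` recovery (truth 0.60, 1% peak noise), 200
randomized small systems (≤ 30 waters, ≤ 8 frames) for exact grid-oracle
agreement, 100 seed pairs of 500-frame two-state trajectories for the
direction pattern, 200 random missing patterns for the curation oracle, and
2000 null replicates (4 groups, n = 3) for Dunnett family-wise-error
calibration. These sizes were chosen so each property is measured with
comfortable statistical margin while a full run stays in the minutes range
on a laptop.

# Known limitations

* `H` is a relative, probe-local statistic: no solvatochromic calibration
  to absolute water counts is attempted.
* Occupancy maps use point counting; electron-density-style smeared maps
  and residence-time kinetics are out of scope.
* The PCA module consumes an existing alignment; computing one is the job
  of a multiple aligner, not of this package.
* Nothing in the pipeline corrects for periodic-boundary artefacts in
  trajectories that were not pre-imaged.
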