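Package: hydrana
Title: Hydration Analysis for Membrane-Receptor Probes, Trajectories and
    Structure Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify local hydration of membrane receptors from
    three complementary data sources. Deconvolutes hydroxycoumarin-probe
    emission spectra into neutral, anionic and tautomer bands and derives a
    hydration parameter H with ANOVA/Dunnett comparisons across ligand or
    lipid conditions. Computes volmap-style water-occupancy probability
    grids, isoprobability masks, state-difference maps and per-probe
    hydration fractions from trajectory ensembles. Performs curated
    C-alpha principal component analysis over structure ensembles with
    missing-residue handling and projection of simulation conformers.
    Includes seeded synthetic-data generators with recorded ground truth
    for every pipeline stage and a config-driven pipeline runner.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    multcomp,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
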