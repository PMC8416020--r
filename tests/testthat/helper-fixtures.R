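# Builds a complete, small pipeline input tree (spectra + trajectories + pca
# ensemble + YAML config) under `dir`. Everything is generated from the
# package's own synthetic module, so the pipeline tests exercise exactly the
# formats the analysis stages read.
build_pipeline_fixture <- function(dir, seed = 1L, n_frames = 30L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  # spectra: 2 conditions x 3 replicates
  manifest <- data.frame()
  h_truth <- c(apo = 0.30, ghrelin = 0.60)
  k <- 0L
  for (cond in names(h_truth)) {
    for (rep_i in 1:3) {
      k <- k + 1L
      h <- h_truth[[cond]]
      tr <- spectrum_truth(
        fractions = c(neutral = 1 - h, anionic = 0.5 * h, tautomer = 0.5 * h),
        noise_sd = 0.01, seed = seed + k)
      fn <- sprintf("spec_%s_%d.csv", cond, rep_i)
      write_spectrum(gen_spectrum(tr)$spectrum, file.path(dir, fn))
      manifest <- rbind(manifest, data.frame(
        file = fn, condition = cond, probe = "5.58", replicate = rep_i))
    }
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)

  # trajectories: two states as multi-model PDB
  for (st in c("inactive", "active")) {
    e <- gen_two_state_trajectory(state = st, n_frames = n_frames,
                                  n_bulk_waters = 5,
                                  seed = seed + ifelse(st == "active", 100, 0))
    write_ensemble_pdb(e, file.path(dir, paste0(st, ".pdb")))
  }

  # pca ensemble: aligned FASTA + per-structure coordinate csvs
  ge <- gen_structure_ensemble(ensemble_truth(seed = seed),
                               n_per_cluster = 4, n_columns = 12)
  ids <- vapply(ge$entries, `[[`, character(1), "id")
  writeLines(as.vector(rbind(paste0(">", ids),
                             strrep("A", 12))),
             file.path(dir, "aln.fasta"))
  cdir <- file.path(dir, "coords")
  dir.create(cdir, showWarnings = FALSE)
  for (e in ge$entries) {
    utils::write.csv(data.frame(column = 1:12, x = e$calpha[, 1],
                                y = e$calpha[, 2], z = e$calpha[, 3]),
                     file.path(cdir, paste0(e$id, ".csv")), row.names = FALSE)
  }

  cfg <- list(
    seed = seed,
    output_dir = file.path(dir, "out"),
    spectra = list(manifest = "manifest.csv", shape = "gaussian",
                   reference = "apo"),
    hydration = list(
      states = list(
        inactive = list(topology = "inactive.pdb", trajectory = "inactive.pdb"),
        active = list(topology = "active.pdb", trajectory = "active.pdb")),
      spacing = 1.0, cutoff = 3.5, threshold = 0.3, delta_threshold = 0.1,
      probes = c(232L, 272L, 268L)),
    pca = list(alignment = "aln.fasta", coords = "coords", n_components = 3L))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(file.path(dir, "config.yaml"))
}
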