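#' Run a configured hydration-analysis pipeline
#'
#' Executes up to three analysis stages from a single YAML configuration:
#' `spectra` (deconvolution of a manifest of spectra into per-replicate H
#' values, condition summaries and ANOVA/Dunnett comparison), `hydration`
#' (per-state occupancy grids on a common bounding box, DX export,
#' per-probe hydration profiles and state comparison) and `pca` (coordinate
#' table, curation, superposition, PCA, optional conformer projection).
#' Stages run in that dependency order; every referenced path is validated
#' before any computation starts, and all outputs land under the configured
#' output directory. Fixed config plus seed gives byte-identical numeric
#' tables; inputs are never mutated.
#'
#' Config keys (all tunables are echoed in the report): `seed`,
#' `output_dir`; `spectra: manifest, shape, reference, baseline`;
#' `hydration: states (name: topology/trajectory), spacing, padding,
#' cutoff, threshold, delta_threshold, probes`; `pca: alignment, coords,
#' n_components, project`.
#'
#' @param config_path path to the YAML config.
#' @return a `"run_report"` object (also written as `report.txt`).
#' @export
run_config <- function(config_path) {
  if (!file.exists(config_path)) abort("config not found: %s", config_path)
  cfg <- yaml::read_yaml(config_path)
  base <- dirname(normalizePath(config_path))
  resolve <- function(p) if (is.null(p) || file.exists(p)) p else file.path(base, p)

  stages <- intersect(c("spectra", "hydration", "pca"), names(cfg))
  if (length(stages) == 0L) abort("config defines no analysis stage")
  if (is.null(cfg$output_dir)) abort("config must set output_dir")
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)

  # -- validate every referenced path before touching anything
  missing_paths <- character(0)
  need <- function(p) if (!is.null(p) && !file.exists(p))
    missing_paths <<- c(missing_paths, p)
  if ("spectra" %in% stages) need(resolve(cfg$spectra$manifest))
  if ("hydration" %in% stages) {
    for (st in cfg$hydration$states) {
      need(resolve(st$topology))
      need(resolve(st$trajectory))
    }
  }
  if ("pca" %in% stages) {
    need(resolve(cfg$pca$alignment))
    need(resolve(cfg$pca$coords))
    need(resolve(cfg$pca$project))
  }
  if (length(missing_paths) > 0L)
    abort("config validation failed; missing input file(s): %s",
          paste(missing_paths, collapse = ", "))

  out_dir <- cfg$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  results <- list()
  with_seed(seed, {
    for (stage in stages) {
      t0 <- proc.time()[["elapsed"]]
      res <- tryCatch(
        switch(stage,
               spectra = run_spectra_stage(cfg$spectra, resolve, out_dir),
               hydration = run_hydration_stage(cfg$hydration, resolve, out_dir),
               pca = run_pca_stage(cfg$pca, resolve, out_dir)),
        error = function(e)
          abort("stage '%s' failed: %s", stage, conditionMessage(e)))
      res$elapsed_s <- proc.time()[["elapsed"]] - t0
      results[[stage]] <- res
    }
  })
  make_report(results, config = cfg, seed = seed, out_dir = out_dir)
}

# -- spectra stage -----------------------------------------------------------
run_spectra_stage <- function(cfg, resolve, out_dir) {
  manifest <- utils::read.csv(resolve(cfg$manifest), stringsAsFactors = FALSE)
  need <- c("file", "condition", "probe", "replicate")
  if (!all(need %in% names(manifest)))
    abort("spectra manifest needs columns %s", paste(need, collapse = ", "))
  shape <- cfg$shape %||% "gaussian"
  reference <- cfg$reference %||% "apo"
  baseline <- cfg$baseline %||% "none"

  fits <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    s <- read_spectrum(resolve(row$file), condition = row$condition,
                       probe = row$probe, replicate = row$replicate)
    fit_band_model(s, init = default_bands(shape), baseline = baseline)
  })
  h_table <- data.frame(
    file = manifest$file, condition = manifest$condition,
    probe = manifest$probe, replicate = manifest$replicate,
    H = vapply(fits, `[[`, numeric(1), "H"),
    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"))
  bands <- do.call(rbind, lapply(seq_along(fits), function(i)
    cbind(file = manifest$file[[i]], band_table(fits[[i]]))))

  groups <- split(h_table$H, h_table$condition)
  comparison <- NULL
  if (length(groups) >= 2L && all(lengths(groups) >= 2L))
    comparison <- compare_hydration_groups(groups, reference = reference)
  summary_tab <- data.frame(
    condition = names(groups),
    mean_H = vapply(groups, mean, numeric(1)),
    sd_H = vapply(groups, stats::sd, numeric(1)),
    n = lengths(groups))
  if (!is.null(comparison)) {
    pad <- comparison$dunnett$p_adjusted[
      match(summary_tab$condition, comparison$dunnett$group)]
    summary_tab$p_adjusted_vs_reference <- pad
  }

  utils::write.csv(h_table, file.path(out_dir, "h_table.csv"), row.names = FALSE)
  utils::write.csv(bands, file.path(out_dir, "band_table.csv"), row.names = FALSE)
  utils::write.csv(summary_tab, file.path(out_dir, "condition_summary.csv"),
                   row.names = FALSE)
  list(summary = summary_tab, h_table = h_table, comparison = comparison,
       parameters = list(shape = shape, reference = reference,
                         baseline = baseline))
}

# -- hydration stage ---------------------------------------------------------
run_hydration_stage <- function(cfg, resolve, out_dir) {
  spacing <- cfg$spacing %||% 1.0
  padding <- cfg$padding %||% 3.0
  cutoff <- cfg$cutoff %||% 3.5
  threshold <- cfg$threshold %||% 0.3
  delta_threshold <- cfg$delta_threshold %||% 0.1
  probes <- as.integer(cfg$probes %||% integer(0))
  if (is.null(cfg$states) || length(cfg$states) == 0L)
    abort("hydration stage needs at least one state")

  ensembles <- lapply(names(cfg$states), function(nm) {
    st <- cfg$states[[nm]]
    superpose_frames(load_ensemble(resolve(st$topology),
                                   resolve(st$trajectory), state_label = nm))
  })
  names(ensembles) <- names(cfg$states)

  # common bounds so per-state grids share geometry
  sels <- lapply(ensembles, select_water)
  boxes <- lapply(names(ensembles), function(nm) {
    e <- ensembles[[nm]]
    cols <- sels[[nm]]
    fc <- do.call(rbind, lapply(seq_len(n_frames(e)), function(f)
      frame_coords(e, f)[cols, , drop = FALSE]))
    list(lower = apply(fc, 2L, min), upper = apply(fc, 2L, max))
  })
  lower <- apply(do.call(rbind, lapply(boxes, `[[`, "lower")), 2L, min) - padding
  upper <- apply(do.call(rbind, lapply(boxes, `[[`, "upper")), 2L, max) + padding
  bounds <- list(lower = lower, upper = upper)

  grids <- lapply(names(ensembles), function(nm) {
    g <- occupancy_grid(ensembles[[nm]], sels[[nm]], spacing = spacing,
                        bounds = bounds)
    write_dx(g, file.path(out_dir, sprintf("grid_%s.dx", nm)))
    g
  })
  names(grids) <- names(ensembles)

  volumes <- vapply(grids, function(g) threshold_mask(g, threshold)$volume,
                    numeric(1))

  profiles <- lapply(names(ensembles), function(nm) {
    e <- ensembles[[nm]]
    lapply(probes, function(p)
      probe_hydration(e, p, sels[[nm]], cutoff = cutoff))
  })
  names(profiles) <- names(ensembles)
  prof_tab <- do.call(rbind, lapply(names(profiles), function(nm)
    do.call(rbind, lapply(profiles[[nm]], function(p)
      data.frame(state = nm, resid = p$probe$resid,
                 contact_fraction = p$contact_fraction,
                 mean_count = p$mean_count)))))
  if (!is.null(prof_tab))
    utils::write.csv(prof_tab, file.path(out_dir, "probe_profiles.csv"),
                     row.names = FALSE)

  state_cmp <- NULL
  if (length(ensembles) == 2L && length(probes) > 0L) {
    nm <- names(ensembles)
    state_cmp <- compare_states(profiles[[nm[[1L]]]], profiles[[nm[[2L]]]],
                                delta_threshold = delta_threshold)
    utils::write.csv(state_cmp, file.path(out_dir, "state_comparison.csv"),
                     row.names = FALSE)
    dg <- difference_grid(grids[[nm[[2L]]]], grids[[nm[[1L]]]])
    write_dx(dg, file.path(out_dir, "difference.dx"))
  }
  list(summary = data.frame(state = names(grids),
                            mask_volume_A3 = as.numeric(volumes)),
       profiles = prof_tab, state_comparison = state_cmp,
       parameters = list(spacing = spacing, padding = padding,
                         cutoff = cutoff, threshold = threshold,
                         delta_threshold = delta_threshold,
                         probes = probes))
}

# -- pca stage ---------------------------------------------------------------
run_pca_stage <- function(cfg, resolve, out_dir) {
  entries <- build_coordinate_table(resolve(cfg$alignment), resolve(cfg$coords))
  cur <- curate_ensemble(entries)
  X <- superpose_ensemble(cur)
  model <- fit_pca(X)
  k <- min(cfg$n_components %||% 5L, length(model$values))

  utils::write.csv(
    data.frame(component = seq_along(model$values),
               eigenvalue = model$values,
               var_explained = model$var_explained),
    file.path(out_dir, "eigenvalues.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(id = rownames(model$scores),
               model$scores[, seq_len(k), drop = FALSE]),
    file.path(out_dir, "scores.csv"), row.names = FALSE)
  writeLines(c(
    sprintf("retained structures: %d", length(cur$ids)),
    sprintf("retained columns: %d", length(cur$columns)),
    sprintf("deleted structures: %s",
            paste(cur$deleted_ids, collapse = ", ")),
    sprintf("deleted columns: %s",
            paste(cur$deleted_columns, collapse = ", "))),
    file.path(out_dir, "curation_report.txt"))

  projections <- NULL
  if (!is.null(cfg$project)) {
    conf <- as.matrix(utils::read.csv(resolve(cfg$project), row.names = 1L))
    projections <- project_conformers(model, conf)
    utils::write.csv(data.frame(id = rownames(projections),
                                projections[, seq_len(k), drop = FALSE]),
                     file.path(out_dir, "projections.csv"), row.names = FALSE)
  }
  list(summary = data.frame(
         retained_structures = length(cur$ids),
         retained_columns = length(cur$columns),
         pc1_var = model$var_explained[[1L]],
         pc2_var = if (length(model$values) > 1L) model$var_explained[[2L]] else NA_real_),
       curation = cur, model = model, projections = projections,
       parameters = list(n_components = k))
}

#' Assemble a run report from completed stage outputs
#'
#' Writes a human-readable `report.txt` under `out_dir` (parameter echo,
#' software version, seed, per-stage wall clock and summary tables; each
#' executed stage appears exactly once) and returns the machine-readable
#' report object.
#'
#' @param results named list of completed stage outputs (>= 1).
#' @param config the parsed configuration (echoed).
#' @param seed the run seed.
#' @param out_dir output directory.
#' @return an object of class `"run_report"`.
#' @export
make_report <- function(results, config = list(), seed = NA_integer_,
                        out_dir = ".") {
  if (length(results) == 0L) abort("no completed stages to report")
  if (anyDuplicated(names(results))) abort("duplicate stage in report")
  ver <- as.character(utils::packageVersion("hydrana"))
  lines <- c(sprintf("hydrana %s run report", ver),
             sprintf("seed: %s", seed),
             sprintf("stages: %s", paste(names(results), collapse = ", ")), "")
  for (nm in names(results)) {
    res <- results[[nm]]
    lines <- c(lines, sprintf("== stage: %s (%.2f s) ==", nm,
                              res$elapsed_s %||% NA_real_))
    pars <- res$parameters
    if (!is.null(pars))
      lines <- c(lines, paste0("  ", names(pars), " = ",
                               vapply(pars, function(p)
                                 paste(format(p), collapse = ","), character(1))))
    if (!is.null(res$summary)) {
      lines <- c(lines, utils::capture.output(print(res$summary,
                                                    row.names = FALSE)))
    }
    if (!is.null(res$comparison))
      lines <- c(lines, utils::capture.output(print(res$comparison)))
    if (!is.null(res$state_comparison))
      lines <- c(lines, utils::capture.output(print(res$state_comparison,
                                                    row.names = FALSE)))
    lines <- c(lines, "")
  }
  writeLines(lines, file.path(out_dir, "report.txt"))
  structure(list(stages = results, config = config, seed = seed,
                 version = ver, out_dir = out_dir),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> hydrana %s, seed %s, stages: %s (outputs in %s)\n",
              x$version, x$seed, paste(names(x$stages), collapse = ", "),
              x$out_dir))
  invisible(x)
}
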