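#' Ground truth for a synthetic three-band spectrum
#'
#' @param fractions named numeric(3): target fractional band areas for
#'   `neutral`, `anionic`, `tautomer`; >= 0, summing to 1. The true
#'   hydration parameter is `H_true = anionic + tautomer`.
#' @param centers,widths named numeric(3) band centres / widths, nm.
#' @param shape `"gaussian"` or `"lognormal"`.
#' @param noise_sd additive gaussian noise SD as a fraction of the peak
#'   intensity (e.g. 0.01 = 1 percent of peak); >= 0.
#' @param seed integer seed.
#' @return an object of class `"spectrum_truth"`.
#' @export
spectrum_truth <- function(fractions = c(neutral = 0.4, anionic = 0.3, tautomer = 0.3),
                           centers = c(neutral = 380, anionic = 450, tautomer = 510),
                           widths = c(neutral = 28, anionic = 26, tautomer = 30),
                           shape = "gaussian", noise_sd = 0, seed = 1L) {
  sp <- c("neutral", "anionic", "tautomer")
  if (!all(sp %in% names(fractions))) abort("fractions must be named neutral/anionic/tautomer")
  fractions <- fractions[sp]
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9)
    abort("fractions must be >= 0 and sum to 1")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  structure(list(fractions = fractions, centers = centers[sp],
                 widths = widths[sp], shape = shape,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 H_true = unname(fractions[["anionic"]] + fractions[["tautomer"]])),
            class = "spectrum_truth")
}

#' Generate a synthetic probe emission spectrum with known truth
#'
#' Band amplitudes are set so the analytic band areas realise exactly the
#' truth's fractional areas, the clean model is scaled to unit peak, and
#' zero-mean gaussian noise of SD `noise_sd` (times the unit peak) is added;
#' negative noisy intensities are clipped at zero. Deterministic in
#' `(truth, wavelengths)` at fixed seed.
#'
#' @param truth a [spectrum_truth()].
#' @param wavelengths nm grid (default 340-600 nm in 1 nm steps).
#' @param condition,probe,replicate metadata stored on the spectrum.
#' @return list with `spectrum` (a [spectrum]) and `truth` (the input truth
#'   augmented with the realised band components).
#' @export
gen_spectrum <- function(truth, wavelengths = seq(340, 600, by = 1),
                         condition = "synthetic", probe = NA_character_,
                         replicate = 1L) {
  stopifnot(inherits(truth, "spectrum_truth"))
  sp <- c("neutral", "anionic", "tautomer")
  # unit-amplitude areas, then amplitude_i proportional to fraction_i / unit_area_i
  unit_area <- vapply(sp, function(s) {
    band_area(band_component(s, truth$centers[[s]], truth$widths[[s]], 1, truth$shape))
  }, numeric(1))
  amps <- truth$fractions / unit_area
  comps <- lapply(sp, function(s)
    band_component(s, truth$centers[[s]], truth$widths[[s]], amps[[s]], truth$shape))
  clean <- evaluate_band_model(comps, 0, wavelengths)
  peak <- max(clean)
  if (peak <= 0) abort("degenerate truth: zero spectrum")
  scale <- 1 / peak
  comps <- lapply(comps, function(b) { b$amplitude <- b$amplitude * scale; b })
  clean <- clean * scale
  intens <- if (truth$noise_sd > 0) {
    with_seed(truth$seed,
              pmax(0, clean + stats::rnorm(length(clean), 0, truth$noise_sd)))
  } else clean
  truth$components <- comps
  list(spectrum = spectrum(wavelengths, intens, condition = condition,
                           probe = probe, replicate = replicate),
       truth = truth)
}

#' Specify one probe site of the toy two-state receptor
#'
#' @param label Ballesteros-Weinstein-style site label, e.g. `"5.58"`.
#' @param resid residue index of the site's probe residue.
#' @param anchor numeric(3): anchor position of the site, Angstrom.
#' @param p_inactive,p_active per-frame water-presence probability of the
#'   site in each state, in \[0, 1\].
#' @return an object of class `"site_spec"`.
#' @export
site_spec <- function(label, resid, anchor, p_inactive, p_active) {
  check_scalar(p_inactive, "p_inactive", 0, 1)
  check_scalar(p_active, "p_active", 0, 1)
  if (length(anchor) != 3L || any(!is.finite(anchor)))
    abort("anchor must be numeric(3)")
  structure(list(label = label, resid = as.integer(resid),
                 anchor = as.numeric(anchor),
                 p_inactive = p_inactive, p_active = p_active),
            class = "site_spec")
}

#' Default two-state probe sites
#'
#' Encodes the qualitative activation pattern of the receptor: site 5.58
#' gains water upon activation (presence probability 0.1 to 0.9), site 6.44
#' loses it (0.9 to 0.1), and site 6.40 is an unchanged 0.5/0.5 control.
#'
#' @return list of three [site_spec()]s.
#' @export
default_hydration_sites <- function() {
  list(site_spec("5.58", 232L, c(6, 6, 4), 0.1, 0.9),
       site_spec("6.44", 272L, c(20, 6, 4), 0.9, 0.1),
       site_spec("6.40", 268L, c(13, 18, 4), 0.5, 0.5))
}

#' Generate a seeded two-state toy hydration trajectory
#'
#' Builds a rigid toy "receptor": one probe residue per site (backbone
#' N/CA/C/O plus a CB side-chain atom placed at the site anchor). In every
#' frame each site independently contains a water molecule with its state's
#' presence probability; present waters are placed uniformly inside a
#' 2.5 Angstrom sphere around the anchor (so the default 3.5 Angstrom
#' contact cutoff always captures them), absent waters are parked at a fixed
#' reservoir position far (>= 10 Angstrom) from every anchor so the atom
#' count stays constant across frames. Bulk waters are placed uniformly in
#' the box, rejection-sampled to stay >= 6 Angstrom from every anchor so
#' they never contaminate site statistics. Deterministic at fixed seed.
#'
#' @param sites list of [site_spec()]s (default [default_hydration_sites()]).
#' @param state `"inactive"` or `"active"`: selects each site's probability.
#' @param n_frames number of frames (default 500).
#' @param n_bulk_waters bulk waters per frame (default 30).
#' @param box numeric(3) box lengths, Angstrom (default 30 x 30 x 30).
#' @param seed integer seed.
#' @return a [trajectory_ensemble()] whose `"truth"` attribute records the
#'   sites, state, probabilities and per-site realised presence vectors.
#' @export
gen_two_state_trajectory <- function(sites = default_hydration_sites(),
                                     state = c("inactive", "active"),
                                     n_frames = 500L, n_bulk_waters = 30L,
                                     box = c(30, 30, 30), seed = 1L) {
  state <- match.arg(state)
  if (n_frames < 1L) abort("n_frames must be >= 1")
  if (n_bulk_waters < 0L) abort("n_bulk_waters must be >= 0")
  anchors <- do.call(rbind, lapply(sites, `[[`, "anchor"))
  if (length(sites) > 1L) {
    dmin <- min(stats::dist(anchors))
    if (dmin < 5)  # 2 x placement radius
      abort("site anchors closer than 5 A (2 x placement radius): %.2f", dmin)
  }

  # receptor: one residue per site, CB at the anchor, backbone offset ~1.5 A
  res_atoms <- do.call(rbind, lapply(seq_along(sites), function(i) {
    s <- sites[[i]]
    data.frame(name = c("N", "CA", "C", "O", "CB"),
               element = c("N", "C", "C", "O", "C"),
               resname = "ALA", resid = s$resid, chain = "A",
               stringsAsFactors = FALSE)
  }))
  res_xyz <- do.call(rbind, lapply(sites, function(s) {
    a <- s$anchor
    rbind(a + c(-2.4, 0.8, 0), a + c(-1.5, 0, 0), a + c(-2.0, -1.2, 0.5),
          a + c(-3.0, -1.6, 0.8), a)
  }))

  n_site <- length(sites)
  wat_atoms <- data.frame(
    name = "OH2", element = "O", resname = "HOH",
    resid = c(seq_len(n_site) + 1000L,
              if (n_bulk_waters > 0L) seq_len(n_bulk_waters) + 2000L),
    chain = "W", stringsAsFactors = FALSE)
  atoms <- rbind(res_atoms, wat_atoms)
  na <- nrow(atoms)

  # fixed reservoirs: box corners pushed outward, one per site
  reservoirs <- do.call(rbind, lapply(seq_len(n_site), function(i)
    box + 10 + 5 * i))

  probs <- vapply(sites, function(s)
    if (state == "inactive") s$p_inactive else s$p_active, numeric(1))

  unif_sphere <- function(n, r) {
    # rejection sampling in the cube; deterministic under the outer seed
    out <- matrix(NA_real_, 0L, 3L)
    while (nrow(out) < n) {
      cand <- matrix(stats::runif(3L * 2L * (n - nrow(out) + 4L), -r, r), ncol = 3L)
      cand <- cand[rowSums(cand^2) <= r^2, , drop = FALSE]
      out <- rbind(out, cand)
    }
    out[seq_len(n), , drop = FALSE]
  }

  truth_presence <- matrix(NA, n_frames, n_site)
  xyz <- with_seed(seed, {
    m <- matrix(NA_real_, n_frames, 3L * na)
    for (f in seq_len(n_frames)) {
      fc <- res_xyz
      present <- stats::runif(n_site) < probs
      truth_presence[f, ] <- present
      off <- unif_sphere(n_site, 2.5)
      site_w <- t(vapply(seq_len(n_site), function(i) {
        if (present[[i]]) anchors[i, ] + off[i, ] else reservoirs[i, ]
      }, numeric(3)))
      bulk <- NULL
      if (n_bulk_waters > 0L) {
        bulk <- matrix(NA_real_, 0L, 3L)
        while (nrow(bulk) < n_bulk_waters) {
          cand <- cbind(stats::runif(2L * n_bulk_waters, 0, box[[1L]]),
                        stats::runif(2L * n_bulk_waters, 0, box[[2L]]),
                        stats::runif(2L * n_bulk_waters, 0, box[[3L]]))
          d2min <- apply(cand, 1L, function(p) min(colSums((t(anchors) - p)^2)))
          bulk <- rbind(bulk, cand[d2min >= 36, , drop = FALSE])
        }
        bulk <- bulk[seq_len(n_bulk_waters), , drop = FALSE]
      }
      fc <- rbind(fc, site_w, bulk)
      m[f, ] <- as.numeric(t(fc))
    }
    m
  })

  e <- trajectory_ensemble(atoms, xyz, state_label = state)
  attr(e, "truth") <- list(
    sites = sites, state = state, probabilities = probs,
    presence = truth_presence, seed = as.integer(seed),
    n_frames = as.integer(n_frames), n_bulk_waters = as.integer(n_bulk_waters),
    box = box)
  e
}

#' Ground truth for a synthetic two-cluster structure ensemble
#'
#' @param hinge hinge displacement magnitude, Angstrom (default 10).
#' @param hinge_length number of terminal columns displaced (default
#'   `NULL`: one quarter of the chain).
#' @param noise_sd isotropic coordinate noise SD, Angstrom (default 0.5).
#' @param missing optional data.frame (`structure`, `column`) of injected
#'   missing flags (structure = index into the generated entry list).
#' @param seed integer seed.
#' @return an object of class `"ensemble_truth"`.
#' @export
ensemble_truth <- function(hinge = 10, hinge_length = NULL, noise_sd = 0.5,
                           missing = NULL, seed = 1L) {
  if (hinge < 0 || noise_sd < 0) abort("hinge and noise_sd must be >= 0")
  structure(list(hinge = hinge, hinge_length = hinge_length,
                 noise_sd = noise_sd, missing = missing,
                 seed = as.integer(seed)),
            class = "ensemble_truth")
}

#' Generate a two-cluster C-alpha structure ensemble with known truth
#'
#' A base chain traces an idealised helix; the active-like cluster displaces
#' a contiguous terminal segment of `hinge_length` columns by the hinge
#' magnitude (a rigid lateral shift mimicking helix spreading at an
#' activation hinge). Isotropic gaussian coordinate noise is added and
#' missing flags are injected per the truth's specification. Deterministic
#' at fixed seed.
#'
#' @param truth an [ensemble_truth()].
#' @param n_per_cluster structures per cluster, >= 2 (default 10).
#' @param n_columns chain length / alignment columns, >= 4 (default 40).
#' @return list with `entries` (list of [structure_entry()]s) and `truth`
#'   (augmented with `labels`: `"inactive-like"`/`"active-like"` per entry).
#' @export
gen_structure_ensemble <- function(truth = ensemble_truth(),
                                   n_per_cluster = 10L, n_columns = 40L) {
  stopifnot(inherits(truth, "ensemble_truth"))
  if (n_per_cluster < 2L) abort("n_per_cluster must be >= 2")
  if (n_columns < 4L) abort("n_columns must be >= 4")
  hl <- truth$hinge_length
  if (is.null(hl)) hl <- max(1L, n_columns %/% 4L)
  if (hl > n_columns) abort("hinge segment (%d) longer than chain (%d)", hl, n_columns)

  t_idx <- seq_len(n_columns)
  base <- cbind(2.3 * cos(t_idx * 100 * pi / 180),
                2.3 * sin(t_idx * 100 * pi / 180),
                1.5 * t_idx)
  active <- base
  seg <- (n_columns - hl + 1L):n_columns
  active[seg, 1L] <- active[seg, 1L] + truth$hinge

  n_tot <- 2L * n_per_cluster
  labels <- rep(c("inactive-like", "active-like"), each = n_per_cluster)
  entries <- with_seed(truth$seed, {
    lapply(seq_len(n_tot), function(i) {
      m <- if (labels[[i]] == "inactive-like") base else active
      m <- m + matrix(stats::rnorm(length(m), 0, truth$noise_sd), ncol = 3L)
      structure_entry(sprintf("S%03d", i), m)
    })
  })
  if (!is.null(truth$missing)) {
    for (r in seq_len(nrow(truth$missing))) {
      si <- truth$missing$structure[[r]]
      co <- truth$missing$column[[r]]
      entries[[si]]$calpha[co, ] <- NA_real_
      entries[[si]]$missing[[co]] <- TRUE
    }
  }
  truth$labels <- labels
  truth$hinge_length <- hl
  list(entries = entries, truth = truth)
}

#' Generate per-condition replicate hydration parameters
#'
#' Replicates are the true condition H plus zero-mean gaussian noise,
#' clipped to \[0, 1\]. Deterministic at fixed seed. The default of three
#' replicates mirrors triplicate fluorescence experiments.
#'
#' @param condition_effects named numeric: true H per condition, in \[0, 1\].
#' @param n_reps replicates per condition, >= 2 (default 3).
#' @param noise_sd replicate noise SD (default 0.02).
#' @param seed integer seed.
#' @return named list of replicate vectors, with the truth attached as the
#'   `"truth"` attribute.
#' @export
gen_h_replicates <- function(condition_effects, n_reps = 3L, noise_sd = 0.02,
                             seed = 1L) {
  if (is.null(names(condition_effects)))
    abort("condition_effects must be named by condition")
  if (any(condition_effects < 0 | condition_effects > 1))
    abort("true H values must lie in [0, 1]")
  if (n_reps < 2L) abort("n_reps must be >= 2")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  out <- with_seed(seed, {
    lapply(condition_effects, function(h)
      pmin(1, pmax(0, h + stats::rnorm(n_reps, 0, noise_sd))))
  })
  attr(out, "truth") <- list(condition_effects = condition_effects,
                             n_reps = as.integer(n_reps),
                             noise_sd = noise_sd, seed = as.integer(seed))
  out
}

#' Write a truth object as a plain-text key-value sidecar
#'
#' @param truth any truth list/object from the generators.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_sidecar <- function(truth, path) {
  flat <- unlist(truth)
  writeLines(paste0(names(flat), " = ", as.character(flat)), path)
  invisible(path)
}
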