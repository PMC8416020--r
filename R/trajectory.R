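#' Construct a trajectory ensemble
#'
#' Holds a topology (atom table) plus per-frame Cartesian coordinates in
#' Angstrom. Coordinates follow the flat `(x1, y1, z1, x2, ...)` layout with
#' one row per frame, the convention used throughout the trajectory-analysis
#' ecosystem, so each frame is `matrix(xyz[f, ], ncol = 3, byrow = TRUE)`.
#'
#' Trajectories are assumed pre-imaged (solute whole, waters wrapped into the
#' primary cell): no minimum-image correction is applied in distance or grid
#' computations.
#'
#' @param atoms data.frame with columns `name`, `element`, `resname`,
#'   `resid` (1-based residue index), `chain`.
#' @param xyz numeric matrix, `n_frames x (3 * n_atoms)`, finite.
#' @param box optional per-frame box lengths (n_frames x 3), Angstrom.
#' @param state_label free-text state tag, e.g. `"inactive"` or `"active"`.
#' @return an object of class `"trajectory_ensemble"`.
#' @export
trajectory_ensemble <- function(atoms, xyz, box = NULL, state_label = "") {
  need <- c("name", "element", "resname", "resid", "chain")
  if (!is.data.frame(atoms) || !all(need %in% names(atoms)))
    abort("atoms must be a data.frame with columns %s", paste(need, collapse = ", "))
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1L)
  if (!is.matrix(xyz) || !is.numeric(xyz))
    abort("xyz must be a numeric matrix (frames x 3*atoms)")
  if (ncol(xyz) != 3L * nrow(atoms))
    abort("coordinate count (%d) does not match 3 x atom count (%d)",
          ncol(xyz), 3L * nrow(atoms))
  if (nrow(xyz) < 1L) abort("need at least one frame")
  if (any(!is.finite(xyz))) abort("coordinates must be finite")
  if (any(atoms$resid < 1L)) abort("residue indices must be >= 1")
  structure(list(atoms = atoms, xyz = xyz, box = box,
                 state_label = as.character(state_label)),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("<trajectory_ensemble> %d atoms x %d frames%s\n",
              nrow(x$atoms), nrow(x$xyz),
              if (nzchar(x$state_label)) paste0(" [", x$state_label, "]") else ""))
  invisible(x)
}

#' Number of frames / atoms
#' @param e a [trajectory_ensemble()].
#' @return integer.
#' @export
n_frames <- function(e) nrow(e$xyz)

#' @rdname n_frames
#' @export
n_atoms <- function(e) nrow(e$atoms)

#' Extract one frame as an n_atoms x 3 matrix
#' @param e a [trajectory_ensemble()].
#' @param f frame index.
#' @return numeric matrix.
#' @export
frame_coords <- function(e, f) {
  matrix(e$xyz[f, ], ncol = 3L, byrow = TRUE)
}

# internal: derive an element symbol from a PDB atom name
guess_element <- function(name) {
  toupper(substr(gsub("[0-9' ]", "", name), 1L, 1L))
}

#' Load a trajectory ensemble from topology + trajectory files
#'
#' The topology is a PDB file; the trajectory may be a multi-model PDB or a
#' DCD file (or `NULL` to take frames from the topology itself). XTC is not
#' supported: convert to DCD or multi-model PDB first.
#'
#' @param topology_path PDB file.
#' @param trajectory_path multi-model PDB or DCD file, or `NULL`.
#' @param state_label state tag stored on the ensemble.
#' @return a [trajectory_ensemble()].
#' @export
load_ensemble <- function(topology_path, trajectory_path = NULL,
                          state_label = "") {
  if (!file.exists(topology_path)) abort("topology not found: %s", topology_path)
  pdb <- tryCatch(bio3d::read.pdb(topology_path, multi = TRUE, verbose = FALSE),
                  error = function(e) abort("unreadable topology %s: %s",
                                            topology_path, conditionMessage(e)))
  at <- pdb$atom
  element <- at$elesy
  bad <- is.na(element) | !nzchar(trimws(element))
  element[bad] <- guess_element(at$elety[bad])
  atoms <- data.frame(name = trimws(at$elety), element = trimws(element),
                      resname = trimws(at$resid), resid = at$resno,
                      chain = ifelse(is.na(at$chain), "A", at$chain),
                      stringsAsFactors = FALSE)
  xyz <- if (is.null(trajectory_path)) {
    unclass(pdb$xyz)
  } else {
    if (!file.exists(trajectory_path)) abort("trajectory not found: %s", trajectory_path)
    ext <- tolower(tools::file_ext(trajectory_path))
    if (ext == "dcd") {
      unclass(bio3d::read.dcd(trajectory_path, verbose = FALSE))
    } else if (ext %in% c("pdb", "ent")) {
      unclass(bio3d::read.pdb(trajectory_path, multi = TRUE, verbose = FALSE)$xyz)
    } else if (ext == "xtc") {
      abort("XTC trajectories are not supported; convert to DCD or multi-model PDB")
    } else {
      abort("unrecognised trajectory format: .%s", ext)
    }
  }
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1L)
  if (ncol(xyz) != 3L * nrow(atoms))
    abort("atom-count mismatch: topology has %d atoms, trajectory frames have %d coordinates",
          nrow(atoms), ncol(xyz))
  trajectory_ensemble(atoms, xyz, state_label = state_label)
}

#' Select atoms by attribute or predicate
#'
#' All given filters are combined with AND. Returns a unique, in-range
#' integer index vector carrying a human-readable `descriptor` attribute.
#'
#' @param e a [trajectory_ensemble()].
#' @param name,resname,resid,element,chain optional filter vectors.
#' @param predicate optional `function(atoms_df) -> logical`.
#' @return integer atom indices.
#' @export
select_atoms <- function(e, name = NULL, resname = NULL, resid = NULL,
                         element = NULL, chain = NULL, predicate = NULL) {
  stopifnot(inherits(e, "trajectory_ensemble"))
  keep <- rep(TRUE, n_atoms(e))
  desc <- character(0)
  if (!is.null(name)) { keep <- keep & e$atoms$name %in% name
    desc <- c(desc, paste0("name ", paste(name, collapse = "/"))) }
  if (!is.null(resname)) { keep <- keep & e$atoms$resname %in% resname
    desc <- c(desc, paste0("resname ", paste(resname, collapse = "/"))) }
  if (!is.null(resid)) { keep <- keep & e$atoms$resid %in% resid
    desc <- c(desc, paste0("resid ", paste(resid, collapse = ","))) }
  if (!is.null(element)) { keep <- keep & e$atoms$element %in% element
    desc <- c(desc, paste0("element ", paste(element, collapse = "/"))) }
  if (!is.null(chain)) { keep <- keep & e$atoms$chain %in% chain
    desc <- c(desc, paste0("chain ", paste(chain, collapse = "/"))) }
  if (!is.null(predicate)) { keep <- keep & predicate(e$atoms)
    desc <- c(desc, "predicate") }
  idx <- which(keep)
  attr(idx, "descriptor") <- if (length(desc)) paste(desc, collapse = " & ") else "all atoms"
  idx
}

#' Default water-oxygen selection
#'
#' Atoms named OW or OH2 in residues named HOH, TIP3, SOL or WAT.
#'
#' @param e a [trajectory_ensemble()].
#' @return integer atom indices.
#' @export
select_water <- function(e) {
  idx <- select_atoms(e, name = c("OW", "OH2"),
                      resname = c("HOH", "TIP3", "SOL", "WAT"))
  attr(idx, "descriptor") <- "water oxygens (OW/OH2 in HOH/TIP3/SOL/WAT)"
  idx
}

#' Receptor C-alpha selection
#'
#' CA atoms outside solvent residues.
#'
#' @param e a [trajectory_ensemble()].
#' @return integer atom indices.
#' @export
select_calpha <- function(e) {
  idx <- select_atoms(e, name = "CA",
                      predicate = function(a) !a$resname %in% c("HOH", "TIP3", "SOL", "WAT"))
  attr(idx, "descriptor") <- "receptor CA"
  idx
}

# internal: optimal rigid-body (Kabsch) transform mapping `moving` onto
# `target` (both k x 3); returns the transformed copy of `apply_to`
kabsch_apply <- function(moving, target, apply_to) {
  cm <- colMeans(moving)
  ct <- colMeans(target)
  P <- sweep(moving, 2L, cm)
  Q <- sweep(target, 2L, ct)
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$u) * det(sv$v))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  sweep(sweep(apply_to, 2L, cm) %*% R, 2L, ct, "+")
}

#' Root-mean-square deviation between two coordinate sets
#' @param a,b k x 3 matrices.
#' @return numeric RMSD in Angstrom.
#' @export
coord_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Superpose all frames onto the first frame
#'
#' Least-squares rigid-body superposition (rotation + translation) of every
#' frame onto frame 1, fitted over a reference atom selection (default:
#' receptor C-alpha). Occupancy grids must be accumulated in the receptor
#' frame, so call this before [occupancy_grid()].
#'
#' @param e a [trajectory_ensemble()].
#' @param reference integer atom indices to fit over; default [select_calpha()].
#' @return a new, superposed [trajectory_ensemble()].
#' @export
superpose_frames <- function(e, reference = NULL) {
  stopifnot(inherits(e, "trajectory_ensemble"))
  if (is.null(reference)) reference <- select_calpha(e)
  if (length(reference) < 3L)
    abort("need at least 3 reference atoms for superposition, got %d",
          length(reference))
  ref1 <- frame_coords(e, 1L)[reference, , drop = FALSE]
  out <- e$xyz
  for (f in seq_len(n_frames(e))) {
    fc <- frame_coords(e, f)
    moved <- kabsch_apply(fc[reference, , drop = FALSE], ref1, fc)
    out[f, ] <- as.numeric(t(moved))
  }
  trajectory_ensemble(e$atoms, out, box = e$box, state_label = e$state_label)
}

#' Write an ensemble as a (multi-model) PDB file
#'
#' @param e a [trajectory_ensemble()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(e, path) {
  stopifnot(inherits(e, "trajectory_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  a <- e$atoms
  nf <- n_frames(e)
  for (f in seq_len(nf)) {
    if (nf > 1L) writeLines(sprintf("MODEL     %4d", f), con)
    fc <- frame_coords(e, f)
    name4 <- ifelse(nchar(a$name) < 4L, paste0(" ", a$name), a$name)
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)) %% 100000L, name4,
      a$resname, substr(a$chain, 1, 1), a$resid %% 10000L,
      fc[, 1L], fc[, 2L], fc[, 3L], 1, 0, a$element)
    writeLines(lines, con)
    if (nf > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
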