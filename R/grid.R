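#' Construct a hydration grid
#'
#' A regular, isotropically spaced voxel grid whose values are per-voxel
#' water-presence probabilities across trajectory frames (occupancy
#' semantics: each value is an exact multiple of `1 / n_frames`). Values are
#' stored as a 3-D array indexed `[ix, iy, iz]`.
#'
#' @param origin numeric(3), Angstrom: position of the lower corner of voxel
#'   `(0, 0, 0)`.
#' @param spacing voxel edge length, Angstrom > 0 (isotropic).
#' @param dims integer(3) voxel counts, all >= 1.
#' @param values numeric array `dims`; probabilities in \[0, 1\] (or
#'   \[-1, 1\] when `signed = TRUE`, as produced by [difference_grid()]).
#' @param n_frames number of frames the occupancy was accumulated over.
#' @param selection free-text descriptor of the selection that was gridded.
#' @param signed allow negative values (difference grids).
#' @return an object of class `"hydration_grid"`.
#' @export
hydration_grid <- function(origin, spacing, dims, values, n_frames = 1L,
                           selection = "", signed = FALSE) {
  if (length(origin) != 3L || any(!is.finite(origin)))
    abort("origin must be numeric(3)")
  check_scalar(spacing, "spacing")
  if (spacing <= 0) abort("spacing must be > 0")
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) abort("dims must be three positive integers")
  if (!identical(dim(values), dims)) dim(values) <- dims
  lo <- if (signed) -1 else 0
  if (any(values < lo - 1e-12) || any(values > 1 + 1e-12))
    abort("grid values must lie in [%d, 1]", lo)
  if (n_frames < 1L) abort("n_frames must be >= 1")
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 dims = dims, values = values, n_frames = as.integer(n_frames),
                 selection = as.character(selection), signed = isTRUE(signed)),
            class = "hydration_grid")
}

#' @export
print.hydration_grid <- function(x, ...) {
  cat(sprintf("<hydration_grid> %d x %d x %d voxels @ %.2f A, origin (%.2f, %.2f, %.2f), %d frames%s\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3], x$n_frames,
              if (x$signed) " [signed]" else ""))
  invisible(x)
}

#' Water-occupancy probability grid from a trajectory
#'
#' Re-implements volmap-style occupancy semantics: the grid covers the
#' axis-aligned bounding box of the selected atoms over all frames, padded
#' on every side; a voxel counts as occupied in a frame iff at least one
#' selected atom centre lies inside its half-open cube
#' `[origin + i*spacing, origin + (i+1)*spacing)`; the voxel value is the
#' occupied-frame count divided by the number of frames. Atom centres are
#' used (not van der Waals volumes) and voxel cubes are half-open so no atom
#' is ever counted into two voxels.
#'
#' Frames should be superposed on the receptor first ([superpose_frames()]);
#' grids are meaningful only in a common frame of reference.
#'
#' @param e a [trajectory_ensemble()].
#' @param sel integer atom indices (default [select_water()]).
#' @param spacing voxel edge, Angstrom (default 1.0).
#' @param padding bounding-box padding, Angstrom (default 3.0).
#' @param bounds optional list `(lower, upper)` of numeric(3) corners fixing
#'   the grid extent explicitly (no padding applied); atoms outside the
#'   bounds are ignored. Use a common bounds box when two grids must share
#'   geometry, e.g. for [difference_grid()].
#' @return a [hydration_grid()].
#' @export
occupancy_grid <- function(e, sel = NULL, spacing = 1.0, padding = 3.0,
                           bounds = NULL) {
  stopifnot(inherits(e, "trajectory_ensemble"))
  if (is.null(sel)) sel <- select_water(e)
  if (length(sel) == 0L) abort("empty atom selection")
  check_scalar(spacing, "spacing")
  if (spacing <= 0) abort("spacing must be > 0")
  if (padding < 0) abort("padding must be >= 0")

  nf <- n_frames(e)
  cols <- as.vector(rbind(3L * (sel - 1L) + 1L, 3L * (sel - 1L) + 2L, 3L * sel))
  # all selected coordinates, one row per (frame, atom)
  sub <- e$xyz[, cols, drop = FALSE]
  xs <- sub[, seq(1L, ncol(sub), by = 3L), drop = FALSE]
  ys <- sub[, seq(2L, ncol(sub), by = 3L), drop = FALSE]
  zs <- sub[, seq(3L, ncol(sub), by = 3L), drop = FALSE]

  if (is.null(bounds)) {
    lo <- c(min(xs), min(ys), min(zs)) - padding
    hi <- c(max(xs), max(ys), max(zs)) + padding
  } else {
    lo <- as.numeric(bounds$lower)
    hi <- as.numeric(bounds$upper)
    if (length(lo) != 3L || length(hi) != 3L || any(hi <= lo))
      abort("bounds must give numeric(3) lower < upper corners")
  }
  origin <- lo
  dims <- as.integer(floor((hi - origin) / spacing)) + 1L

  counts <- integer(prod(dims))
  nx <- dims[1L]; nxy <- dims[1L] * dims[2L]
  for (f in seq_len(nf)) {
    ix <- floor((xs[f, ] - origin[1L]) / spacing)
    iy <- floor((ys[f, ] - origin[2L]) / spacing)
    iz <- floor((zs[f, ] - origin[3L]) / spacing)
    ok <- ix >= 0L & ix < dims[1L] & iy >= 0L & iy < dims[2L] &
      iz >= 0L & iz < dims[3L]
    lin <- unique(ix[ok] + nx * iy[ok] + nxy * iz[ok])
    counts[lin + 1L] <- counts[lin + 1L] + 1L
  }
  vals <- array(counts / nf, dim = dims)
  hydration_grid(origin, spacing, dims, vals, n_frames = nf,
                 selection = attr(sel, "descriptor") %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Threshold a grid into an isoprobability mask
#'
#' Voxels with probability >= `p` are marked hydrated; published volumetric
#' maps conventionally draw the 0.3 isoprobability surface, which is the
#' default here.
#'
#' @param g a [hydration_grid()].
#' @param p probability threshold in \[0, 1\] (default 0.3).
#' @return list with `mask` (logical array) and `volume` (Angstrom^3:
#'   true-voxel count times `spacing^3`).
#' @export
threshold_mask <- function(g, p = 0.3) {
  stopifnot(inherits(g, "hydration_grid"))
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    abort("threshold p must lie in [0, 1]")
  mask <- g$values >= p
  list(mask = mask, volume = sum(mask) * g$spacing^3)
}

#' Signed difference of two hydration grids
#'
#' Elementwise `a - b` on identical grid geometry (values in \[-1, 1\]).
#' Used to contrast the hydration pattern of two receptor states; a positive
#' region in `active - inactive` marks water gained upon activation.
#'
#' @param a,b [hydration_grid()]s sharing origin, spacing and dims.
#' @return a signed [hydration_grid()].
#' @export
difference_grid <- function(a, b) {
  stopifnot(inherits(a, "hydration_grid"), inherits(b, "hydration_grid"))
  if (!identical(a$dims, b$dims) ||
      max(abs(a$origin - b$origin)) > 1e-9 ||
      abs(a$spacing - b$spacing) > 1e-9)
    abort("grid geometry mismatch (origin/spacing/dims must be identical; resampling is not supported)")
  hydration_grid(a$origin, a$spacing, a$dims, a$values - b$values,
                 n_frames = max(a$n_frames, b$n_frames),
                 selection = sprintf("(%s) - (%s)", a$selection, b$selection),
                 signed = TRUE)
}

#' Write a hydration grid as an OpenDX scalar field
#'
#' Emits the `object 1 class gridpositions` dialect readable by standard
#' molecular viewers: grid counts, origin, three axis-aligned `delta` rows
#' with the spacing on the diagonal, and row-major data (z fastest).
#'
#' @param g a [hydration_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dx <- function(g, path) {
  stopifnot(inherits(g, "hydration_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  d <- g$dims
  writeLines(c(
    "# OpenDX scalar field written by hydrana",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.10g %.10g %.10g", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("delta %.10g 0 0", g$spacing),
    sprintf("delta 0 %.10g 0", g$spacing),
    sprintf("delta 0 0 %.10g", g$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # row-major: x slowest, z fastest
  v <- as.vector(aperm(g$values, c(3L, 2L, 1L)))
  n <- length(v)
  pad <- (3L - n %% 3L) %% 3L
  vm <- matrix(c(sprintf("%.10g", v), rep("", pad)), nrow = 3L)
  writeLines(apply(vm, 2L, function(r) paste(r[nzchar(r)], collapse = " ")), con)
  writeLines(c('object "density" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX scalar field
#'
#' @param path a DX file as written by [write_dx()] (or any axis-aligned,
#'   isotropically spaced `gridpositions` scalar field).
#' @return a [hydration_grid()] (marked signed so difference maps round-trip).
#' @export
read_dx <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  gp <- grep("class gridpositions counts", lines, value = TRUE)
  if (length(gp) == 0L) abort("malformed DX file (no gridpositions object): %s", path)
  dims <- as.integer(strsplit(trimws(sub(".*counts", "", gp[[1L]])), "\\s+")[[1L]])
  if (length(dims) != 3L || anyNA(dims)) abort("malformed DX counts in %s", path)
  og <- grep("^origin", lines, value = TRUE)
  if (length(og) == 0L) abort("malformed DX file (no origin): %s", path)
  origin <- as.numeric(strsplit(trimws(sub("^origin", "", og[[1L]])), "\\s+")[[1L]])
  dl <- grep("^delta", lines, value = TRUE)
  if (length(dl) < 3L) abort("malformed DX file (need 3 delta rows): %s", path)
  deltas <- t(vapply(dl[1:3], function(l)
    as.numeric(strsplit(trimws(sub("^delta", "", l)), "\\s+")[[1L]]),
    numeric(3)))
  diag_d <- diag(deltas)
  if (any(abs(deltas - diag(diag_d)) > 1e-9) ||
      max(abs(diff(diag_d))) > 1e-9)
    abort("only axis-aligned isotropic DX grids are supported: %s", path)
  spacing <- diag_d[[1L]]
  ai <- grep("class array", lines)
  if (length(ai) == 0L) abort("malformed DX file (no data array): %s", path)
  nitems <- as.integer(sub(".*items\\s+(\\d+).*", "\\1", lines[[ai[[1L]]]]))
  if (is.na(nitems) || nitems != prod(dims))
    abort("DX item count does not match grid dims in %s", path)
  tail_lines <- lines[(ai[[1L]] + 1L):length(lines)]
  tail_lines <- tail_lines[!grepl("^(object|component|attribute)", tail_lines)]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(tail_lines), "\\s+"))))
  vals <- vals[!is.na(vals)]
  if (length(vals) < nitems)
    abort("truncated DX data section in %s (%d of %d values)", path,
          length(vals), nitems)
  vals <- vals[seq_len(nitems)]
  arr <- aperm(array(vals, dim = rev(dims)), c(3L, 2L, 1L))
  hydration_grid(origin, spacing, dims, arr, n_frames = 1L,
                 selection = basename(path), signed = TRUE)
}
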