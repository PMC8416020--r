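# Independent brute-force oracles. These deliberately avoid the code paths of
# the implementation: occupancy is checked by direct interval membership per
# voxel, probe contacts by explicit sqrt distances, curation by a literal
# transcription of the two discard rules, and superposition by bio3d.

# occupancy oracle: per frame, per atom, find the voxels whose half-open cube
# contains the atom by direct lower <= x < upper comparisons on each axis
oracle_occupancy <- function(e, sel, origin, spacing, dims) {
  nf <- hydrana::n_frames(e)
  counts <- array(0L, dim = dims)
  ax_lower <- lapply(1:3, function(a) origin[[a]] + (seq_len(dims[[a]]) - 1L) * spacing)
  ax_upper <- lapply(1:3, function(a) origin[[a]] + seq_len(dims[[a]]) * spacing)
  for (f in seq_len(nf)) {
    fc <- hydrana::frame_coords(e, f)[sel, , drop = FALSE]
    occ <- array(FALSE, dim = dims)
    for (i in seq_len(nrow(fc))) {
      hit <- lapply(1:3, function(a)
        which(ax_lower[[a]] <= fc[i, a] & fc[i, a] < ax_upper[[a]]))
      if (all(lengths(hit) == 1L))
        occ[hit[[1L]], hit[[2L]], hit[[3L]]] <- TRUE
    }
    counts <- counts + occ
  }
  counts / nf
}

# probe-contact oracle: explicit all-pairs euclidean distances
oracle_probe_counts <- function(e, probe_atom_idx, water_idx, cutoff) {
  nf <- hydrana::n_frames(e)
  counts <- numeric(nf)
  for (f in seq_len(nf)) {
    fc <- hydrana::frame_coords(e, f)
    n_in <- 0L
    for (w in water_idx) {
      dmin <- Inf
      for (p in probe_atom_idx) {
        d <- sqrt(sum((fc[w, ] - fc[p, ])^2))
        if (d < dmin) dmin <- d
      }
      if (dmin <= cutoff) n_in <- n_in + 1L
    }
    counts[f] <- n_in
  }
  counts
}

# curation oracle: literal transcription of the two printed rules on the
# initial set
oracle_curation <- function(entries) {
  M <- do.call(rbind, lapply(entries, `[[`, "missing"))
  ids <- vapply(entries, `[[`, character(1), "id")
  nmiss <- colSums(M)
  sole <- logical(nrow(M))
  for (s in seq_len(nrow(M))) {
    for (co in seq_len(ncol(M))) {
      if (M[s, co] && nmiss[co] == 1L) sole[s] <- TRUE
    }
  }
  list(deleted_ids = ids[sole], deleted_columns = which(nmiss >= 2L))
}

# random small water-only system for the grid oracle tests
make_random_waters <- function(seed, max_waters = 30L, max_frames = 8L,
                               box = 8) {
  set.seed(seed)
  nw <- sample(1:max_waters, 1L)
  nf <- sample(1:max_frames, 1L)
  atoms <- data.frame(name = "OH2", element = "O", resname = "HOH",
                      resid = seq_len(nw), chain = "W",
                      stringsAsFactors = FALSE)
  xyz <- matrix(runif(nf * 3L * nw, 0, box), nrow = nf)
  hydrana::trajectory_ensemble(atoms, xyz)
}

# random rotation matrix from a QR decomposition
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# random missing-pattern structure ensemble for curation property tests
make_random_entries <- function(seed, n_struct = NULL, n_col = NULL,
                                p_miss = NULL) {
  set.seed(seed)
  if (is.null(n_struct)) n_struct <- sample(4:12, 1L)
  if (is.null(n_col)) n_col <- sample(5:15, 1L)
  if (is.null(p_miss)) p_miss <- runif(1, 0, 0.25)
  lapply(seq_len(n_struct), function(i) {
    m <- matrix(rnorm(3L * n_col), ncol = 3L)
    miss <- runif(n_col) < p_miss
    if (all(miss)) miss[sample(n_col, 1L)] <- FALSE
    m[miss, ] <- NA_real_
    hydrana::structure_entry(sprintf("E%02d", i), m)
  })
}
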