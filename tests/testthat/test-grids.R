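make_point_waters <- function(coords_per_frame) {
  nw <- nrow(coords_per_frame[[1]])
  atoms <- data.frame(name = "OH2", element = "O", resname = "HOH",
                      resid = seq_len(nw), chain = "W",
                      stringsAsFactors = FALSE)
  xyz <- do.call(rbind, lapply(coords_per_frame, function(m) as.numeric(t(m))))
  trajectory_ensemble(atoms, xyz)
}

test_that("occupancy counting is exact for hand-built systems", {
  # one water fixed at the same point across 10 frames
  pt <- matrix(c(2.2, 3.7, 1.1), 1, 3)
  e <- make_point_waters(rep(list(pt), 10))
  g <- occupancy_grid(e, select_water(e), spacing = 1, padding = 2)
  expect_equal(sum(g$values == 1), 1L)
  expect_equal(sum(g$values), 1)
  expect_equal(g$n_frames, 10L)

  # water inside one voxel in exactly 3 of 10 frames -> 0.3
  inside <- matrix(c(2.2, 3.7, 1.1), 1, 3)
  outside <- matrix(c(7.6, 7.6, 7.6), 1, 3)
  frames <- c(rep(list(inside), 3), rep(list(outside), 7))
  e2 <- make_point_waters(frames)
  g2 <- occupancy_grid(e2, select_water(e2), spacing = 1, padding = 1)
  idx <- floor((c(2.2, 3.7, 1.1) - g2$origin) / g2$spacing) + 1
  expect_equal(g2$values[idx[1], idx[2], idx[3]], 0.3)
})

test_that("occupancy grids match the brute-force counting oracle", {
  for (seed in 1:20) {
    e <- make_random_waters(seed)
    sel <- select_water(e)
    g <- occupancy_grid(e, sel, spacing = 1.5, padding = 1)
    expect_identical(dim(g$values), as.integer(g$dims))
    oracle <- oracle_occupancy(e, sel, g$origin, g$spacing, g$dims)
    expect_equal(g$values, oracle, ignore_attr = TRUE)
    expect_true(all(abs(g$values * g$n_frames -
                          round(g$values * g$n_frames)) < 1e-12))
  }
})

test_that("threshold masks are nested and volumes are correct", {
  e <- make_random_waters(99)
  g <- occupancy_grid(e, select_water(e), spacing = 1.5, padding = 1)
  m3 <- threshold_mask(g, 0.3)
  m5 <- threshold_mask(g, 0.5)
  expect_true(all(m5$mask <= m3$mask))  # mask(0.5) subset of mask(0.3)
  expect_lte(m5$volume, m3$volume)

  low <- hydration_grid(c(0, 0, 0), 1, c(3, 3, 3),
                        array(0.2, c(3, 3, 3)), n_frames = 5)
  expect_equal(threshold_mask(low, 0.3)$volume, 0)
  expect_false(any(threshold_mask(low, 0.3)$mask))

  vals <- array(0, c(3, 3, 3))
  vals[1:7] <- c(0.3, 0.4, 0.9, 0.3, 0.31, 1.0, 0.3)
  g7 <- hydration_grid(c(0, 0, 0), 1, c(3, 3, 3), vals, n_frames = 10)
  expect_equal(threshold_mask(g7, 0.3)$volume, 7)
  expect_error(threshold_mask(g7, 1.2), "\\[0, 1\\]")
  expect_error(threshold_mask(g7, -0.1), "\\[0, 1\\]")
})

test_that("difference grids are antisymmetric, bounded and geometry-checked", {
  e1 <- make_random_waters(5)
  e2 <- make_random_waters(6)
  bounds <- list(lower = c(-1, -1, -1), upper = c(9, 9, 9))
  a <- occupancy_grid(e1, select_water(e1), spacing = 1, bounds = bounds)
  b <- occupancy_grid(e2, select_water(e2), spacing = 1, bounds = bounds)
  d_ab <- difference_grid(a, b)
  d_ba <- difference_grid(b, a)
  expect_equal(d_ab$values, -d_ba$values)
  expect_true(all(d_ab$values >= -1 & d_ab$values <= 1))
  d_aa <- difference_grid(a, a)
  expect_true(all(d_aa$values == 0))

  shifted <- hydration_grid(a$origin + 0.5, a$spacing, a$dims, a$values,
                            a$n_frames)
  expect_error(difference_grid(a, shifted), "geometry")
})

test_that("DX files round-trip exactly and fail loudly when truncated", {
  e <- make_random_waters(11)
  g <- occupancy_grid(e, select_water(e), spacing = 2, padding = 1)
  f <- withr::local_tempfile(fileext = ".dx")
  write_dx(g, f)
  g2 <- read_dx(f)
  expect_identical(g2$dims, g$dims)
  expect_equal(g2$origin, g$origin, tolerance = 1e-9)
  expect_equal(g2$spacing, g$spacing, tolerance = 1e-9)
  expect_lt(max(abs(g2$values - g$values)), 1e-6)

  # header: three delta rows with the spacing on the diagonal
  lines <- readLines(f)
  deltas <- grep("^delta", lines, value = TRUE)
  expect_length(deltas, 3L)
  dmat <- t(sapply(deltas, function(l)
    as.numeric(strsplit(trimws(sub("delta", "", l)), "\\s+")[[1]])))
  expect_equal(unname(diag(dmat)), rep(g$spacing, 3))
  expect_true(all(dmat[upper.tri(dmat) | lower.tri(dmat)] == 0))

  trunc <- withr::local_tempfile(fileext = ".dx")
  writeLines(lines[1:(grep("data follows", lines) + 1)], trunc)
  expect_error(read_dx(trunc), "truncated")
  empty <- withr::local_tempfile(fileext = ".dx")
  writeLines("not a dx file", empty)
  expect_error(read_dx(empty), "malformed")
})

test_that("gridding is invariant under a common rigid motion + superposition", {
  e <- gen_two_state_trajectory(n_frames = 15, n_bulk_waters = 10, seed = 21)
  ca <- select_calpha(e)
  R <- random_rotation(3)
  shift <- c(4, -2, 7)
  xyz_rot <- t(apply(e$xyz, 1, function(v) {
    m <- matrix(v, ncol = 3, byrow = TRUE)
    as.numeric(t(m %*% R + matrix(shift, nrow(m), 3, byrow = TRUE)))
  }))
  # keep frame 1 in the reference frame so superposition maps the rigidly
  # moved frames back onto it
  xyz_rot[1, ] <- e$xyz[1, ]
  e_rot <- trajectory_ensemble(e$atoms, xyz_rot, state_label = e$state_label)

  s1 <- superpose_frames(e, ca)
  s2 <- superpose_frames(e_rot, ca)
  # re-grid both on the reference frame with identical bounds
  bounds <- list(lower = c(-5, -5, -5), upper = c(35, 35, 35))
  g1 <- occupancy_grid(s1, select_water(s1), spacing = 1.5, bounds = bounds)
  g2 <- occupancy_grid(s2, select_water(s2), spacing = 1.5, bounds = bounds)
  expect_equal(g2$values, g1$values, tolerance = 1e-9)
})
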