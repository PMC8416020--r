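aln3 <- c(A = "ACDEFGHIKL", B = "ACDEFGHIKL", C = "ACDEFGHIKL")
coords_for <- function(n = 10, seed = 1) {
  set.seed(seed)
  data.frame(column = 1:n, x = rnorm(n), y = rnorm(n), z = rnorm(n))
}

test_that("coordinate tables map alignment columns and gaps", {
  tabs <- list(A = coords_for(seed = 1), B = coords_for(seed = 2),
               C = coords_for(seed = 3))
  entries <- build_coordinate_table(aln3, tabs)
  expect_length(entries, 3L)
  expect_true(all(!vapply(entries, function(e) any(e$missing), logical(1))))
  expect_equal(entries[[2]]$calpha[4, ],
               as.numeric(tabs$B[4, c("x", "y", "z")]))

  aln_gap <- c(A = "ACD-FGHIKL", B = "ACDEFGHIKL", C = "ACDEFGHIKL")
  e2 <- build_coordinate_table(aln_gap, tabs)
  expect_true(e2[[1]]$missing[4])
  expect_false(any(e2[[2]]$missing))

  expect_error(build_coordinate_table(aln3, tabs[c("A", "B")]),
               "no coordinate table")
  expect_error(build_coordinate_table(c(A = "ACDE", B = "ACD"), tabs),
               "equal length")
})

test_that("coordinate tables load from FASTA + csv directory", {
  dir <- withr::local_tempdir()
  writeLines(c(">A", "ACDEFGHIKL", ">B", "ACDEFGHIKL"),
             file.path(dir, "aln.fasta"))
  for (id in c("A", "B"))
    utils::write.csv(coords_for(seed = match(id, c("A", "B"))),
                     file.path(dir, paste0(id, ".csv")), row.names = FALSE)
  entries <- build_coordinate_table(file.path(dir, "aln.fasta"), dir)
  expect_length(entries, 2L)
  expect_identical(entries[[1]]$id, "A")
})

test_that("curation applies the two missing-residue rules on the initial set", {
  mk <- function(id, missing_cols, n = 8) {
    m <- matrix(rnorm(3 * n), ncol = 3)
    m[missing_cols, ] <- NA_real_
    structure_entry(id, m)
  }
  # no missing: everything retained
  clean <- lapply(1:5, function(i) mk(paste0("S", i), integer(0)))
  cur <- curate_ensemble(clean)
  expect_length(cur$ids, 5L)
  expect_length(cur$columns, 8L)
  expect_length(cur$deleted_ids, 0L)

  # column 3 missing in exactly 2 structures: column dropped, structures kept
  two_off <- list(mk("S1", 3), mk("S2", 3), mk("S3", integer(0)),
                  mk("S4", integer(0)), mk("S5", integer(0)))
  cur2 <- curate_ensemble(two_off)
  expect_setequal(cur2$ids, paste0("S", 1:5))
  expect_identical(cur2$deleted_columns, 3L)
  expect_false(3L %in% cur2$columns)

  # S4 is the only structure missing column 6: S4 dropped, column kept
  sole <- list(mk("S1", integer(0)), mk("S2", integer(0)),
               mk("S3", integer(0)), mk("S4", 6), mk("S5", integer(0)))
  cur3 <- curate_ensemble(sole)
  expect_identical(cur3$deleted_ids, "S4")
  expect_true(6L %in% cur3$columns)
  expect_length(cur3$columns, 8L)

  expect_error(curate_ensemble(clean[1]), "at least 2")
})

test_that("curation matches the brute-force rule oracle on random patterns", {
  for (seed in 1:50) {
    entries <- make_random_entries(seed)
    oracle <- oracle_curation(entries)
    n_remaining <- length(entries) - length(oracle$deleted_ids)
    n_cols <- nrow(entries[[1]]$calpha) - length(oracle$deleted_columns)
    if (n_remaining < 2L || n_cols == 0L) {
      expect_error(curate_ensemble(entries), "retains")
      next
    }
    cur <- curate_ensemble(entries)
    expect_setequal(cur$deleted_ids, oracle$deleted_ids)
    expect_setequal(cur$deleted_columns, oracle$deleted_columns)
    expect_false(anyNA(cur$xyz))  # fully observed
    expect_equal(ncol(cur$xyz), 3L * length(cur$columns))
  }
})

test_that("ensemble superposition removes rigid motion and matches bio3d", {
  set.seed(17)
  base <- matrix(rnorm(30, sd = 5), ncol = 3)
  X <- rbind(as.numeric(t(base)), as.numeric(t(base)))
  rownames(X) <- c("a", "b")
  S <- superpose_ensemble(X, mode = "reference")
  expect_lt(coord_rmsd(matrix(S[1, ], ncol = 3, byrow = TRUE),
                       matrix(S[2, ], ncol = 3, byrow = TRUE)), 1e-10)

  R <- random_rotation(8)
  rot <- base %*% R + matrix(c(3, 1, -2), nrow(base), 3, byrow = TRUE)
  X2 <- rbind(as.numeric(t(base)), as.numeric(t(rot)))
  S2 <- superpose_ensemble(X2, mode = "iterative-mean")
  expect_lt(coord_rmsd(matrix(S2[1, ], ncol = 3, byrow = TRUE),
                       matrix(S2[2, ], ncol = 3, byrow = TRUE)), 1e-8)

  # random ensemble: pairwise RMSDs after fitting match bio3d's fit.xyz
  set.seed(23)
  Xr <- do.call(rbind, lapply(1:4, function(i)
    as.numeric(t(base + matrix(rnorm(30, sd = 1), ncol = 3)))))
  Sr <- superpose_ensemble(Xr, mode = "reference")
  fit_b <- suppressWarnings(bio3d::fit.xyz(fixed = Xr[1, ], mobile = Xr))
  for (i in 2:4) {
    ours <- coord_rmsd(matrix(Sr[i, ], ncol = 3, byrow = TRUE),
                       matrix(Sr[1, ], ncol = 3, byrow = TRUE))
    theirs <- coord_rmsd(matrix(fit_b[i, ], ncol = 3, byrow = TRUE),
                         matrix(fit_b[1, ], ncol = 3, byrow = TRUE))
    expect_equal(ours, theirs, tolerance = 1e-8)
  }
  expect_error(superpose_ensemble(Xr[, 1:6]), "at least 3")
})

test_that("PCA satisfies its algebraic invariants", {
  set.seed(5)
  X <- matrix(rnorm(20 * 12), 20, 12)
  m <- fit_pca(X)
  r <- length(m$values)
  expect_lt(max(abs(crossprod(m$vectors) - diag(r))), 1e-8)
  expect_true(all(diff(m$values) <= 1e-12))
  expect_true(all(m$values >= 0))
  # trace conservation: eigenvalue sum equals total variance
  total_var <- sum(apply(X, 2, var))
  expect_equal(sum(m$values), total_var, tolerance = 1e-9)
  expect_equal(sum(m$var_explained), 1, tolerance = 1e-12)

  # two distinct points: PC1 parallel to their difference
  p1 <- rnorm(9); p2 <- rnorm(9)
  m2 <- fit_pca(rbind(p1, p2))
  d <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  expect_equal(abs(sum(m2$vectors[, 1] * d)), 1, tolerance = 1e-9)
  expect_true(all(m2$values[-1] < 1e-12))

  expect_error(fit_pca(rbind(p1, p1)), "rank-0")
  # deterministic sign convention
  m3 <- fit_pca(X)
  expect_identical(m$vectors, m3$vectors)
  for (j in seq_len(r)) expect_gt(m$vectors[which.max(abs(m$vectors[, j])), j], 0)
})

test_that("projection is consistent with training scores and nested in k", {
  set.seed(6)
  X <- matrix(rnorm(15 * 12), 15, 12)
  m <- fit_pca(X)
  # the ensemble mean projects to the origin
  expect_lt(max(abs(project_conformers(m, m$mean, superpose = FALSE))), 1e-10)
  # training rows reproduce fit_pca scores
  P <- project_conformers(m, X, superpose = FALSE)
  expect_equal(unname(P), unname(m$scores), tolerance = 1e-10)
  # reconstruction residual is non-increasing in k
  x <- X[3, ] - m$mean
  resid_k <- vapply(seq_along(m$values), function(k) {
    V <- m$vectors[, 1:k, drop = FALSE]
    sqrt(sum((x - V %*% crossprod(V, x))^2))
  }, numeric(1))
  expect_true(all(diff(resid_k) <= 1e-9))
  expect_lt(resid_k[length(resid_k)], 1e-8)  # full-rank round-trip

  expect_error(project_conformers(m, X[, 1:9]), "expects")
})

test_that("interval lists expand to sorted unique indices", {
  expect_equal(expand_interval_list("1-3, 5"), c(1L, 2L, 3L, 5L))
  expect_identical(expand_interval_list(""), integer(0))
  expect_error(expand_interval_list("20-10"), "reversed")
  expect_error(expand_interval_list("3, x"), "malformed")
  expect_equal(expand_interval_list("5, 1, 3-5"), c(1L, 3L, 4L, 5L))
  # en dashes are accepted
  expect_equal(expand_interval_list("1–3"), 1:3)
})

test_that("the conserved-core interval list expands to 164 positions", {
  pos <- expand_interval_list(ghsr_conserved_intervals)
  expect_length(pos, 164L)
  expect_true(all(diff(pos) > 0))
})

test_that("a two-cluster ensemble is separated on PC1", {
  accs <- vapply(1:3, function(seed) {
    ge <- gen_structure_ensemble(ensemble_truth(hinge = 10, noise_sd = 0.5,
                                                seed = seed))
    m <- fit_pca(superpose_ensemble(curate_ensemble(ge$entries)))
    sc <- m$scores[, 1]
    lab <- ge$truth$labels
    mu <- tapply(sc, lab, mean)
    thr <- mean(mu)
    hi <- names(mu)[which.max(mu)]
    lo <- names(mu)[which.min(mu)]
    mean(ifelse(sc > thr, hi, lo) == lab)
  }, numeric(1))
  expect_true(all(accs >= 0.95))
})

test_that("PC1 dominates when the hinge displacement dwarfs the noise", {
  ge <- gen_structure_ensemble(ensemble_truth(hinge = 10, noise_sd = 0.25,
                                              seed = 2))
  m <- fit_pca(superpose_ensemble(curate_ensemble(ge$entries)))
  expect_gte(m$var_explained[1], 0.90)
})
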