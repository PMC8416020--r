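#' One structure's C-alpha trace on a common alignment frame
#'
#' @param id structure identifier (PDB-like).
#' @param calpha numeric matrix, `n_columns x 3`; rows of `NA` mark alignment
#'   columns where the residue is missing in this structure.
#' @return an object of class `"structure_entry"`.
#' @export
structure_entry <- function(id, calpha) {
  if (!is.matrix(calpha) || ncol(calpha) != 3L)
    abort("calpha must be an n x 3 matrix")
  miss <- is.na(calpha[, 1L])
  if (any(is.na(calpha) != is.na(calpha[, c(1L, 1L, 1L)])))
    abort("missing flags must cover whole rows (x, y, z together)")
  if (all(miss)) abort("structure %s has no observed columns", id)
  if (any(!is.finite(calpha[!miss, ]))) abort("coordinates must be finite")
  structure(list(id = as.character(id), calpha = calpha, missing = miss),
            class = "structure_entry")
}

#' Build per-structure C-alpha tables on an alignment frame
#'
#' Maps each structure's C-alpha coordinates onto the columns of a multiple
#' sequence alignment: gap characters (and columns without coordinates)
#' become missing flags.
#'
#' @param alignment either a path to an aligned FASTA file or a named
#'   character vector of equal-length aligned sequences.
#' @param structures named list (by structure id) of coordinate tables with
#'   columns `column` (1-based alignment column), `x`, `y`, `z`; or a
#'   directory containing `<id>.csv` files of that form.
#' @return list of [structure_entry()]s, one per alignment sequence.
#' @export
build_coordinate_table <- function(alignment, structures) {
  if (is.character(alignment) && length(alignment) == 1L && file.exists(alignment)) {
    fa <- bio3d::read.fasta(alignment)
    seqs <- apply(fa$ali, 1L, paste, collapse = "")
  } else {
    seqs <- alignment
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    abort("alignment sequences must be named by structure id")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    abort("aligned sequences must have equal length (got %s)",
          paste(unique(lens), collapse = ", "))
  ncol_aln <- lens[[1L]]

  if (is.character(structures) && length(structures) == 1L) {
    dir <- structures
    files <- file.path(dir, paste0(names(seqs), ".csv"))
    structures <- lapply(files, function(f) {
      if (!file.exists(f)) return(NULL)
      utils::read.csv(f)
    })
    names(structures) <- names(seqs)
  }
  missing_ids <- setdiff(names(seqs), names(structures))
  if (length(missing_ids) > 0L ||
      any(vapply(structures[names(seqs)], is.null, logical(1))))
    abort("no coordinate table for structure id(s): %s",
          paste(union(missing_ids,
                      names(seqs)[vapply(structures[names(seqs)], is.null, logical(1))]),
            collapse = ", "))

  lapply(names(seqs), function(id) {
    aa <- strsplit(seqs[[id]], "")[[1L]]
    tab <- structures[[id]]
    m <- matrix(NA_real_, nrow = ncol_aln, ncol = 3L)
    keep <- tab$column >= 1L & tab$column <= ncol_aln
    m[tab$column[keep], ] <- as.matrix(tab[keep, c("x", "y", "z")])
    m[aa == "-", ] <- NA_real_  # gaps always missing
    structure_entry(id, m)
  })
}

#' Curate a structure ensemble by the missing-residue rules
#'
#' Single pass over the initial set: (1) a structure is discarded if it is
#' the only one with a missing residue at some alignment column (those
#' columns are thereby rescued); (2) an alignment column is discarded if it
#' is missing in at least two structures of the initial set. Both rules are
#' assessed on the initial set, so columns with exactly one missing
#' structure survive via structure deletion, and the retained matrix is
#' fully observed. Set `iterate = TRUE` to reapply the two rules on the
#' reduced set until stable.
#'
#' @param entries list of [structure_entry()]s, length >= 2.
#' @param iterate reapply the rules until no further deletion (default
#'   `FALSE`: one pass).
#' @return an object of class `"curated_ensemble"`: `ids`, `columns`
#'   (retained alignment column indices), `xyz` (structures x 3*columns,
#'   fully observed, columns interleaved x,y,z), `deleted_ids`,
#'   `deleted_columns`.
#' @export
curate_ensemble <- function(entries, iterate = FALSE) {
  if (length(entries) < 2L) abort("need at least 2 structures")
  ids <- vapply(entries, `[[`, character(1), "id")
  if (anyDuplicated(ids)) abort("duplicate structure ids")
  nc <- unique(vapply(entries, function(e) nrow(e$calpha), integer(1)))
  if (length(nc) != 1L) abort("entries disagree on alignment length")

  M <- do.call(rbind, lapply(entries, `[[`, "missing"))  # structures x columns
  keep_s <- rep(TRUE, nrow(M))
  keep_c <- rep(TRUE, ncol(M))
  repeat {
    Msub <- M
    Msub[!keep_s, ] <- FALSE
    Msub[, !keep_c] <- FALSE
    nmiss <- colSums(Msub)
    # rule 1: sole offenders
    sole_cols <- which(nmiss == 1L & keep_c)
    sole_structs <- unique(unlist(lapply(sole_cols, function(j) which(Msub[, j]))))
    # rule 2: columns missing in >= 2 structures
    multi_cols <- which(nmiss >= 2L & keep_c)
    if (length(sole_structs) == 0L && length(multi_cols) == 0L) break
    keep_s[sole_structs] <- FALSE
    keep_c[multi_cols] <- FALSE
    if (!iterate) break
  }

  if (sum(keep_s) < 2L)
    abort("curation retains fewer than 2 structures")
  if (sum(keep_c) == 0L)
    abort("curation retains no alignment columns")

  cols <- which(keep_c)
  xyz <- t(vapply(entries[keep_s], function(e)
    as.numeric(t(e$calpha[cols, , drop = FALSE])), numeric(3L * length(cols))))
  if (anyNA(xyz)) abort("internal error: curated matrix is not fully observed")
  rownames(xyz) <- ids[keep_s]
  structure(
    list(ids = ids[keep_s], columns = cols, xyz = xyz,
         deleted_ids = ids[!keep_s], deleted_columns = which(!keep_c)),
    class = "curated_ensemble")
}

#' @export
print.curated_ensemble <- function(x, ...) {
  cat(sprintf("<curated_ensemble> %d structures x %d columns (deleted: %d structures, %d columns)\n",
              length(x$ids), length(x$columns),
              length(x$deleted_ids), length(x$deleted_columns)))
  invisible(x)
}

#' Superpose a curated ensemble
#'
#' Least-squares rigid-body superposition of every structure, either onto
#' the first structure (`"reference"`) or onto the iteratively refined mean
#' (`"iterative-mean"`, default): structures are fitted to the running mean,
#' the mean is recomputed, and the loop repeats until the mean shifts by
#' less than `tol` Angstrom.
#'
#' @param ce a [curated_ensemble()] or a plain `structures x 3k` matrix.
#' @param mode `"iterative-mean"` or `"reference"`.
#' @param tol convergence tolerance on the max mean shift, Angstrom.
#' @param max_iter iteration cap.
#' @return the superposed coordinate matrix (same shape, rownames kept).
#' @export
superpose_ensemble <- function(ce, mode = c("iterative-mean", "reference"),
                               tol = 1e-6, max_iter = 100L) {
  mode <- match.arg(mode)
  X <- if (inherits(ce, "curated_ensemble")) ce$xyz else ce
  if (anyNA(X)) abort("superposition requires a fully observed matrix")
  k <- ncol(X) / 3L
  if (k < 3L) abort("need at least 3 columns (9 coordinates) to superpose")
  as_mat <- function(v) matrix(v, ncol = 3L, byrow = TRUE)
  as_vec <- function(m) as.numeric(t(m))
  fit_all <- function(X, target) {
    t(apply(X, 1L, function(v) as_vec(kabsch_apply(as_mat(v), target, as_mat(v)))))
  }
  target <- as_mat(X[1L, ])
  X <- fit_all(X, target)
  if (mode == "reference") return(X)
  mu <- colMeans(X)
  for (i in seq_len(max_iter)) {
    X <- fit_all(X, as_mat(mu))
    mu_new <- colMeans(X)
    shift <- max(abs(mu_new - mu))
    mu <- mu_new
    if (shift < tol) break
  }
  X
}

#' Principal component analysis of C-alpha coordinates
#'
#' Eigendecomposition of the covariance of the row vectors about their mean
#' (covariance of raw Angstrom coordinates, the standard choice for C-alpha
#' ensemble PCA), computed by singular value decomposition of the centred
#' matrix. Eigenvalues are returned in descending order; each eigenvector's
#' sign is fixed so its largest-magnitude loading is positive, making
#' projections reproducible.
#'
#' @param X superposed coordinate matrix, `structures x 3k`, >= 2 rows.
#' @return an object of class `"pca_model"`: `mean`, `vectors`
#'   (`3k x r`, orthonormal), `values` (descending, >= 0),
#'   `var_explained`, `scores` (training projections, `structures x r`).
#' @export
fit_pca <- function(X) {
  if (!is.matrix(X) || nrow(X) < 2L) abort("need a matrix with >= 2 rows")
  if (anyNA(X)) abort("PCA input must be fully observed")
  mu <- colMeans(X)
  C <- sweep(X, 2L, mu)
  if (max(abs(C)) == 0) abort("rank-0 input: all structures are identical")
  sv <- svd(C)
  r <- min(nrow(X) - 1L, ncol(X))
  vectors <- sv$v[, seq_len(r), drop = FALSE]
  values <- sv$d[seq_len(r)]^2 / (nrow(X) - 1L)
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(r)) {
    i <- which.max(abs(vectors[, j]))
    if (vectors[i, j] < 0) vectors[, j] <- -vectors[, j]
  }
  scores <- C %*% vectors
  colnames(scores) <- colnames(vectors) <- paste0("PC", seq_len(r))
  structure(list(mean = mu, vectors = vectors, values = values,
                 var_explained = values / sum(values), scores = scores),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              length(x$values), 100 * x$var_explained[1],
              if (length(x$values) > 1) 100 * x$var_explained[2] else 0))
  invisible(x)
}

#' Project conformers onto a fitted PCA model
#'
#' Scores are the eigenvector-basis coordinates of `conformer - mean`. With
#' `superpose = TRUE` (default) each conformer is first rigid-body fitted
#' onto the model mean, which is required when the conformers come from an
#' independently aligned trajectory.
#'
#' @param m a [fit_pca()] model.
#' @param conformers matrix `n x 3k` on the same retained column set.
#' @param superpose fit each conformer onto the model mean first.
#' @return score matrix `n x r` (rownames preserved).
#' @export
project_conformers <- function(m, conformers, superpose = TRUE) {
  stopifnot(inherits(m, "pca_model"))
  if (is.vector(conformers)) conformers <- matrix(conformers, nrow = 1L)
  if (ncol(conformers) != length(m$mean))
    abort("conformers have %d coordinates but the model expects %d",
          ncol(conformers), length(m$mean))
  if (superpose) {
    target <- matrix(m$mean, ncol = 3L, byrow = TRUE)
    conformers <- t(apply(conformers, 1L, function(v) {
      mm <- matrix(v, ncol = 3L, byrow = TRUE)
      as.numeric(t(kabsch_apply(mm, target, mm)))
    }))
  }
  scores <- sweep(conformers, 2L, m$mean) %*% m$vectors
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  scores
}

#' Expand a comma-separated index/range list
#'
#' Accepts entries such as `"45, 46, 48-68"`; ranges are inclusive and both
#' ASCII hyphens and typographic en dashes are understood. Returns the
#' sorted union.
#'
#' @param text the list as a single string; `""` gives `integer(0)`.
#' @return sorted unique integer vector.
#' @export
expand_interval_list <- function(text) {
  if (!is.character(text) || length(text) != 1L)
    abort("text must be a single string")
  text <- gsub("–|—", "-", text)
  tokens <- trimws(strsplit(text, ",")[[1L]])
  tokens <- tokens[nzchar(tokens)]
  out <- integer(0)
  for (tk in tokens) {
    if (grepl("^\\d+$", tk)) {
      out <- c(out, as.integer(tk))
    } else if (grepl("^\\d+\\s*-\\s*\\d+$", tk)) {
      ab <- as.integer(strsplit(tk, "-")[[1L]])
      ab <- ab[!is.na(ab)]
      if (ab[[2L]] < ab[[1L]]) abort("reversed range: '%s'", tk)
      out <- c(out, seq(ab[[1L]], ab[[2L]]))
    } else {
      abort("malformed token: '%s'", tk)
    }
  }
  sort(unique(out))
}

#' Conserved-core residue intervals of the ghrelin receptor
#'
#' The GHSR-numbered residue positions retained after curating the class-A
#' GPCR structure ensemble (missing-residue rules of [curate_ensemble()]);
#' expanding with [expand_interval_list()] yields the 164 conserved
#' positions, covering most of the transmembrane domain.
#'
#' @format a single string of comma-separated indices and inclusive ranges.
#' @export
ghsr_conserved_intervals <- paste(
  "45, 46, 48-68, 76-102, 120-148, 162-179, 181, 212, 213, 215-219,",
  "221-239, 261, 263-286, 310-324")

#' Structures discarded by the ensemble-curation rules
#'
#' PDB identifiers of the six class-A GPCR structures removed as sole
#' offenders (each the only structure missing a residue at some retained
#' alignment position) from the initial set of
#' `ghsr_pca_initial_count` = 268 structures, leaving 262.
#'
#' @format character vector of PDB ids.
#' @export
ghsr_pca_discarded_ids <- c("5WB2", "4PY0", "5ZKP", "3RZE", "4RWA", "4DAJ")

#' @rdname ghsr_pca_discarded_ids
#' @format integer.
#' @export
ghsr_pca_initial_count <- 268L
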