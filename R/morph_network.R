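## Single-subject morphological similarity extraction.
##
## The gray-matter segmentation is tiled, from the low corner of the bounding
## box of nonzero GM, into non-overlapping 3x3x3-voxel cubes. The similarity
## of two cubes is the maximum Pearson correlation of their 27 values over
## the 24 proper rotations of the cube, so two patches of cortex with the
## same local thickness/folding texture score high regardless of local
## orientation. Cube-pair similarities are then averaged within ROI pairs of
## a parcellation atlas ("matrix resizing") to give a symmetric ROI x ROI
## matrix per subject.

## 27 voxel positions in fixed raster order (x fastest), coords in {-1,0,1}^3
.cube_coords <- function() {
  as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
}

#' The 24 proper rotations of a 3x3x3 cube, as index permutations
#'
#' Enumerates all 48 signed axis permutations of the cube's voxel lattice and
#' keeps the 24 with determinant +1 (rigid rotations; reflections are
#' excluded because they are not rigid motions of anatomy). Each element is a
#' permutation `p` of `1:27` such that `values[p]` is the rotated cube, with
#' voxel values stored in raster order (x fastest). The set contains the
#' identity and is closed under composition.
#'
#' @param include_reflections if `TRUE`, return all 48 signed permutations
#'   (improper symmetries included); default `FALSE`.
#' @return a 27 x n integer matrix, one permutation per column.
#' @export
rotation_set <- function(include_reflections = FALSE) {
  coords <- .cube_coords()
  key <- function(m) (m[, 1] + 1) + 3 * (m[, 2] + 1) + 9 * (m[, 3] + 1) + 1
  perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  sgn3 <- function(p) { # parity of an axis permutation
    s <- 1
    for (i in 1:2) for (j in (i + 1):3) if (p[i] > p[j]) s <- -s
    s
  }
  out <- list()
  for (p in perms3) {
    for (sx in c(1, -1)) for (sy in c(1, -1)) for (sz in c(1, -1)) {
      s <- c(sx, sy, sz)
      if (!include_reflections && sgn3(p) * prod(s) != 1) next
      ## rotated voxel position: new = S %*% P %*% old
      newc <- sweep(coords[, p, drop = FALSE], 2, s, `*`)
      perm <- integer(27)
      perm[key(newc)] <- seq_len(27) # rotated[idx(R c)] = values[idx(c)]
      out[[length(out) + 1L]] <- perm
    }
  }
  do.call(cbind, out)
}

#' Tile a GM volume into 3x3x3 cubes with atlas labels
#'
#' The tiling grid is anchored at the low corner of the bounding box of
#' nonzero GM voxels; only complete cubes inside the grid are kept, and cubes
#' whose GM content is entirely zero are discarded. Each retained cube is
#' assigned the majority atlas label among its 27 voxels (ties broken by the
#' smallest label); cubes whose majority label is background (0) are
#' discarded. Cubes are ordered lexicographically by origin.
#'
#' @param gm a [gm_volume()].
#' @param atlas an [atlas_volume()] on the same grid.
#' @param min_gm_voxels minimum number of voxels with GM > 0 for a cube to be
#'   kept (default 1, i.e. keep if any voxel is nonzero).
#' @return a list of class `cube_set`: `values` (n_cubes x 27 matrix, raster
#'   order), `origin` (n_cubes x 3, 0-based voxel coordinates of the low
#'   corner), `roi` (integer labels), `anchor` (0-based tiling anchor).
#' @export
tile_cubes <- function(gm, atlas, min_gm_voxels = 1L) {
  mn_assert(inherits(gm, "gm_volume") && inherits(atlas, "atlas_volume"),
            "tile_cubes expects a gm_volume and an atlas_volume")
  mn_assert(identical(dim(gm$data), dim(atlas$data)),
            "gm and atlas volumes must share the same grid shape")
  g <- gm$data
  dm <- dim(g)
  nz <- which(g != 0, arr.ind = TRUE)
  empty <- structure(list(values = matrix(0, 0, 27),
                          origin = matrix(0L, 0, 3),
                          roi = integer(0), anchor = c(0L, 0L, 0L)),
                     class = "cube_set")
  if (nrow(nz) == 0) return(empty)
  anchor <- apply(nz, 2, min) - 1L # 0-based low corner of the bounding box
  starts <- lapply(1:3, function(a) {
    if (anchor[a] > dm[a] - 3L) return(integer(0))
    seq.int(anchor[a], dm[a] - 3L, by = 3L)
  })
  if (any(vapply(starts, length, 1L) == 0)) return(empty)
  origins <- as.matrix(expand.grid(x = starts[[1]], y = starts[[2]],
                                   z = starts[[3]]))
  ## lexicographic by origin (x, then y, then z)
  origins <- origins[order(origins[, 1], origins[, 2], origins[, 3]), ,
                     drop = FALSE]
  off <- .cube_coords() + 1L # 0..2 offsets in raster order
  keep_vals <- vector("list", nrow(origins))
  keep_roi <- integer(nrow(origins))
  keep <- logical(nrow(origins))
  for (i in seq_len(nrow(origins))) {
    o <- origins[i, ]
    vox <- cbind(o[1] + off[, 1], o[2] + off[, 2], o[3] + off[, 3]) + 1L
    v <- g[vox]
    if (sum(v != 0) < min_gm_voxels) next
    labs <- atlas$data[vox]
    tab <- tabulate(labs + 1L) # counts for labels 0,1,2,...
    lab <- which.max(tab) - 1L # which.max takes the first max -> smallest label
    if (lab == 0L) next
    keep[i] <- TRUE
    keep_vals[[i]] <- v
    keep_roi[i] <- lab
  }
  if (!any(keep)) return(empty)
  structure(list(values = do.call(rbind, keep_vals[keep]),
                 origin = unname(origins[keep, , drop = FALSE]),
                 roi = keep_roi[keep],
                 anchor = as.integer(anchor)),
            class = "cube_set")
}

#' @export
print.cube_set <- function(x, ...) {
  cat(sprintf("<cube_set> %d cubes, %d ROIs, anchor (%s)\n",
              nrow(x$values), length(unique(x$roi)),
              paste(x$anchor, collapse = ",")))
  invisible(x)
}

## Rows centered and scaled to unit norm; zero-variance rows -> all-zero rows
## so their correlation with anything is 0 by convention.
.normalize_cube_rows <- function(v) {
  v <- v - rowMeans(v)
  nrm <- sqrt(rowSums(v^2))
  nz <- nrm > 0
  v[nz, ] <- v[nz, , drop = FALSE] / nrm[nz]
  v[!nz, ] <- 0
  v
}

#' Rotation-maximized similarity between two cubes
#'
#' `max` over the 24 proper rotations `g` of the Pearson correlation between
#' `a` and `g(b)`. If either cube has zero variance the correlation is
#' undefined and the similarity is 0 by convention.
#'
#' @param a,b numeric vectors of 27 GM values (raster order).
#' @param rotations permutation matrix from [rotation_set()] (recomputed if
#'   missing).
#' @return a scalar in `[-1, 1]`.
#' @export
cube_similarity <- function(a, b, rotations = rotation_set()) {
  mn_assert(length(a) == 27 && length(b) == 27,
            "cubes must have exactly 27 values")
  an <- .normalize_cube_rows(matrix(as.double(a), 1))
  bn <- .normalize_cube_rows(matrix(as.double(b), 1))
  if (all(an == 0) || all(bn == 0)) return(0)
  max(vapply(seq_len(ncol(rotations)),
             function(k) sum(an * bn[, rotations[, k]]), double(1)))
}

## All rotation-maximized similarities between two banks of cubes.
## A: nA x 27, B: nB x 27 (raw values). Returns nA x nB matrix.
## Normalizing commutes with permutation of positions, so
## cor(a, g(b)) = <a_hat, b_hat[perm_g]> and each rotation is one BLAS
## crossproduct over the whole block -- memory stays bounded by one block.
.cube_similarity_block <- function(A, B, rotations) {
  An <- .normalize_cube_rows(A)
  Bn <- .normalize_cube_rows(B)
  best <- matrix(-Inf, nrow(A), nrow(B))
  for (k in seq_len(ncol(rotations))) {
    best <- pmax(best, tcrossprod(An, Bn[, rotations[, k], drop = FALSE]))
  }
  ## zero-variance cubes: convention 0, not -Inf/NaN
  zA <- rowSums(abs(An)) == 0
  zB <- rowSums(abs(Bn)) == 0
  if (any(zA)) best[zA, ] <- 0
  if (any(zB)) best[, zB] <- 0
  pmin(pmax(best, -1), 1) # clamp rounding spill
}

#' Resize cube-pair similarities onto the atlas ROIs
#'
#' Entry (I, J), I < J, is the arithmetic mean of the rotation-maximized
#' similarity over all cube pairs with one cube in ROI I and one in ROI J;
#' the lower triangle mirrors the upper and the diagonal is 0 (within-ROI
#' similarity is reported separately in the diagnostics, not stored in the
#' matrix). ROI pairs with no contributing cube pairs get value 0 and a zero
#' pair count. Cube pairs are streamed one ROI block at a time so memory is
#' bounded by the largest block, never the full cube-pair matrix.
#'
#' @param cubes a `cube_set` from [tile_cubes()].
#' @param roi_ids ROI labels defining row/column order; defaults to the
#'   sorted labels present in `cubes`.
#' @param rotations permutation matrix from [rotation_set()].
#' @return a list of class `roi_matrix`: `values` (symmetric, zero diagonal),
#'   `scale = "r"`, `roi_ids`, `n_cube_pairs` (per-entry contributing pair
#'   counts), `within_roi` (mean within-ROI similarity per ROI, diagnostics).
#' @export
resize_to_atlas <- function(cubes, roi_ids = NULL,
                            rotations = rotation_set()) {
  mn_assert(inherits(cubes, "cube_set"), "expected a cube_set")
  if (is.null(roi_ids)) roi_ids <- sort(unique(cubes$roi))
  n <- length(roi_ids)
  mn_assert(n >= 1, "no ROIs present")
  vals <- matrix(0, n, n, dimnames = list(roi_ids, roi_ids))
  npairs <- matrix(0L, n, n, dimnames = list(roi_ids, roi_ids))
  within <- rep(NA_real_, n)
  idx_by_roi <- lapply(roi_ids, function(r) which(cubes$roi == r))
  for (i in seq_len(n)) {
    Ai <- cubes$values[idx_by_roi[[i]], , drop = FALSE]
    if (nrow(Ai) >= 2) {
      blk <- .cube_similarity_block(Ai, Ai, rotations)
      within[i] <- mean(blk[upper.tri(blk)])
    }
    if (i == n) next
    for (j in seq.int(i + 1L, n)) {
      Bj <- cubes$values[idx_by_roi[[j]], , drop = FALSE]
      k <- nrow(Ai) * nrow(Bj)
      npairs[i, j] <- npairs[j, i] <- k
      if (k == 0) next
      blk <- .cube_similarity_block(Ai, Bj, rotations)
      vals[i, j] <- vals[j, i] <- mean(blk)
    }
  }
  structure(list(values = vals, scale = "r", roi_ids = roi_ids,
                 n_cube_pairs = npairs, within_roi = within),
            class = "roi_matrix")
}

#' Full single-subject similarity extraction
#'
#' Convenience wrapper: [tile_cubes()] then [resize_to_atlas()], with the ROI
#' order taken from the atlas labels (so subjects with missing ROIs still
#' align).
#'
#' @inheritParams tile_cubes
#' @param roi_ids ROI order; defaults to all labels present in the atlas.
#' @return a `roi_matrix` (scale `"r"`).
#' @export
morph_similarity <- function(gm, atlas, roi_ids = NULL, min_gm_voxels = 1L) {
  if (is.null(roi_ids))
    roi_ids <- setdiff(sort(unique(as.vector(atlas$data))), 0L)
  cubes <- tile_cubes(gm, atlas, min_gm_voxels = min_gm_voxels)
  resize_to_atlas(cubes, roi_ids = roi_ids)
}

#' @export
print.roi_matrix <- function(x, ...) {
  cat(sprintf("<roi_matrix> %d x %d, scale=%s\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}
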