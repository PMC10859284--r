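rot <- rotation_set()

test_that("rotation set has 24 elements including the identity", {
  expect_equal(ncol(rot), 24L)
  expect_true(any(apply(rot, 2, function(p) all(p == 1:27))))
  ## all distinct permutations of 1:27
  expect_equal(anyDuplicated(t(rot)), 0L)
  expect_true(all(apply(rot, 2, sort) == 1:27))
})

test_that("rotation set is closed under composition and matches the oracle", {
  keys <- apply(rot, 2, paste, collapse = ",")
  for (i in seq_len(ncol(rot))) for (j in seq_len(ncol(rot))) {
    comp <- rot[, i][rot[, j]]
    expect_true(paste(comp, collapse = ",") %in% keys)
  }
  oracle <- sort(unname(vapply(oracle_rotations(), paste, "", collapse = ",")))
  expect_equal(sort(keys), oracle)
})

test_that("including reflections doubles the set to 48", {
  expect_equal(ncol(rotation_set(include_reflections = TRUE)), 48L)
})

test_that("cube_similarity recovers rotated copies and is bounded", {
  set.seed(101)
  a <- runif(27)
  expect_equal(cube_similarity(a, a), 1)
  for (k in seq_len(ncol(rot)))
    expect_equal(cube_similarity(a, a[rot[, k]]), 1, tolerance = 1e-12)
})

test_that("cube_similarity matches the brute-force oracle on random pairs", {
  set.seed(202)
  for (rep in 1:25) {
    a <- runif(27)
    b <- runif(27)
    expect_equal(cube_similarity(a, b), oracle_cube_similarity(a, b),
                 tolerance = 1e-12)
  }
})

test_that("cube_similarity is symmetric, rotation-invariant and >= plain cor", {
  set.seed(303)
  for (rep in 1:20) {
    a <- runif(27); b <- runif(27)
    s <- cube_similarity(a, b)
    expect_equal(s, cube_similarity(b, a), tolerance = 1e-12)
    expect_gte(s + 1e-12, cor(a, b))
    g <- rot[, sample.int(24, 1)]
    expect_equal(cube_similarity(a[g], b), s, tolerance = 1e-12)
    expect_equal(cube_similarity(a, b[g]), s, tolerance = 1e-12)
  }
})

test_that("zero-variance cubes score 0 by convention", {
  expect_equal(cube_similarity(rep(0.5, 27), runif(27)), 0)
  expect_equal(cube_similarity(rep(0, 27), rep(1, 27)), 0)
})

test_that("tile_cubes tiles from the nonzero bounding box", {
  mk <- function(dims, fill = 1) {
    g <- gm_volume(array(fill, dims))
    a <- atlas_volume(array(1L, dims))
    list(g = g, a = a)
  }
  v6 <- mk(c(6, 6, 6))
  expect_equal(nrow(tile_cubes(v6$g, v6$a)$values), 8L)
  v5 <- mk(c(5, 5, 5))
  expect_equal(nrow(tile_cubes(v5$g, v5$a)$values), 1L)
  v0 <- mk(c(6, 6, 6), fill = 0)
  expect_equal(nrow(tile_cubes(v0$g, v0$a)$values), 0L)

  ## anchor follows the bounding box: zero out the first x-slab
  arr <- array(1, c(7, 6, 6))
  arr[1, , ] <- 0
  cs <- tile_cubes(gm_volume(arr), atlas_volume(array(1L, c(7, 6, 6))))
  expect_equal(cs$anchor, c(1L, 0L, 0L))
  expect_equal(nrow(cs$values), 8L)

  expect_error(tile_cubes(mk(c(6, 6, 6))$g, atlas_volume(array(1L, c(9, 6, 6)))),
               class = "mn_validation_error")
})

test_that("tile_cubes assigns majority labels with smallest-label tie-break", {
  arr <- array(1L, c(3, 3, 3))
  arr[1:3, 1:3, 1] <- 2L # 9 voxels of label 2, 18 of label 1
  cs <- tile_cubes(gm_volume(array(1, c(3, 3, 3))), atlas_volume(arr))
  expect_equal(cs$roi, 1L)
  ## exact tie 13/13 after one background voxel -> smallest label wins
  arr2 <- array(1L, c(3, 3, 3))
  arr2[14:26 + 1] <- 2L
  arr2[1] <- 0L
  cs2 <- tile_cubes(gm_volume(array(1, c(3, 3, 3))), atlas_volume(arr2))
  expect_equal(cs2$roi, 1L)
  ## majority background -> cube dropped
  arr3 <- array(0L, c(3, 3, 3))
  arr3[1:13] <- 1L
  cs3 <- tile_cubes(gm_volume(array(1, c(3, 3, 3))), atlas_volume(arr3))
  expect_equal(nrow(cs3$values), 0L)
})

test_that("resize_to_atlas averages cube-pair similarities per ROI pair", {
  ## hand-built cube set: 2 ROIs x 2 cubes with known cross similarities
  set.seed(17)
  base <- runif(27)
  mk_cube <- function(v) (v - mean(v)) / sd(v)
  cubes <- structure(list(
    values = rbind(base, base * 2 + 1, runif(27), runif(27)),
    origin = matrix(0L, 4, 3), roi = c(1L, 1L, 2L, 2L),
    anchor = c(0L, 0L, 0L)), class = "cube_set")
  m <- resize_to_atlas(cubes)
  manual <- mean(c(oracle_cube_similarity(cubes$values[1, ], cubes$values[3, ]),
                   oracle_cube_similarity(cubes$values[1, ], cubes$values[4, ]),
                   oracle_cube_similarity(cubes$values[2, ], cubes$values[3, ]),
                   oracle_cube_similarity(cubes$values[2, ], cubes$values[4, ])))
  expect_equal(m$values[1, 2], manual, tolerance = 1e-12)
  expect_equal(m$values, t(m$values))
  expect_equal(diag(m$values), c(`1` = 0, `2` = 0))
  expect_equal(m$n_cube_pairs[1, 2], 4L)
  expect_true(all(m$values >= -1 & m$values <= 1))
})

test_that("resize_to_atlas handles single-cube ROIs and missing ROIs", {
  set.seed(18)
  cubes <- structure(list(values = rbind(runif(27), runif(27)),
                          origin = matrix(0L, 2, 3), roi = c(1L, 2L),
                          anchor = c(0L, 0L, 0L)), class = "cube_set")
  m <- resize_to_atlas(cubes, roi_ids = 1:3)
  expect_equal(m$values[1, 2],
               cube_similarity(cubes$values[1, ], cubes$values[2, ]))
  ## ROI 3 has no cubes: zero similarity, zero pair counts
  expect_equal(m$values[1, 3], 0)
  expect_equal(m$n_cube_pairs[1, 3], 0L)
})

test_that("identical motifs across ROIs give similarity 1 without noise", {
  d <- synthetic_design(grid_shape = c(6, 6, 6), n_roi = 2, n_low = 1,
                        n_high = 1, shared_motif_pairs = list(c(1, 2)),
                        noise_sd = 0, seed = 4)
  at <- make_atlas(d)
  v <- make_subject_volume(at, d, "Low", 9)
  m <- morph_similarity(v, at)
  expect_equal(m$values[1, 2], 1, tolerance = 1e-12)
})
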