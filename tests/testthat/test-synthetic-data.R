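test_that("synthetic_design validates its invariants", {
  expect_error(synthetic_design(grid_shape = c(7, 6, 6)),
               class = "mn_validation_error")
  expect_error(synthetic_design(n_roi = 1), class = "mn_validation_error")
  expect_error(synthetic_design(effect_size = -1),
               class = "mn_validation_error")
  expect_error(synthetic_design(n_roi = 4, effect_edges = list(c(1, 9))),
               class = "mn_validation_error")
  expect_error(synthetic_design(n_low = 0), class = "mn_validation_error")
})

test_that("make_atlas partitions whole cubes with >= 2 cubes per ROI", {
  d <- synthetic_design(grid_shape = c(6, 6, 6), n_roi = 2, n_low = 1,
                        n_high = 1)
  at <- make_atlas(d)
  expect_equal(sort(unique(as.vector(at$data))), 1:2)
  expect_equal(as.integer(table(at$data)), c(108L, 108L)) # 4 cubes each
  ## no cube straddles ROIs: every 3-block is single-valued
  for (cx in c(0, 3)) for (cy in c(0, 3)) for (cz in c(0, 3)) {
    blk <- at$data[cx + 1:3, cy + 1:3, cz + 1:3]
    expect_length(unique(as.vector(blk)), 1)
  }

  d2 <- synthetic_design(grid_shape = c(27, 27, 27), n_roi = 16, n_low = 1,
                         n_high = 1)
  at2 <- make_atlas(d2)
  expect_false(any(at2$data == 0))
  counts <- table(at2$data)
  expect_length(counts, 16)
  expect_true(all(counts >= 2 * 27)) # >= 2 cubes per ROI
  expect_equal(sum(counts), 27^3)

  expect_error(make_atlas(synthetic_design(grid_shape = c(3, 3, 3), n_roi = 2,
                                           n_low = 1, n_high = 1)),
               class = "mn_sizing_error")
})

test_that("make_subject_volume is deterministic and validates the group", {
  d <- tiny_design()
  at <- make_atlas(d)
  v1 <- make_subject_volume(at, d, "Low", 77)
  v2 <- make_subject_volume(at, d, "Low", 77)
  expect_identical(v1$data, v2$data)
  v3 <- make_subject_volume(at, d, "Low", 78)
  expect_false(identical(v1$data, v3$data))
  expect_true(all(v1$data >= 0 & v1$data <= 1))
  expect_error(make_subject_volume(at, d, "Medium", 1),
               class = "mn_validation_error")
})

test_that("noise-free orthogonal motifs reproduce the brute-force similarity", {
  d <- synthetic_design(grid_shape = c(6, 6, 6), n_roi = 2, n_low = 1,
                        n_high = 1, noise_sd = 0, seed = 31)
  at <- make_atlas(d)
  v <- make_subject_volume(at, d, "Low", 5)
  m <- morph_similarity(v, at)
  expected <- oracle_cube_similarity(d$roi_motifs[1, ], d$roi_motifs[2, ])
  expect_equal(m$values[1, 2], expected, tolerance = 1e-12)
})

test_that("cohort round-trips through scoring to the intended groups", {
  d <- synthetic_design(grid_shape = c(6, 6, 6), n_roi = 2, n_low = 10,
                        n_high = 10, seed = 32)
  res <- make_cohort(d)
  expect_equal(nrow(res$cohort), 20)
  expect_equal(res$cohort$stress_group, res$cohort$intended_group)
  ## covariates on plausible scales
  expect_true(all(res$cohort$age >= 14 & res$cohort$age <= 15))
  expect_true(all(res$cohort$sex %in% c("F", "M")))
  expect_true(all(res$cohort$site %in% c("site1", "site2")))
})

test_that("make_cohort writes reproducible files", {
  d <- synthetic_design(grid_shape = c(6, 6, 6), n_roi = 2, n_low = 2,
                        n_high = 2, seed = 33)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  make_cohort(d, dir = d1)
  make_cohort(d, dir = d2)
  f1 <- file.path(d1, "cohort.csv"); f2 <- file.path(d2, "cohort.csv")
  c1 <- read.csv(f1); c2 <- read.csv(f2)
  c1$volume_path <- c2$volume_path <- NULL # paths differ by target dir
  expect_identical(c1, c2)
  expect_identical(digest::digest(file = file.path(d1, "sub-001_gm.nii")),
                   digest::digest(file = file.path(d2, "sub-001_gm.nii")))
  expect_true(file.exists(file.path(d1, "atlas.nii")))
  expect_true(file.exists(file.path(d1, "design.json")))
  expect_true(file.exists(file.path(d1, "roi_lookup.tsv")))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("planted effects raise High-group similarity at effect edges", {
  d <- synthetic_design(grid_shape = c(6, 6, 6), n_roi = 2, n_low = 1,
                        n_high = 1, effect_edges = list(c(1, 2)),
                        effect_size = 3, noise_sd = 0.08, seed = 34)
  at <- make_atlas(d)
  sims <- function(group) vapply(1:20, function(i) {
    v <- make_subject_volume(at, d, group, derive_seed(34, group, i))
    morph_similarity(v, at)$values[1, 2]
  }, double(1))
  expect_gt(mean(sims("High")), mean(sims("Low")))
})

test_that("simulate_edge_dataset plants an exact standardized difference", {
  data <- simulate_edge_dataset(6, 400, 400, effect_edges = list(c(1, 3)),
                                effect_size = 1.5, within_sd = 0.1, seed = 35)
  e <- attr(data, "effect_edges")
  hi <- data$edges[data$groups == "High", e]
  lo <- data$edges[data$groups == "Low", e]
  d_hat <- (mean(hi) - mean(lo)) /
    sqrt((var(hi) + var(lo)) / 2)
  expect_lt(abs(d_hat - 1.5), 0.25)
  ## null world: no planted difference anywhere
  null <- simulate_edge_dataset(6, 400, 400, effect_size = 0, seed = 36)
  t0 <- edge_tstats(null)$t
  expect_lt(max(abs(t0)), 5)
})
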