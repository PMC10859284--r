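## Synthetic registered GM volumes, toy atlas and cohort tables.
##
## The generator's world: each ROI has a fixed 27-value base texture
## ("motif"); every cube of a subject's volume carries its ROI's motif plus
## independent Gaussian voxel noise, clipped to [0, 1]. ROI pairs listed in
## shared_motif_pairs receive identical motifs, so their cube similarity is
## high; for High-group subjects the motifs at effect_edges are additionally
## blended toward each other, planting a group difference in similarity.
## Cohort rows carry 39 LEQ item ratings constructed to land inside the
## intended group's cut-off windows, plus covariates drawn from simple
## distributions mirroring an adolescent multi-site cohort: age ~ U[14, 15],
## sex ~ Bernoulli(0.5), site ~ uniform over 2 levels, PDS ~ N(16, 2.7),
## SES ~ N(7, 3).

#' Describe a synthetic dataset
#'
#' @param grid_shape voxel counts per axis, each divisible by 3.
#' @param n_roi number of ROIs (>= 2).
#' @param n_low,n_high group sizes (>= 1).
#' @param shared_motif_pairs list of 2-vectors of ROI indices assigned
#'   identical base textures.
#' @param effect_edges list of 2-vectors of ROI indices whose similarity is
#'   raised in the High group.
#' @param effect_size nonnegative scalar controlling how strongly High-group
#'   motifs at effect edges are blended toward each other (0 = null world).
#' @param noise_sd voxel noise standard deviation.
#' @param seed integer master seed; all motifs, questionnaires, covariates
#'   and subject volumes derive from it.
#' @return a list of class `synthetic_design` (includes per-ROI motifs).
#' @export
synthetic_design <- function(grid_shape = c(27, 27, 27), n_roi = 16,
                             n_low = 12, n_high = 12,
                             shared_motif_pairs = list(),
                             effect_edges = list(),
                             effect_size = 0, noise_sd = 0.05, seed = 1) {
  mn_assert(length(grid_shape) == 3 && all(grid_shape %% 3 == 0),
            "grid_shape must have 3 axes, each divisible by 3")
  mn_assert(n_roi >= 2, "n_roi must be >= 2")
  mn_assert(n_low >= 1 && n_high >= 1, "group sizes must be >= 1")
  mn_assert(effect_size >= 0, "effect_size must be >= 0")
  mn_assert(noise_sd >= 0, "noise_sd must be >= 0")
  chk_pairs <- function(ps, what) {
    for (p in ps)
      mn_assert(length(p) == 2 && all(p >= 1 & p <= n_roi) && p[1] != p[2],
                paste0(what, " must be pairs of distinct ROI indices in range"))
  }
  chk_pairs(shared_motif_pairs, "shared_motif_pairs")
  chk_pairs(effect_edges, "effect_edges")
  ## per-ROI base textures: smooth-ish random patterns centered at 0.5
  motifs <- with_seed(derive_seed(seed, "motifs"), {
    m <- matrix(stats::runif(n_roi * 27, 0.2, 0.8), n_roi, 27)
    for (p in shared_motif_pairs) m[p[2], ] <- m[p[1], ]
    m
  })
  structure(list(grid_shape = as.integer(grid_shape), n_roi = as.integer(n_roi),
                 n_low = as.integer(n_low), n_high = as.integer(n_high),
                 shared_motif_pairs = shared_motif_pairs,
                 effect_edges = effect_edges,
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = as.integer(seed), roi_motifs = motifs),
            class = "synthetic_design")
}

#' Build the toy parcellation atlas of a synthetic design
#'
#' The cube grid (grid_shape / 3 blocks per axis) is split, in lexicographic
#' cube order, into `n_roi` consecutive runs of nearly equal size, so every
#' ROI is a union of whole 3x3x3 cube blocks (no cube straddles ROIs), every
#' voxel carries exactly one label in `1..n_roi`, and every ROI holds at
#' least 2 cubes.
#'
#' @param design a [synthetic_design()].
#' @return an [atlas_volume()].
#' @export
make_atlas <- function(design) {
  mn_assert(inherits(design, "synthetic_design"), "expected a synthetic_design")
  gs <- design$grid_shape
  nc <- gs %/% 3L
  n_cubes <- prod(nc)
  if (n_cubes < 2L * design$n_roi)
    mn_stop(sprintf(
      "grid %s hosts %d cubes; %d ROIs need at least %d (>= 2 cubes each)",
      paste(gs, collapse = "x"), n_cubes, design$n_roi, 2L * design$n_roi),
      class = "mn_sizing_error")
  ## cube index -> ROI label, lexicographic cube order (x fastest)
  per <- n_cubes %/% design$n_roi
  extra <- n_cubes %% design$n_roi
  sizes <- rep(per, design$n_roi) + c(rep(1L, extra),
                                      rep(0L, design$n_roi - extra))
  cube_lab <- rep(seq_len(design$n_roi), times = sizes)
  ## expand each cube block to its 27 voxels
  vol <- array(0L, dim = gs)
  cubes <- as.matrix(expand.grid(x = seq_len(nc[1]), y = seq_len(nc[2]),
                                 z = seq_len(nc[3])))
  cubes <- cubes[order(cubes[, 1], cubes[, 2], cubes[, 3]), , drop = FALSE]
  for (i in seq_len(n_cubes)) {
    cx <- (cubes[i, 1] - 1L) * 3L
    cy <- (cubes[i, 2] - 1L) * 3L
    cz <- (cubes[i, 3] - 1L) * 3L
    vol[cx + 1:3, cy + 1:3, cz + 1:3] <- cube_lab[i]
  }
  atlas_volume(vol)
}

## motif actually used for a cube of roi r, given group and effect edges:
## High-group motifs at an effect edge are blended toward each other, which
## raises their expected similarity relative to the Low group
.effective_motifs <- function(design, group) {
  m <- design$roi_motifs
  if (group == "High" && design$effect_size > 0) {
    lam <- min(0.95, 0.15 * design$effect_size)
    base <- m
    for (p in design$effect_edges) {
      m[p[1], ] <- (1 - lam) * base[p[1], ] + lam * base[p[2], ]
      m[p[2], ] <- (1 - lam) * base[p[2], ] + lam * base[p[1], ]
    }
  }
  m
}

#' Generate one subject's registered GM volume
#'
#' Every cube block carries its ROI's (group-adjusted) motif plus independent
#' `N(0, noise_sd)` voxel noise, clipped to `[0, 1]`. Bit-identical for the
#' same `subject_seed`.
#'
#' @param atlas the atlas from [make_atlas()].
#' @param design the [synthetic_design()].
#' @param group `"Low"` or `"High"`.
#' @param subject_seed integer seed for this subject's noise stream.
#' @return a [gm_volume()].
#' @export
make_subject_volume <- function(atlas, design, group, subject_seed) {
  mn_assert(inherits(design, "synthetic_design"), "expected a synthetic_design")
  mn_assert(group %in% c("Low", "High"),
            paste0("unknown group label: ", group))
  gs <- design$grid_shape
  mn_assert(identical(dim(atlas$data), gs), "atlas grid does not match design")
  motifs <- .effective_motifs(design, group)
  vol <- array(0, dim = gs)
  nc <- gs %/% 3L
  off <- .cube_coords() + 1L # raster-order offsets 0..2
  with_seed(subject_seed, {
    for (cz in seq_len(nc[3])) for (cy in seq_len(nc[2])) for (cx in seq_len(nc[1])) {
      ox <- (cx - 1L) * 3L; oy <- (cy - 1L) * 3L; oz <- (cz - 1L) * 3L
      lab <- atlas$data[ox + 1L, oy + 1L, oz + 1L]
      vals <- motifs[lab, ] + stats::rnorm(27, 0, design$noise_sd)
      vox <- cbind(ox + off[, 1], oy + off[, 2], oz + off[, 3]) + 1L
      vol[vox] <- pmin(pmax(vals, 0), 1)
    }
  })
  gm_volume(vol)
}

## sample() that never falls into the 1:n trap on length-1 vectors
.pick <- function(x, k = 1) x[sample.int(length(x), k)]

## one subject's LEQ item ratings landing inside the intended group window
.make_leq_items <- function(group) {
  if (group == "Low") {
    n_nle <- .pick(0:5)
    lo <- max(-5L, -2L * n_nle)
    total <- if (n_nle == 0) 0L else .pick(seq(lo, -n_nle))
  } else {
    n_nle <- .pick(6:10)
    lo <- max(-20L, -2L * n_nle)
    hi <- min(-11L, -n_nle)
    total <- .pick(seq(lo, hi))
  }
  items <- rep(NA_real_, LEQ_N_ITEMS) # NA = event never experienced
  if (n_nle > 0) {
    n_minus2 <- abs(total) - n_nle # ratings: that many -2s, rest -1s
    ratings <- c(rep(-2, n_minus2), rep(-1, n_nle - n_minus2))
    items[.pick(seq_len(LEQ_N_ITEMS), n_nle)] <- ratings
  }
  ## sprinkle some neutral/positive experienced events among the rest
  free <- which(is.na(items))
  n_pos <- .pick(0:min(6, length(free)))
  if (n_pos > 0)
    items[.pick(free, n_pos)] <- .pick(rep(0:2, n_pos), n_pos)
  items
}

#' Generate a full synthetic cohort
#'
#' Writes (optionally) per-subject GM volumes and the atlas as NIfTI files,
#' and builds the cohort table: subject id, intended group, 39 LEQ item
#' ratings constructed to satisfy the intended group's cut-offs, and
#' covariates. Each subject consumes an RNG stream derived from
#' `(design$seed, subject index)`, so the cohort can be extended without
#' reshuffling existing subjects.
#'
#' @param design a [synthetic_design()].
#' @param dir output directory for NIfTI volumes and the cohort CSV; `NULL`
#'   keeps volumes in memory only.
#' @param write_volumes write per-subject `.nii` files (default `TRUE` when
#'   `dir` is given).
#' @return a list of class `synthetic_cohort`: `cohort` (data frame),
#'   `atlas`, `volumes` (list of `gm_volume`, `NULL`s if written to disk
#'   only), `paths` (file paths or `NA`), `design`.
#' @export
make_cohort <- function(design, dir = NULL, write_volumes = !is.null(dir)) {
  mn_assert(inherits(design, "synthetic_design"), "expected a synthetic_design")
  atlas <- make_atlas(design)
  n <- design$n_low + design$n_high
  groups <- rep(c("Low", "High"), c(design$n_low, design$n_high))
  ids <- sprintf("sub-%03d", seq_len(n))
  rows <- vector("list", n)
  volumes <- vector("list", n)
  paths <- rep(NA_character_, n)
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n)) {
    sseed <- derive_seed(design$seed, "subject", i)
    row <- with_seed(derive_seed(design$seed, "cohort-row", i), {
      items <- .make_leq_items(groups[i])
      data.frame(subject = ids[i], intended_group = groups[i],
                 age = round(stats::runif(1, 14, 15), 2),
                 sex = sample(c("F", "M"), 1),
                 site = sample(c("site1", "site2"), 1),
                 PDS = round(stats::rnorm(1, 16, 2.7), 2),
                 SES = round(stats::rnorm(1, 7, 3), 2),
                 t(stats::setNames(items, paste0("leq_item_",
                                                 seq_len(LEQ_N_ITEMS)))))
    })
    rows[[i]] <- row
    vol <- make_subject_volume(atlas, design, groups[i], sseed)
    if (write_volumes) {
      paths[i] <- file.path(dir, paste0(ids[i], "_gm.nii"))
      write_nifti(vol, paths[i])
    }
    volumes[[i]] <- vol
  }
  cohort <- do.call(rbind, rows)
  cohort$volume_path <- paths
  cohort <- score_cohort(cohort)
  if (!is.null(dir)) {
    write_nifti(atlas, file.path(dir, "atlas.nii"))
    utils::write.csv(cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
    rec <- design
    rec$roi_motifs <- NULL
    class(rec) <- NULL
    jsonlite::write_json(rec, file.path(dir, "design.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_roi_lookup(design$n_roi, file.path(dir, "roi_lookup.tsv"))
  }
  structure(list(cohort = cohort, atlas = atlas, volumes = volumes,
                 paths = paths, design = design),
            class = "synthetic_cohort")
}

#' Simulate an edge-level dataset with planted group effects
#'
#' Skips volume extraction and draws per-subject z-scale ROI matrices
#' directly: every edge `e` has a baseline mean `mu_e ~ N(0.5, 0.1)` and
#' per-subject values `mu_e + N(0, within_sd)`; High-group subjects get an
#' additional shift of `effect_size * within_sd` at the designated effect
#' edges, i.e. `effect_size` is exactly the standardized mean difference
#' (Cohen's d) at those edges. Used for power/calibration studies of the
#' edge statistics and group tests.
#'
#' @param n_roi number of ROIs.
#' @param n_low,n_high group sizes.
#' @param effect_edges list of ROI index pairs carrying the effect.
#' @param effect_size standardized mean difference at effect edges.
#' @param within_sd within-group edge SD (default 0.1).
#' @param seed integer seed.
#' @return an [edge_dataset()] with attribute `"effect_edges"` (edge indices
#'   in upper-triangle order).
#' @export
simulate_edge_dataset <- function(n_roi, n_low, n_high,
                                  effect_edges = list(), effect_size = 0,
                                  within_sd = 0.1, seed = 1) {
  mn_assert(n_roi >= 2, "n_roi must be >= 2")
  pairs <- upper_pairs(n_roi)
  ne <- nrow(pairs)
  eff_idx <- vapply(effect_edges, function(p) {
    p <- sort(p)
    which(pairs[, 1] == p[1] & pairs[, 2] == p[2])
  }, integer(1))
  n <- n_low + n_high
  groups <- rep(c("Low", "High"), c(n_low, n_high))
  mats <- with_seed(derive_seed(seed, "edge-sim"), {
    mu <- stats::rnorm(ne, 0.5, 0.1)
    lapply(seq_len(n), function(i) {
      v <- mu + stats::rnorm(ne, 0, within_sd)
      if (groups[i] == "High" && length(eff_idx))
        v[eff_idx] <- v[eff_idx] + effect_size * within_sd
      ut_to_matrix(v, n_roi, seq_len(n_roi))
    })
  })
  out <- edge_dataset(mats, groups)
  attr(out, "effect_edges") <- eff_idx
  out
}

#' Write a toy ROI lookup table
#'
#' Columns: label, name, hemisphere (alternating L/R), network (cycled over
#' a small set of canonical network names).
#'
#' @param n_roi number of ROIs.
#' @param path output TSV path.
#' @return the lookup data frame, invisibly.
#' @export
write_roi_lookup <- function(n_roi, path) {
  nets <- c("VisCent", "VisPeri", "SomMotA", "SomMotB", "DorsAttnA",
            "DorsAttnB", "SalVentAttnA", "SalVentAttnB", "LimbicOFC",
            "LimbicTempPole", "ContA", "ContB", "ContC", "DefaultA",
            "DefaultB", "DefaultC", "TempPar")
  lut <- data.frame(label = seq_len(n_roi),
                    name = sprintf("ROI_%03d", seq_len(n_roi)),
                    hemisphere = rep_len(c("L", "R"), n_roi),
                    network = rep_len(nets, n_roi))
  utils::write.table(lut, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(lut)
}
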