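## End-to-end pipeline: score -> extract -> z -> threshold grid -> metrics ->
## hubs/tests/FDR -> partial correlations -> NBS. Every stage reads and
## writes plain-text files in the output tree plus a JSON manifest, so stages
## can be rerun individually and reruns with the same config and seed are
## bit-identical (no timestamps enter any output file; timing goes to
## stderr).

GLOBAL_MEASURES <- c("mean_CP", "mean_DC", "LP", "E_glob", "SW")

## ---- matrix TSV helpers (lossless: 17 significant digits) ----

write_matrix_tsv <- function(m, path) {
  ids <- colnames(m) %||% seq_len(ncol(m))
  lines <- c(paste(ids, collapse = "\t"),
             apply(m, 1, function(r)
               paste(formatC(r, digits = 17, format = "g"), collapse = "\t")))
  writeLines(lines, path)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  ids <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  vals <- do.call(rbind, lapply(lines[-1], function(l)
    as.double(strsplit(l, "\t", fixed = TRUE)[[1]])))
  dimnames(vals) <- list(ids, ids)
  vals
}

write_manifest <- function(path, ...) {
  jsonlite::write_json(list(..., package_version =
                              as.character(utils::packageVersion("morphnet"))),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

stage_log <- function(stage, msg) {
  message(sprintf("[morphnet:%s] %s", stage, msg))
}

## ---- configuration ----

#' Load and validate a pipeline run configuration
#'
#' The configuration is a YAML (or JSON) file, or an equivalent list, with
#' fields: `cohort_csv`, `atlas`, `roi_lookup`, `output_dir`, `seed`, and
#' optional `sparsity_levels` (default [sparsity_grid()]), `min_gm_voxels`
#' (default 1), `n_null` (small-world null networks, default 20),
#' `covariates` (default age, sex, site, PDS, SES), and `nbs`
#' (`n_perm`, `alpha`, `mode`, `primary_threshold`). All referenced input
#' files must exist; validation happens before any compute.
#'
#' @param config a file path or a named list.
#' @return a validated config list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) {
    mn_assert(file.exists(config), paste0("config file not found: ", config),
              class = "mn_io_error")
    config <- yaml::read_yaml(config)
  }
  mn_assert(is.list(config), "config must be a list or a YAML file path")
  for (f in c("cohort_csv", "atlas", "output_dir", "seed"))
    mn_assert(!is.null(config[[f]]), paste0("config field missing: ", f))
  for (f in c("cohort_csv", "atlas", "roi_lookup")) {
    if (!is.null(config[[f]]))
      mn_assert(file.exists(config[[f]]),
                paste0("config input does not exist: ", config[[f]]),
                class = "mn_io_error")
  }
  defaults <- list(sparsity_levels = sparsity_grid(), min_gm_voxels = 1L,
                   n_null = 20L,
                   covariates = c("age", "sex", "site", "PDS", "SES"),
                   nbs = list())
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  nbs_defaults <- list(n_perm = 1000L, alpha = 0.05, mode = "edge_fdr",
                       primary_threshold = 3)
  for (nm in names(nbs_defaults))
    if (is.null(config$nbs[[nm]])) config$nbs[[nm]] <- nbs_defaults[[nm]]
  config$seed <- as.integer(config$seed)
  structure(config, class = "run_config")
}

## read the scored cohort, keeping only classified subjects with volumes
.analyzed_cohort <- function(out_dir) {
  path <- file.path(out_dir, "cohort_scored.csv")
  mn_assert(file.exists(path),
            "cohort_scored.csv not found; run the score stage first",
            class = "mn_io_error")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

## ---- stages ----

#' @rdname run_pipeline
#' @export
stage_score <- function(config) {
  config <- run_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- utils::read.csv(config$cohort_csv, stringsAsFactors = FALSE)
  cohort <- score_cohort(cohort)
  out <- file.path(config$output_dir, "cohort_scored.csv")
  utils::write.csv(cohort, out, row.names = FALSE)
  write_manifest(file.path(config$output_dir, "manifest_score.json"),
                 stage = "score", cohort_csv = config$cohort_csv,
                 cohort_sha = digest::digest(file = config$cohort_csv),
                 n_subjects = nrow(cohort),
                 groups = as.list(table(cohort$stress_group)))
  stage_log("score", sprintf("%d subjects scored", nrow(cohort)))
  invisible(out)
}

#' @rdname run_pipeline
#' @export
stage_extract <- function(config) {
  config <- run_config(config)
  cohort <- .analyzed_cohort(config$output_dir)
  mn_assert("volume_path" %in% names(cohort),
            "cohort table needs a volume_path column")
  atlas <- read_volume(config$atlas, "atlas")
  roi_ids <- setdiff(sort(unique(as.vector(atlas$data))), 0L)
  mdir <- file.path(config$output_dir, "matrices")
  dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
  rot <- rotation_set()
  for (i in seq_len(nrow(cohort))) {
    sid <- cohort$subject[i]
    gm <- read_volume(cohort$volume_path[i], "gm")
    cubes <- tile_cubes(gm, atlas, min_gm_voxels = config$min_gm_voxels)
    rmat <- resize_to_atlas(cubes, roi_ids = roi_ids, rotations = rot)
    zmat <- fisher_z(rmat)
    write_matrix_tsv(rmat$values, file.path(mdir, paste0(sid, "_r.tsv")))
    write_matrix_tsv(zmat$values, file.path(mdir, paste0(sid, "_z.tsv")))
    write_manifest(file.path(mdir, paste0(sid, "_manifest.json")),
                   stage = "extract", subject = sid,
                   volume_sha = digest::digest(file = cohort$volume_path[i]),
                   anchor = cubes$anchor, n_cubes = nrow(cubes$values),
                   min_gm_voxels = config$min_gm_voxels,
                   n_rotations = ncol(rot))
  }
  write_manifest(file.path(config$output_dir, "manifest_extract.json"),
                 stage = "extract", atlas = config$atlas,
                 atlas_sha = digest::digest(file = config$atlas),
                 roi_ids = roi_ids, n_subjects = nrow(cohort))
  stage_log("extract", sprintf("%d subjects, %d ROIs", nrow(cohort),
                               length(roi_ids)))
  invisible(mdir)
}

.subject_zmat <- function(out_dir, sid) {
  read_matrix_tsv(file.path(out_dir, "matrices", paste0(sid, "_z.tsv")))
}

#' @rdname run_pipeline
#' @export
stage_threshold <- function(config) {
  config <- run_config(config)
  cohort <- .analyzed_cohort(config$output_dir)
  ndir <- file.path(config$output_dir, "networks")
  dir.create(ndir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(cohort))) {
    sid <- cohort$subject[i]
    z <- .subject_zmat(config$output_dir, sid)
    for (s in config$sparsity_levels) {
      net <- threshold_sparsity(z, s)
      p <- which(upper.tri(net$adjacency) & net$adjacency, arr.ind = TRUE)
      el <- data.frame(roi_i = net$roi_ids[p[, 1]],
                       roi_j = net$roi_ids[p[, 2]])
      el <- el[order(el$roi_i, el$roi_j), ]
      utils::write.table(el,
        file.path(ndir, sprintf("%s_s%02d_edges.tsv", sid, round(s * 100))),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  write_manifest(file.path(config$output_dir, "manifest_threshold.json"),
                 stage = "threshold",
                 sparsity_levels = config$sparsity_levels,
                 k_rule = "round(s * n(n-1)/2)")
  stage_log("threshold", sprintf("%d subjects x %d sparsity levels",
                                 nrow(cohort), length(config$sparsity_levels)))
  invisible(ndir)
}

#' @rdname run_pipeline
#' @export
stage_metrics <- function(config) {
  config <- run_config(config)
  cohort <- .analyzed_cohort(config$output_dir)
  glob <- list()
  nodal <- list()
  for (i in seq_len(nrow(cohort))) {
    sid <- cohort$subject[i]
    z <- .subject_zmat(config$output_dir, sid)
    for (s in config$sparsity_levels) {
      net <- threshold_sparsity(z, s)
      gm <- graph_metrics(net, n_null = config$n_null,
                          seed = derive_seed(config$seed, "sw", sid, s))
      glob[[length(glob) + 1L]] <- data.frame(
        subject = sid, sparsity = s, n_edges = gm$n_edges,
        mean_CP = gm$mean_CP, mean_DC = gm$mean_DC, LP = gm$LP,
        unreachable_frac = gm$unreachable_frac, E_glob = gm$E_glob,
        SW = gm$SW)
      nodal[[length(nodal) + 1L]] <- data.frame(
        subject = sid, sparsity = s, roi = rep(net$roi_ids, 3),
        metric = rep(c("DC", "CP", "BC"), each = length(net$roi_ids)),
        value = c(gm$DC, gm$CP, gm$BC))
    }
  }
  gpath <- file.path(config$output_dir, "metrics_global.csv")
  npath <- file.path(config$output_dir, "metrics_nodal.csv")
  utils::write.csv(do.call(rbind, glob), gpath, row.names = FALSE)
  utils::write.csv(do.call(rbind, nodal), npath, row.names = FALSE)
  write_manifest(file.path(config$output_dir, "manifest_metrics.json"),
                 stage = "metrics", n_null = config$n_null,
                 seed = config$seed,
                 sparsity_levels = config$sparsity_levels)
  stage_log("metrics", "global + nodal measures written")
  invisible(c(gpath, npath))
}

## nodal long table -> subjects x nodes matrix for one metric and sparsity
.nodal_matrix <- function(nodal, cohort, metric, s) {
  sub <- nodal[nodal$metric == metric & abs(nodal$sparsity - s) < 1e-9, ]
  rois <- sort(unique(sub$roi))
  m <- matrix(NA_real_, nrow(cohort), length(rois),
              dimnames = list(cohort$subject, rois))
  idx <- cbind(match(sub$subject, cohort$subject), match(sub$roi, rois))
  m[idx] <- sub$value
  m
}

#' @rdname run_pipeline
#' @export
stage_compare <- function(config) {
  config <- run_config(config)
  cohort <- .analyzed_cohort(config$output_dir)
  glob <- utils::read.csv(file.path(config$output_dir, "metrics_global.csv"))
  nodal <- utils::read.csv(file.path(config$output_dir, "metrics_nodal.csv"))
  keep <- cohort$stress_group %in% c("Low", "High")
  groups <- cohort$stress_group
  cov_with <- config$covariates
  cov_without <- setdiff(cov_with, "SES")
  gstats <- list()
  for (s in config$sparsity_levels) {
    gsub <- glob[abs(glob$sparsity - s) < 1e-9, ]
    gsub <- gsub[match(cohort$subject, gsub$subject), ]
    for (meas in GLOBAL_MEASURES) {
      y <- gsub[[meas]]
      ## SW can be non-estimable (NA) at extreme densities for some subjects
      ok <- is.finite(y)
      for (vn in c("with_SES", "without_SES")) {
        cv <- if (vn == "with_SES") cov_with else cov_without
        enough <- all(table(factor(cohort$stress_group[ok],
                                   levels = c("Low", "High"))) >= 2)
        not_estimable <- list(estimate = NA_real_, t = NA_real_,
                              df = NA_integer_, p = NA_real_)
        ## tiny cohorts can saturate or break the model (rank deficiency);
        ## report the test as not estimable instead of aborting the run
        res <- if (enough)
          tryCatch(group_effect_lm(y[ok], cohort[ok, , drop = FALSE],
                                   covariates = cv),
                   mn_rank_error = function(e) not_estimable)
        else not_estimable
        gstats[[length(gstats) + 1L]] <- data.frame(
          sparsity = s, measure = meas, model = vn, n_used = sum(ok),
          estimate = res$estimate, t = res$t, df = res$df, p = res$p)
      }
    }
  }
  gstats <- do.call(rbind, gstats)
  ## FDR family: per (measure, model) across sparsity levels is NOT applied
  ## for global measures (single test per measure/sparsity as reported);
  ## nodal tests form one family per (metric, sparsity)
  hstats <- list()
  for (s in config$sparsity_levels) {
    for (metric in c("BC", "DC", "CP")) {
      nv <- .nodal_matrix(nodal, cohort, metric, s)
      nodes <- if (metric == "CP") seq_len(ncol(nv))
               else detect_hubs(nv[keep, , drop = FALSE], groups[keep])
      if (!length(nodes)) next
      tt <- hub_ttests(nv, nodes, groups)
      tt$roi <- colnames(nv)[tt$node]
      tt$metric <- metric
      tt$sparsity <- s
      tt$family <- sprintf("%s_s%02d", metric, round(s * 100))
      hstats[[length(hstats) + 1L]] <- tt
    }
  }
  hstats <- if (length(hstats)) do.call(rbind, hstats) else
    data.frame(node = integer(0))
  gpath <- file.path(config$output_dir, "group_stats_global.csv")
  hpath <- file.path(config$output_dir, "group_stats_nodal.csv")
  utils::write.csv(gstats, gpath, row.names = FALSE)
  utils::write.csv(hstats, hpath, row.names = FALSE)
  write_manifest(file.path(config$output_dir, "manifest_compare.json"),
                 stage = "compare", covariates_with_SES = cov_with,
                 covariates_without_SES = cov_without,
                 hub_rule = "group mean > across-node mean + 2 SD, union",
                 fdr = "BH per (metric, sparsity) family")
  stage_log("compare", sprintf("%d global tests, %d nodal tests",
                               nrow(gstats), nrow(hstats)))
  invisible(c(gpath, hpath))
}

#' @rdname run_pipeline
#' @export
stage_correlate <- function(config) {
  config <- run_config(config)
  cohort <- .analyzed_cohort(config$output_dir)
  glob <- utils::read.csv(file.path(config$output_dir, "metrics_global.csv"))
  ## whole-group analysis: every scored subject, PDS z-standardized
  Z <- data.frame(age = cohort$age, sex = factor(cohort$sex),
                  site = factor(cohort$site),
                  PDS = as.numeric(scale(cohort$PDS)))
  out <- list()
  for (s in config$sparsity_levels) {
    gsub <- glob[abs(glob$sparsity - s) < 1e-9, ]
    gsub <- gsub[match(cohort$subject, gsub$subject), ]
    for (meas in GLOBAL_MEASURES) {
      y <- gsub[[meas]]
      ok <- is.finite(y)
      pc <- tryCatch(
        partial_correlation(cohort$n_nle[ok], y[ok], Z[ok, , drop = FALSE]),
        mn_error = function(e) list(r = NA_real_, t = NA_real_,
                                    df = NA_integer_, p = NA_real_,
                                    n = sum(ok)))
      out[[length(out) + 1L]] <- data.frame(
        sparsity = s, measure = meas, r_partial = pc$r, t = pc$t,
        df = pc$df, p = pc$p, n = pc$n)
    }
  }
  path <- file.path(config$output_dir, "partial_correlations.csv")
  utils::write.csv(do.call(rbind, out), path, row.names = FALSE)
  write_manifest(file.path(config$output_dir, "manifest_correlate.json"),
                 stage = "correlate",
                 covariates = c("age", "sex", "site", "PDS_z"))
  stage_log("correlate", "partial correlations written")
  invisible(path)
}

#' @rdname run_pipeline
#' @export
stage_nbs <- function(config) {
  config <- run_config(config)
  cohort <- .analyzed_cohort(config$output_dir)
  keep <- cohort$stress_group %in% c("Low", "High")
  mats <- lapply(cohort$subject[keep],
                 function(sid) .subject_zmat(config$output_dir, sid))
  data <- edge_dataset(mats, cohort$stress_group[keep])
  res <- run_nbs(data, n_perm = config$nbs$n_perm, alpha = config$nbs$alpha,
                 mode = config$nbs$mode,
                 primary_threshold = config$nbs$primary_threshold,
                 seed = derive_seed(config$seed, "nbs"))
  lut <- if (!is.null(config$roi_lookup))
    utils::read.delim(config$roi_lookup, stringsAsFactors = FALSE) else NULL
  sig <- res$significant
  if (!is.null(lut) && nrow(sig)) {
    sig$network_i <- lut$network[match(sig$roi_i, lut$label)]
    sig$network_j <- lut$network[match(sig$roi_j, lut$label)]
  }
  spath <- file.path(config$output_dir, "nbs_significant_edges.tsv")
  tpath <- file.path(config$output_dir, "nbs_t_matrix.tsv")
  utils::write.table(sig, spath, sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(res$t_matrix, tpath)
  write_manifest(file.path(config$output_dir, "manifest_nbs.json"),
                 stage = "nbs", n_perm = res$n_perm, alpha = res$alpha,
                 mode = res$mode, seed = res$seed,
                 resolution_warning = res$warn_resolution,
                 n_significant = nrow(sig))
  stage_log("nbs", sprintf("%d significant edge(s)", nrow(sig)))
  invisible(spath)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: score, extract, threshold, metrics,
#' compare, correlate, nbs. Each stage writes its outputs plus a JSON
#' manifest under `output_dir`; a rerun with the same config and seed is
#' bit-identical. Any stage failure aborts with the stage name.
#'
#' @param config a config list or YAML path; see [run_config()].
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  stages <- list(score = stage_score, extract = stage_extract,
                 threshold = stage_threshold, metrics = stage_metrics,
                 compare = stage_compare, correlate = stage_correlate,
                 nbs = stage_nbs)
  for (nm in names(stages)) {
    t0 <- Sys.time()
    tryCatch(stages[[nm]](config), error = function(e) {
      mn_stop(sprintf("pipeline stage '%s' failed: %s", nm,
                      conditionMessage(e)), class = "mn_pipeline_error")
    })
    stage_log(nm, sprintf("done in %.1fs",
                          as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  write_manifest(file.path(config$output_dir, "manifest_run.json"),
                 stage = "run-all", seed = config$seed,
                 sparsity_levels = config$sparsity_levels,
                 nbs = config$nbs, n_null = config$n_null,
                 covariates = config$covariates)
  invisible(config$output_dir)
}
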