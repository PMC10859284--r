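## Permutation-based inference on edge connectivity strength between groups.
##
## Runs on the unthresholded z-scale ROI matrices ("connectivity strength"),
## not on binarized networks. Two multiple-comparison modes: per-edge
## permutation p-values followed by BH-FDR across edges (default; single-edge
## inference), and the classic component-extent mode where supra-threshold
## edges form components whose size is compared to the permutation
## max-component null.

#' Bundle per-subject z matrices into an edge dataset
#'
#' @param matrices list of `roi_matrix` objects (scale `"z"`) or plain
#'   symmetric matrices, one per subject, identical size and ROI order.
#' @param groups group label per subject (`"Low"`/`"High"`).
#' @return a list of class `edge_dataset`: `edges` (subjects x edges matrix
#'   of upper-triangle values), `groups`, `roi_ids`, `pairs` (edge index ->
#'   ROI pair).
#' @export
edge_dataset <- function(matrices, groups) {
  mn_assert(length(matrices) == length(groups),
            "one group label per subject matrix required")
  mn_assert(length(matrices) >= 4, "need at least 2 subjects per group")
  vals <- lapply(matrices, function(m)
    if (inherits(m, "roi_matrix")) m$values else m)
  n <- nrow(vals[[1]])
  mn_assert(all(vapply(vals, function(v)
    is.matrix(v) && all(dim(v) == n), logical(1))),
    "all subject matrices must have identical dimensions")
  roi_ids <- if (inherits(matrices[[1]], "roi_matrix"))
    matrices[[1]]$roi_ids else (rownames(vals[[1]]) %||% seq_len(n))
  pairs <- upper_pairs(n)
  edges <- t(vapply(vals, ut_values, double(nrow(pairs))))
  tb <- table(groups)
  mn_assert(length(tb) == 2 && all(tb >= 2),
            "need exactly two groups with >= 2 subjects each")
  structure(list(edges = edges, groups = as.character(groups),
                 roi_ids = roi_ids, pairs = pairs, n_roi = n),
            class = "edge_dataset")
}

## Pooled-variance two-sample t for every column of X (subjects x edges),
## High minus Low, fully vectorized. perm_ind: optional permutations x
## subjects 0/1 indicator of "High" membership -> one t matrix per row.
.edge_t_matrix <- function(X, high_ind) {
  n <- nrow(X)
  n1 <- rowSums(high_ind)            # per permutation: High group size
  n2 <- n - n1
  Tot <- colSums(X)
  Tot2 <- colSums(X^2)
  S1 <- high_ind %*% X               # perms x edges: High sums
  S1sq <- high_ind %*% (X^2)
  m1 <- S1 / n1
  m2 <- sweep(-S1, 2, Tot, `+`) / n2
  ss1 <- S1sq - S1^2 / n1
  ss2 <- sweep(-S1sq, 2, Tot2, `+`) - (sweep(-S1, 2, Tot, `+`))^2 / n2
  sp2 <- (ss1 + ss2) / (n - 2)
  sp2[sp2 < 0] <- 0                  # guard against rounding
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  num <- m1 - m2
  t <- num / se
  ## zero pooled variance: equal values -> 0; separated constants -> capped
  bad <- !is.finite(t)
  if (any(bad)) t[bad] <- ifelse(num[bad] == 0, 0, sign(num[bad]) * 1e12)
  t
}

#' Per-edge two-sample t statistics (High vs Low)
#'
#' Pooled-variance two-sample t at every upper-triangle edge, oriented as
#' High minus Low, returned as a symmetric matrix. Edges with zero pooled
#' variance but different group means are capped at a large sentinel
#' (`+/-1e12`) and flagged.
#'
#' @param data an [edge_dataset()].
#' @return list with `t_matrix` (symmetric, zero diagonal), `t` (per-edge
#'   vector), `df`, `zero_variance` (logical per-edge flag).
#' @export
edge_tstats <- function(data) {
  mn_assert(inherits(data, "edge_dataset"), "expected an edge_dataset")
  X <- data$edges
  hi <- matrix(as.numeric(data$groups == "High"), nrow = 1)
  t <- as.numeric(.edge_t_matrix(X, hi))
  list(t_matrix = ut_to_matrix(t, data$n_roi, data$roi_ids), t = t,
       df = nrow(X) - 2L, zero_variance = abs(t) >= 1e12)
}

## connected components of the graph formed by a logical edge mask
.edge_components <- function(mask, pairs, n) {
  comp <- rep(0L, n)
  nxt <- 0L
  adj <- vector("list", n)
  for (e in which(mask)) {
    i <- pairs[e, 1]; j <- pairs[e, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  for (s in seq_len(n)) {
    if (comp[s] > 0 || is.null(adj[[s]])) next
    nxt <- nxt + 1L
    frontier <- s
    comp[s] <- nxt
    while (length(frontier)) {
      nb <- unique(unlist(adj[frontier], use.names = FALSE))
      nb <- nb[comp[nb] == 0]
      comp[nb] <- nxt
      frontier <- nb
    }
  }
  comp_edge <- ifelse(mask, comp[pairs[, 1]], 0L)
  sizes <- if (nxt > 0) tabulate(comp_edge[comp_edge > 0], nbins = nxt)
           else integer(0)
  list(node_comp = comp, edge_comp = comp_edge, edge_counts = sizes)
}

#' Network-based statistics by permutation
#'
#' Observed per-edge |t| statistics are compared to a null distribution from
#' random relabelings of subjects to groups (group sizes preserved). In mode
#' `"edge_fdr"` (default) each edge gets a permutation p-value
#' `(1 + exceedances) / (n_perm + 1)` followed by BH-FDR across edges at
#' `alpha`; in mode `"component"` edges with `|t|` above `primary_threshold`
#' form components whose edge count is compared to the permutation
#' max-component-size null (classic NBS).
#'
#' @param data an [edge_dataset()].
#' @param n_perm number of permutations (>= 1).
#' @param alpha significance level in (0, 1).
#' @param mode `"edge_fdr"` or `"component"`.
#' @param primary_threshold |t| threshold forming components (mode
#'   `"component"` only; default 3).
#' @param seed integer seed for the permutation stream.
#' @return a list of class `nbs_result`: `t_matrix`, `p_uncorrected`,
#'   `p_corr` (per-edge vectors in upper-triangle order), `significant`
#'   (data frame: roi_i, roi_j, t, p_corr), `n_perm`, `alpha`, `mode`,
#'   `seed`, plus mode-specific diagnostics.
#' @export
run_nbs <- function(data, n_perm = 1000, alpha = 0.05,
                    mode = c("edge_fdr", "component"),
                    primary_threshold = 3, seed = 1) {
  mode <- match.arg(mode)
  mn_assert(inherits(data, "edge_dataset"), "expected an edge_dataset")
  mn_assert(n_perm >= 1, "n_perm must be >= 1")
  mn_assert(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  warn_resolution <- 1 / (n_perm + 1) > alpha
  X <- data$edges
  n <- nrow(X)
  n_high <- sum(data$groups == "High")
  obs <- edge_tstats(data)
  obs_t <- obs$t
  perm_ind <- with_seed(derive_seed(seed, "nbs-perm"), {
    t(vapply(seq_len(n_perm), function(b) {
      ind <- numeric(n)
      ind[sample.int(n, n_high)] <- 1
      ind
    }, numeric(n)))
  })
  perm_t <- abs(.edge_t_matrix(X, perm_ind)) # n_perm x edges
  if (mode == "edge_fdr") {
    exceed <- colSums(perm_t >= matrix(abs(obs_t), n_perm, length(obs_t),
                                       byrow = TRUE))
    p_unc <- (1 + exceed) / (n_perm + 1)
    fdr <- bh_fdr(p_unc, q = alpha)
    p_corr <- fdr$p_adjusted
    sig_edges <- which(p_corr < alpha)
    extra <- list()
  } else {
    mask_obs <- abs(obs_t) > primary_threshold
    comps <- .edge_components(mask_obs, data$pairs, data$n_roi)
    null_max <- apply(perm_t, 1, function(tt) {
      cc <- .edge_components(tt > primary_threshold, data$pairs, data$n_roi)
      if (length(cc$edge_counts)) max(cc$edge_counts) else 0L
    })
    comp_p <- vapply(seq_along(comps$edge_counts), function(ci)
      (1 + sum(null_max >= comps$edge_counts[ci])) / (n_perm + 1), double(1))
    p_unc <- rep(1, length(obs_t))
    p_corr <- rep(1, length(obs_t))
    for (ci in seq_along(comps$edge_counts)) {
      sel <- comps$edge_comp == ci
      p_unc[sel] <- comp_p[ci]
      p_corr[sel] <- comp_p[ci]
    }
    sig_edges <- which(p_corr < alpha)
    extra <- list(components = comps, component_p = comp_p,
                  null_max_component = null_max,
                  primary_threshold = primary_threshold)
  }
  sig <- data.frame(roi_i = data$roi_ids[data$pairs[sig_edges, 1]],
                    roi_j = data$roi_ids[data$pairs[sig_edges, 2]],
                    t = obs_t[sig_edges], p_corr = p_corr[sig_edges])
  structure(c(list(t_matrix = obs$t_matrix, t = obs_t,
                   p_uncorrected = p_unc, p_corr = p_corr,
                   significant = sig, n_perm = n_perm, alpha = alpha,
                   mode = mode, seed = seed,
                   warn_resolution = warn_resolution,
                   pairs = data$pairs, roi_ids = data$roi_ids),
              extra),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> mode=%s n_perm=%d alpha=%.3f: %d significant edge(s)\n",
              x$mode, x$n_perm, x$alpha, nrow(x$significant)))
  invisible(x)
}
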