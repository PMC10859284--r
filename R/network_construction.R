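## r -> z transform and proportional sparsity thresholding.

#' Fisher r-to-z transform of an ROI similarity matrix
#'
#' Elementwise `atanh` after clipping `|r|` to `1 - 1e-7` so perfect
#' correlations stay finite. Symmetry and the zero diagonal are preserved,
#' and because `atanh` is strictly increasing, thresholding the z matrix
#' selects exactly the same edges as thresholding r.
#'
#' @param m a `roi_matrix` with `scale = "r"`.
#' @return a `roi_matrix` with `scale = "z"`.
#' @export
fisher_z <- function(m) {
  mn_assert(inherits(m, "roi_matrix"), "expected a roi_matrix")
  mn_assert(identical(m$scale, "r"), "fisher_z expects an r-scale matrix")
  mn_assert(all(abs(m$values) <= 1 + 1e-12), "r values must lie in [-1, 1]")
  z <- atanh(pmin(pmax(m$values, -1 + 1e-7), 1 - 1e-7))
  diag(z) <- 0
  out <- m
  out$values <- z
  out$scale <- "z"
  out
}

#' The seven sparsity levels of the analysis grid
#'
#' @return `c(0.05, 0.10, 0.15, 0.20, 0.25, 0.30, 0.35)`.
#' @export
sparsity_grid <- function() seq(0.05, 0.35, by = 0.05)

#' Proportional sparsity thresholding to a binary network
#'
#' Keeps the `K = round(s * n(n-1)/2)` largest upper-triangle values as
#' edges and symmetrizes. Ties at the cut are resolved deterministically by
#' descending value, then ascending (row, column), which also makes edge
#' sets nested across increasing sparsity levels.
#'
#' @param m a `roi_matrix` (either scale) or a bare symmetric matrix.
#' @param s target sparsity (connection density) in (0, 1).
#' @return a list of class `binary_network`: `adjacency` (symmetric logical,
#'   zero diagonal), `sparsity`, `n_edges`, `roi_ids`.
#' @export
threshold_sparsity <- function(m, s) {
  vals <- if (inherits(m, "roi_matrix")) m$values else m
  roi_ids <- if (inherits(m, "roi_matrix")) m$roi_ids else
    (rownames(vals) %||% seq_len(nrow(vals)))
  mn_assert(is.matrix(vals) && nrow(vals) == ncol(vals),
            "expected a square matrix")
  mn_assert(is.numeric(s) && length(s) == 1 && s > 0 && s < 1,
            "sparsity must be a single value in (0, 1)")
  n <- nrow(vals)
  p <- upper_pairs(n)
  total <- nrow(p)
  K <- round(s * total)
  if (K == 0)
    mn_stop(sprintf("sparsity %.3f retains 0 of %d edges (degenerate network)",
                    s, total), class = "mn_degenerate_error")
  v <- vals[cbind(p[, 1], p[, 2])]
  sel <- order(-v, p[, 1], p[, 2])[seq_len(K)]
  adj <- matrix(FALSE, n, n, dimnames = list(roi_ids, roi_ids))
  adj[cbind(p[sel, 1], p[sel, 2])] <- TRUE
  adj <- adj | t(adj)
  structure(list(adjacency = adj, sparsity = s, n_edges = K,
                 roi_ids = roi_ids),
            class = "binary_network")
}

#' Construct a binary network directly from a logical/0-1 adjacency matrix
#'
#' Mostly for tests and small examples; symmetrizes and zeroes the diagonal.
#'
#' @param adj square logical or 0/1 matrix.
#' @return a `binary_network`.
#' @export
binary_network <- function(adj) {
  mn_assert(is.matrix(adj) && nrow(adj) == ncol(adj),
            "adjacency must be square")
  adj <- (adj | t(adj))
  diag(adj) <- FALSE
  n <- nrow(adj)
  structure(list(adjacency = adj, sparsity = sum(adj) / (n * (n - 1)),
                 n_edges = sum(adj) / 2,
                 roi_ids = rownames(adj) %||% seq_len(n)),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %d nodes, %d edges (sparsity %.3f)\n",
              nrow(x$adjacency), x$n_edges, x$sparsity))
  invisible(x)
}
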