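## Hub detection, covariate-adjusted group comparison, BH-FDR, and partial
## correlation of network measures with stress level.

#' Detect network hubs by the 2-SD rule
#'
#' A node is a hub when its group-mean nodal value (degree or betweenness)
#' exceeds the across-node mean by more than 2 across-node standard
#' deviations. Hubs are detected within each group separately and the tested
#' set is the union across groups. With zero variance across nodes the hub
#' set is empty.
#'
#' @param nodal_values subjects x nodes numeric matrix of a nodal measure.
#' @param groups character/factor of group labels per subject (one group:
#'   pass a constant vector or `NULL`).
#' @param n_sd hub threshold in SD units (default 2).
#' @return sorted integer vector of hub node indices (possibly empty).
#' @export
detect_hubs <- function(nodal_values, groups = NULL, n_sd = 2) {
  mn_assert(is.matrix(nodal_values) && ncol(nodal_values) >= 2,
            "nodal_values must be a subjects x nodes matrix with >= 2 nodes")
  if (is.null(groups)) groups <- rep("all", nrow(nodal_values))
  mn_assert(length(groups) == nrow(nodal_values),
            "groups must have one label per subject (row)")
  hubs <- integer(0)
  for (g in unique(groups)) {
    m <- colMeans(nodal_values[groups == g, , drop = FALSE])
    s <- stats::sd(m)
    if (is.na(s) || s == 0) next
    hubs <- union(hubs, which(m > mean(m) + n_sd * s))
  }
  sort(hubs)
}

#' Covariate-adjusted group effect on a global measure
#'
#' Least-squares fit of `y` on an intercept, a two-level stress-group factor
#' and the listed covariates (categorical covariates dummy-coded with the
#' first level as reference). The reported group-term t statistic and
#' two-sided p are identical to the ANCOVA F-test inference for a two-level
#' factor; with no covariates the statistic reduces exactly to a
#' pooled-variance two-sample t-test.
#'
#' @param y numeric response, one value per analyzed subject.
#' @param cohort data frame with a `stress_group` column (only `"Low"` and
#'   `"High"` rows are analyzed) and the covariate columns.
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @return a list of class `stat_result`: `estimate` (High minus Low, adjusted),
#'   `t`, `df`, `p`, `n`, `covariates`.
#' @export
group_effect_lm <- function(y, cohort,
                            covariates = c("age", "sex", "site", "PDS", "SES")) {
  mn_assert("stress_group" %in% names(cohort),
            "cohort must contain a stress_group column")
  keep <- cohort$stress_group %in% c("Low", "High")
  y <- y[keep]
  dat <- cohort[keep, , drop = FALSE]
  mn_assert(length(y) == nrow(dat), "y must have one value per cohort row")
  grp <- factor(dat$stress_group, levels = c("Low", "High"))
  mn_assert(all(table(grp) >= 2), "need >= 2 subjects per group")
  ## proportional thresholding fixes the edge count, so e.g. mean degree is
  ## identical for every subject: no variance, no testable group effect
  if (stats::sd(y) < 1e-12)
    return(structure(list(estimate = 0, t = NA_real_, df = length(y) - 2L,
                          p = NA_real_, n = length(y),
                          covariates = covariates, degenerate = TRUE),
                     class = "stat_result"))
  df <- data.frame(.y = y, .group = grp)
  for (cv in covariates) {
    mn_assert(cv %in% names(dat), paste0("missing covariate column: ", cv))
    v <- dat[[cv]]
    df[[cv]] <- if (is.character(v) || is.logical(v)) factor(v) else v
  }
  fml <- stats::as.formula(paste(".y ~ .group",
                                 if (length(covariates))
                                   paste("+", paste(covariates, collapse = " + "))
                                 else ""))
  fit <- stats::lm(fml, data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    mn_stop(paste0("design matrix is rank deficient; collinear terms: ",
                   paste(bad, collapse = ", ")), class = "mn_rank_error")
  }
  sm <- summary(fit)$coefficients
  row <- ".groupHigh"
  structure(list(estimate = unname(sm[row, "Estimate"]),
                 t = unname(sm[row, "t value"]),
                 df = fit$df.residual,
                 p = unname(sm[row, "Pr(>|t|)"]),
                 n = length(y), covariates = covariates),
            class = "stat_result")
}

#' Two-sample t-tests on nodal values at tested nodes
#'
#' Per tested node, a two-tailed pooled-variance t-test of Low versus High
#' on the nodal value (t > 0 means higher in the Low group). All tested nodes
#' of one metric at one sparsity level form one FDR family; BH-adjusted
#' p-values are appended.
#'
#' @param nodal_values subjects x nodes matrix.
#' @param nodes integer indices of nodes to test (e.g. from [detect_hubs()],
#'   or all nodes for clustering).
#' @param groups group label per subject; only `"Low"`/`"High"` rows used.
#' @param q FDR threshold used for the `significant` flag (default 0.05).
#' @return data frame: `node`, `estimate` (Low minus High mean difference),
#'   `t`, `df`, `p`, `p_corr`, `significant`.
#' @export
hub_ttests <- function(nodal_values, nodes, groups, q = 0.05) {
  mn_assert(length(nodes) >= 1, "no nodes to test")
  keep <- groups %in% c("Low", "High")
  nv <- nodal_values[keep, , drop = FALSE]
  g <- groups[keep]
  mn_assert(sum(g == "Low") >= 2 && sum(g == "High") >= 2,
            "need >= 2 subjects per group")
  res <- lapply(nodes, function(j) {
    x <- nv[g == "Low", j]
    y <- nv[g == "High", j]
    tt <- pooled_t(x, y)
    data.frame(node = j, estimate = tt$estimate, t = tt$t, df = tt$df,
               p = tt$p)
  })
  out <- do.call(rbind, res)
  out$p_corr <- bh_fdr(out$p)$p_adjusted
  out$significant <- out$p_corr <= q
  out
}

## pooled-variance two-sample t (textbook formula); zero pooled variance ->
## t = 0 when means agree, +/-Inf otherwise
pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  md <- mean(x) - mean(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- if (se == 0) { if (md == 0) 0 else sign(md) * Inf } else md / se
  df <- n1 + n2 - 2
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  list(estimate = md, t = t, df = df, p = p)
}

#' Benjamini-Hochberg step-up false discovery rate adjustment
#'
#' Adjusted p for the i-th smallest raw p is
#' `min over j >= i of min(1, m * p_(j) / j)`; rejections at level `q` are
#' the tests with adjusted p at or below `q`.
#'
#' @param p vector of raw p-values in `[0, 1]` (one FDR family).
#' @param q rejection threshold (default 0.05).
#' @return list with `p_adjusted` (same order as input) and `rejected`
#'   (logical).
#' @export
bh_fdr <- function(p, q = 0.05) {
  mn_assert(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj_sorted <- pmin(1, p[o] * m / seq_len(m))
  adj_sorted <- rev(cummin(rev(adj_sorted)))
  adj <- numeric(m)
  adj[o] <- adj_sorted
  list(p_adjusted = adj, rejected = adj <= q)
}

#' Partial correlation controlling for covariates
#'
#' Residualizes `x` and `y` on an intercept plus the covariates by least
#' squares and returns the Pearson correlation of the residuals, with a
#' two-sided p from the t distribution on `n - k - 2` degrees of freedom
#' (`k` = number of covariate columns after dummy coding). With empty
#' covariates this is the plain Pearson correlation.
#'
#' @param x,y numeric vectors (e.g. NLE count and a global graph measure).
#' @param Z `NULL`, or a data frame / matrix of covariates; character or
#'   factor columns are dummy-coded.
#' @return list with `r` (partial correlation), `t`, `df`, `p`, `n`.
#' @export
partial_correlation <- function(x, y, Z = NULL) {
  n <- length(x)
  mn_assert(length(y) == n, "x and y must have equal length")
  if (is.null(Z) || (is.data.frame(Z) && ncol(Z) == 0)) {
    zz <- matrix(1, n, 1)
    k <- 0L
  } else {
    if (!is.data.frame(Z)) Z <- as.data.frame(Z)
    mn_assert(nrow(Z) == n, "Z must have one row per observation")
    zz <- stats::model.matrix(~ ., data = Z)
    k <- ncol(zz) - 1L
    if (qr(zz)$rank < ncol(zz))
      mn_stop("covariate matrix is rank deficient", class = "mn_rank_error")
  }
  mn_assert(n > k + 2, "need n > number of covariates + 2")
  rx <- stats::lm.fit(zz, x)$residuals
  ry <- stats::lm.fit(zz, y)$residuals
  ## a variable fully explained by Z leaves only floating-point dust in the
  ## residual, whose direction is meaningless: the partial correlation is 0
  degen <- function(res, orig)
    stats::sd(res) < 1e-10 * (stats::sd(orig) + abs(mean(orig)) + 1)
  r <- if (degen(rx, x) || degen(ry, y)) 0 else stats::cor(rx, ry)
  df <- n - k - 2L
  t <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), df)
  list(r = r, t = t, df = df, p = p, n = n)
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> estimate=%.4g t=%.3f df=%d p=%.4g (n=%d)\n",
              x$estimate, x$t, x$df, x$p, x$n))
  invisible(x)
}
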