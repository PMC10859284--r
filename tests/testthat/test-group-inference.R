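test_that("detect_hubs applies the 2-SD rule per group with union", {
  nv <- matrix(1, 4, 400)
  nv[, 57] <- 10
  expect_equal(detect_hubs(nv), 57L)
  expect_equal(detect_hubs(matrix(3, 5, 20)), integer(0)) # zero variance

  ## fixture vector of 20 node means checked by direct arithmetic
  means <- c(rep(2, 18), 9, 2.5)
  nv2 <- matrix(rep(means, each = 3), 3, 20)
  expected <- which(means > mean(means) + 2 * sd(means))
  expect_equal(detect_hubs(nv2), expected)

  ## per-group detection unions group-specific hubs
  g <- c("Low", "Low", "High", "High")
  nv3 <- rbind(matrix(c(rep(1, 19), 8), 2, 20, byrow = TRUE),
               matrix(c(8, rep(1, 19)), 2, 20, byrow = TRUE))
  expect_equal(detect_hubs(nv3, g), c(1L, 20L))
})

test_that("group_effect_lm with no covariates equals the pooled t-test", {
  set.seed(10)
  cohort <- data.frame(stress_group = rep(c("Low", "High"), c(12, 9)))
  y <- rnorm(21) + (cohort$stress_group == "High") * 0.8
  res <- group_effect_lm(y, cohort, covariates = character(0))
  tt <- t.test(y[cohort$stress_group == "High"],
               y[cohort$stress_group == "Low"], var.equal = TRUE)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  expect_equal(res$df, unname(tt$parameter))
})

test_that("group_effect_lm recovers a planted effect and ignores orthogonal covariates", {
  set.seed(11)
  n <- 200
  cohort <- data.frame(stress_group = rep(c("Low", "High"), each = n / 2),
                       age = rnorm(n, 14.5, 0.5),
                       sex = sample(c("F", "M"), n, TRUE),
                       site = sample(c("s1", "s2"), n, TRUE),
                       PDS = rnorm(n, 16, 2.7), SES = rnorm(n, 7, 3))
  gamma <- 0.6
  y <- gamma * (cohort$stress_group == "High") + rnorm(n)
  res <- group_effect_lm(y, cohort)
  se <- res$estimate / res$t
  expect_lt(abs(res$estimate - gamma), 3 * se)

  ## covariate numerically orthogonalized against the group indicator
  g <- as.numeric(cohort$stress_group == "High")
  cov_orth <- rnorm(n)
  cov_orth <- residuals(lm(cov_orth ~ g))
  cohort$orth <- cov_orth
  r0 <- group_effect_lm(y, cohort, covariates = character(0))
  r1 <- group_effect_lm(y, cohort, covariates = "orth")
  expect_equal(r1$estimate, r0$estimate, tolerance = 1e-10)
})

test_that("group_effect_lm reports collinear columns", {
  cohort <- data.frame(stress_group = rep(c("Low", "High"), each = 5),
                       a = 1:10, b = 2 * (1:10))
  y <- rnorm(10)
  expect_error(group_effect_lm(y, cohort, covariates = c("a", "b")),
               class = "mn_rank_error")
  expect_error(group_effect_lm(y, cohort, covariates = "nope"),
               class = "mn_validation_error")
})

test_that("bh_fdr reproduces the hand-worked step-up example", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.50)
  res <- bh_fdr(p, q = 0.05)
  ## by hand: m=5; sorted adj = min over j>=i of 5*p_j/j =
  ## (0.05, 0.05, 0.05, 0.05, 0.5)
  expect_equal(res$p_adjusted, c(0.05, 0.05, 0.05, 0.05, 0.5))
  expect_equal(res$rejected, c(TRUE, TRUE, TRUE, TRUE, FALSE))

  expect_equal(bh_fdr(rep(1, 7))$p_adjusted, rep(1, 7))
  expect_false(any(bh_fdr(rep(1, 7))$rejected))
  expect_equal(bh_fdr(0.03)$p_adjusted, 0.03)

  ## monotone in raw p and always >= raw p
  set.seed(12)
  p2 <- runif(50)
  adj <- bh_fdr(p2)$p_adjusted
  expect_true(all(adj >= p2 - 1e-15))
  o <- order(p2)
  expect_true(all(diff(adj[o]) >= -1e-15))
  ## matches the stock implementation
  expect_equal(adj, p.adjust(p2, "BH"), tolerance = 1e-12)
})

test_that("hub_ttests computes the textbook pooled t per node with one FDR family", {
  x <- c(4.1, 3.8, 4.4, 4.0, 3.9, 4.2)
  y <- c(3.2, 3.5, 3.1, 3.6, 3.3, 3.4)
  nv <- cbind(c(x, y), rnorm(12))
  g <- rep(c("Low", "High"), each = 6)
  res <- hub_ttests(nv, 1:2, g)
  sp <- sqrt((5 * var(x) + 5 * var(y)) / 10)
  t_manual <- (mean(x) - mean(y)) / (sp * sqrt(1 / 6 + 1 / 6))
  expect_equal(res$t[1], t_manual, tolerance = 1e-12)
  expect_equal(res$df[1], 10)
  expect_equal(res$p_corr, bh_fdr(res$p)$p_adjusted)
})

test_that("hub t-test p-values are uniform under the null and detect planted shifts", {
  set.seed(13)
  n_nodes <- 1000
  g <- rep(c("Low", "High"), each = 15)
  nv <- matrix(rnorm(30 * n_nodes), 30, n_nodes)
  res <- hub_ttests(nv, seq_len(n_nodes), g)
  frac <- mean(res$p < 0.05)
  expect_lt(abs(frac - 0.05), 0.02) # binomial 3.1 SE band

  ## planted shift d = 2 at one node, n = 40/group
  hits <- 0
  for (rep in 1:20) {
    nv2 <- matrix(rnorm(80 * 50), 80, 50)
    nv2[41:80, 7] <- nv2[41:80, 7] + 2
    r2 <- hub_ttests(nv2, 1:50, rep(c("Low", "High"), each = 40))
    if (which.min(r2$p) == 7) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("partial_correlation equals Pearson with empty covariates", {
  set.seed(14)
  x <- rnorm(60); y <- 0.4 * x + rnorm(60)
  pc <- partial_correlation(x, y)
  expect_equal(pc$r, cor(x, y), tolerance = 1e-12)
  expect_equal(pc$p, cor.test(x, y)$p.value, tolerance = 1e-10)
})

test_that("partial_correlation recovers a known partial correlation", {
  set.seed(15)
  n <- 500
  z <- rnorm(n)
  rho <- 0.5
  e1 <- rnorm(n); e2 <- rho * e1 + sqrt(1 - rho^2) * rnorm(n)
  x <- 2 * z + e1
  y <- -1.5 * z + e2
  pc <- partial_correlation(x, y, data.frame(z = z))
  expect_lt(abs(pc$r - rho), 0.08)
  ## y fully explained by Z -> partial correlation 0
  pc0 <- partial_correlation(x, 3 * z + 1, data.frame(z = z))
  expect_equal(pc0$r, 0)
  ## factor covariates are dummy coded; rank deficiency is caught
  expect_error(partial_correlation(x, y, data.frame(z = z, z2 = 2 * z)),
               class = "mn_rank_error")
})
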