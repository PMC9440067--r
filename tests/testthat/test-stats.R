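test_that("Dunn z matches hand rank arithmetic", {
  # identical groups: equal mean ranks -> z = 0, p = 1
  r0 <- dunn_test(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(r0$pairwise$z, 0)
  expect_equal(r0$pairwise$p_value, 1)
  # {1,2,3} vs {4,5,6}: Rbar 2 and 5, no ties, v0 = 6*7/12 = 3.5
  r1 <- dunn_test(1:6, rep(c("a", "b"), each = 3))
  z_hand <- (2 - 5) / sqrt(3.5 * (1 / 3 + 1 / 3))
  expect_equal(r1$pairwise$z, z_hand)
  expect_equal(r1$pairwise$p_value, 2 * pnorm(-abs(z_hand)))
  # tie correction: duplicate values enter T = sum(t^3 - t)
  v <- c(1, 2, 2, 3, 4, 4)
  rt <- dunn_test(v, rep(c("a", "b"), each = 3))
  N <- 6; Tt <- (2^3 - 2) * 2
  v0 <- N * (N + 1) / 12 - Tt / (12 * (N - 1))
  rb <- tapply(rank(v), rep(c("a", "b"), each = 3), mean)
  expect_equal(rt$pairwise$z,
               unname((rb[1] - rb[2]) / sqrt(v0 * (2 / 3))))
  expect_error(dunn_test(rep(1, 6), rep(c("a", "b"), each = 3)), "degenerate")
  # BH adjustment is monotone above raw p
  r3 <- dunn_test(c(rnorm(5), rnorm(5, 3), rnorm(5, 6)),
                  rep(c("a", "b", "c"), each = 5))
  expect_true(all(r3$pairwise$adjusted_p >= r3$pairwise$p_value - 1e-12))
})

test_that("PERMANOVA separates perfectly separated groups and matches enumeration", {
  # perfect separation: zero within, positive between (groups big enough
  # that partition-preserving permutations are vanishingly rare)
  d <- matrix(1, 16, 16)
  d[1:8, 1:8] <- 0; d[9:16, 9:16] <- 0
  d <- distance_matrix(d, paste0("s", 1:16))
  gs <- rep(c("a", "b"), each = 8)
  r <- permanova(d, gs, n_permutations = 199, seed = 1)
  expect_equal(r$p_value, 1 / 200)
  g <- rep(c("a", "b"), each = 3)
  # random 6-sample distances: Monte-Carlo p ~= exhaustive enumeration
  set.seed(8)
  x <- matrix(rnorm(12), 6, 2)
  dr <- distance_matrix(as.matrix(stats::dist(x)), paste0("s", 1:6))
  p_exact <- permanova_enumerate(dr, g)
  r2 <- permanova(dr, g, n_permutations = 1999, seed = 2)
  expect_lt(abs(r2$p_value - p_exact), 0.03)
  # statistic agrees with the independently coded pseudo-F
  expect_equal(r2$statistic, pseudo_f_oracle(dr, g))
})

test_that("PERMANOVA pseudo-F agrees with vegan and pairwise mode adjusts p", {
  skip_if_not_installed("vegan")
  set.seed(9)
  x <- matrix(rnorm(30), 15, 2)
  g <- rep(c("a", "b", "c"), each = 5)
  d <- distance_matrix(as.matrix(stats::dist(x)), paste0("s", 1:15))
  r <- permanova(d, g, n_permutations = 99, seed = 1)
  va <- vegan::adonis2(stats::as.dist(d) ~ g, permutations = 99)
  expect_equal(r$statistic, va$F[1], tolerance = 1e-10)
  pw <- permanova(d, g, n_permutations = 99, seed = 1, pairwise = TRUE)
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$adjusted_p >= pw$p_value - 1e-12))
})

test_that("Mantel handles identity and independence, matching vegan on the statistic", {
  set.seed(3)
  x <- matrix(rnorm(20), 10, 2)
  d1 <- distance_matrix(as.matrix(stats::dist(x)), paste0("s", 1:10))
  m_self <- mantel_test(d1, d1, n_permutations = 199, seed = 1)
  expect_equal(m_self$statistic, 1)
  expect_lte(m_self$p_value, 0.01)
  d2 <- distance_matrix(as.matrix(stats::dist(matrix(rnorm(20), 10, 2))),
                        paste0("s", 1:10))
  m_ind <- mantel_test(d1, d2, n_permutations = 499, seed = 1)
  skip_if_not_installed("vegan")
  expect_equal(m_ind$statistic,
               unname(vegan::mantel(stats::as.dist(d1), stats::as.dist(d2),
                                    permutations = 0)$statistic),
               tolerance = 1e-10)
})

test_that("environmental PCA contributions behave for degenerate structures", {
  set.seed(5)
  base <- rnorm(30)
  env <- cbind(a = base, b = 2 * base + 3, c = rnorm(30))
  expect_warning(p <- env_pca(cbind(env, zv = 1)), "zero-variance")
  expect_equal(ncol(p$scores), 3)
  # a and b perfectly correlated: PC1 carries their joint variance equally
  expect_equal(p$contributions_pct["a", 1], p$contributions_pct["b", 1],
               tolerance = 1e-8)
  expect_true(all(abs(colSums(p$contributions_pct) - 100) < 1e-8))
  # identity covariance: eigenvalues near 1
  big <- matrix(rnorm(5000), 1000, 5)
  expect_true(all(abs(env_pca(big)$eigenvalues - 1) < 0.2))
})

test_that("VIF pruning matches a step-by-step manual execution", {
  set.seed(6)
  x1 <- rnorm(50); x2 <- rnorm(50)
  orth <- cbind(a = x1, b = x2)
  expect_equal(vif_prune(orth, 10)$retained, c("a", "b"))
  coll <- cbind(a = x1, b = x2, c = x1 + x2)
  pr <- vif_prune(coll, 10)
  expect_equal(nrow(pr$removed), 1)
  expect_true(is.infinite(pr$removed$vif[1]))
  # 5 correlated predictors: replicate the sequential rule independently
  z <- rnorm(60)
  x <- cbind(p1 = z + rnorm(60, 0, 0.1), p2 = z + rnorm(60, 0, 0.1),
             p3 = z + rnorm(60, 0, 0.1), p4 = rnorm(60), p5 = rnorm(60))
  manual <- x
  repeat {
    v <- sapply(seq_len(ncol(manual)), function(j) {
      r2 <- summary(stats::lm(manual[, j] ~ manual[, -j]))$r.squared
      1 / (1 - r2)
    })
    if (all(v < 5)) break
    manual <- manual[, -which.max(v), drop = FALSE]
  }
  expect_equal(vif_prune(x, 5)$retained, colnames(manual))
})

test_that("RDA R2 matches univariate regression and exact fits", {
  set.seed(7)
  x <- cbind(rnorm(40), rnorm(40))
  y_exact <- x %*% matrix(c(1, 2, -1, 0.5), 2, 2)
  expect_equal(rda_adjusted_r2(y_exact, x)$r_squared, 1, tolerance = 1e-12)
  y1 <- 3 * x[, 1] + rnorm(40)
  mine <- rda_adjusted_r2(matrix(y1), x)
  lmfit <- summary(stats::lm(y1 ~ x))
  expect_equal(mine$r_squared, lmfit$r.squared, tolerance = 1e-12)
  expect_equal(mine$adj_r_squared, lmfit$adj.r.squared, tolerance = 1e-12)
  expect_error(rda_adjusted_r2(matrix(rnorm(3)), matrix(rnorm(9), 3, 3)),
               "undefined")
})

test_that("variation partitioning matches inclusion-exclusion and vegan", {
  set.seed(10)
  n <- 60
  a <- matrix(rnorm(n * 2), n, 2); b <- matrix(rnorm(n * 2), n, 2)
  c_ <- matrix(rnorm(n * 2), n, 2)
  y <- cbind(a %*% c(1, 1) + rnorm(n, 0, 0.5),
             b %*% c(2, -1) + rnorm(n, 0, 0.5),
             c_ %*% c(0.5, 0.5) + rnorm(n))
  vp <- variation_partitioning(y, list(A = a, B = b, C = c_),
                               n_permutations = 99, seed = 1)
  A <- function(u) rda_adjusted_r2(y, do.call(cbind, list(a, b, c_)[u]))$adj_r_squared
  # independent inclusion-exclusion formulas for the 7 fractions
  a123 <- A(1:3)
  uA <- a123 - A(2:3); uB <- a123 - A(c(1, 3)); uC <- a123 - A(1:2)
  sAB <- A(c(1, 3)) + A(c(2, 3)) - a123 - A(3)
  sAC <- A(1:2) + A(2:3) - a123 - A(2)
  sBC <- A(1:2) + A(c(1, 3)) - a123 - A(1)
  sABC <- a123 - uA - uB - uC - sAB - sAC - sBC
  expect_equal(unname(vp$unique_fractions), c(uA, uB, uC), tolerance = 1e-10)
  expect_equal(unname(vp$fractions[["A&B"]]), sAB, tolerance = 1e-10)
  expect_equal(unname(vp$fractions[["A&B&C"]]), sABC, tolerance = 1e-10)
  expect_equal(sum(vp$fractions), vp$full_model_adj_r2, tolerance = 1e-10)
  # orthogonal two-set case: shared ~ 0, uniques match marginal models
  vp2 <- variation_partitioning(y[, 1:2], list(A = a, B = b),
                                n_permutations = 99, seed = 1)
  expect_lt(abs(vp2$fractions[["A&B"]]), 0.05)
  # duplicated set: uniques collapse, shared carries the model
  vp3 <- variation_partitioning(y, list(A = a, A2 = a), n_permutations = 99,
                                seed = 1)
  expect_lt(max(abs(vp3$unique_fractions)), 1e-10)
  expect_equal(unname(vp3$fractions[["A&A2"]]), vp3$full_model_adj_r2,
               tolerance = 1e-10)
  skip_if_not_installed("vegan")
  vv <- vegan::varpart(y, a, b, c_)
  expect_equal(unname(vp$unique_fractions),
               unname(vv$part$indfract$Adj.R.square[1:3]), tolerance = 1e-6)
  expect_error(variation_partitioning(y, list(a, b)), "named")
  expect_error(variation_partitioning(y, list(A = a)), "2 and 4")
})
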