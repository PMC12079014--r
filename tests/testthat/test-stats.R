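test_that("Mantel test behaves on identity, monotone transforms, and the null", {
  set.seed(81)
  D1 <- dist_matrix(as.matrix(dist(matrix(rnorm(30), 10))))
  r <- mantel_spearman(D1, D1, n_perm = 199)
  expect_equal(r$rho, 1)
  expect_equal(r$p_perm, 1 / 200)
  # rank correlation is invariant to strictly increasing transforms
  D2 <- dist_matrix(sqrt(unclass(D1)))
  expect_equal(mantel_spearman(D1, D2, n_perm = 99)$rho, 1)
  # independent matrices: p roughly uniform (coarse check on 40 replicates)
  ps <- replicate(40, {
    A <- dist_matrix(as.matrix(dist(matrix(rnorm(24), 8))))
    B <- dist_matrix(as.matrix(dist(matrix(rnorm(24), 8))))
    mantel_spearman(A, B, n_perm = 99)$p_perm
  })
  expect_gt(mean(ps > 0.5), 0.25)
  # permutation p-values are discrete, so ties are expected under the KS test
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  expect_error(mantel_spearman(D1, dist_matrix(unclass(D1) * 0)), "zero variance")
})

test_that("paired t test matches the closed-form statistic and is antisymmetric", {
  x <- c(2, 4, 6); y <- c(1, 2, 3)   # differences 1, 2, 3
  r <- paired_t(x, y)
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2)
  r2 <- paired_t(y, x)
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)
  z <- c(1, 2, 5)
  expect_equal(paired_t(z, z)$t, 0)
  expect_equal(paired_t(z, z)$p, 1)
  # the 45 site pairs of a 10-site gradient give df = 44
  set.seed(82)
  expect_equal(paired_t(runif(45), runif(45))$df, 44)
})

test_that("Bonferroni threshold is alpha over the family size", {
  expect_equal(bonferroni_threshold(0.05, 4), 0.0125)
  expect_equal(bonferroni_threshold(0.01, 10), 0.001)
  expect_error(bonferroni_threshold(0, 4))
})

test_that("gradient model recovers known coefficients and flags heteroscedasticity", {
  set.seed(83)
  aridity <- rep(10^seq(0, 1, length.out = 10), 2)
  season <- rep(c("wet", "dry"), each = 10)
  la <- log10(aridity) - mean(log10(aridity))
  y <- 1 + 2 * la - 3 * la^2 + 0.5 * (season == "dry")
  # noiseless fixture: lm warns that the fit is essentially perfect
  fit <- suppressWarnings(fit_gradient_lm(y, aridity, season))
  co <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(unname(co["(Intercept)"]), 1, tolerance = 1e-10)
  expect_equal(unname(co["la"]), 2, tolerance = 1e-10)
  expect_equal(unname(co["la2"]), -3, tolerance = 1e-10)
  expect_equal(unname(co["seasondry"]), 0.5, tolerance = 1e-10)
  # residuals orthogonal to the design
  X <- model.matrix(fit$model)
  expect_lt(max(abs(crossprod(X, resid(fit$model)))), 1e-8)
  # stochastic recovery of a pure quadratic effect within 2 SE
  hits <- replicate(20, {
    yy <- 2 * la^2 + rnorm(20, 0, 0.3)
    f <- fit_gradient_lm(yy, aridity, season)
    i <- match("la2", f$coefficients$term)
    abs(f$coefficients$estimate[i] - 2) < 2 * f$coefficients$se[i]
  })
  expect_gt(mean(hits), 0.8)
  # heteroscedastic noise triggers the HC3 flag most of the time
  ar6 <- rep(10^seq(0, 1, length.out = 10), 6)
  se6 <- rep(c("wet", "dry"), each = 30)
  la6 <- log10(ar6) - mean(log10(ar6))
  flags <- replicate(20, {
    yy <- la6 + rnorm(60, 0, 0.05 + 2 * (la6 - min(la6)))
    fit_gradient_lm(yy, ar6, se6)$robust_se_used
  })
  expect_gt(mean(flags), 0.5)
  expect_error(fit_gradient_lm(y, -aridity, season), "positive")
  expect_error(fit_gradient_lm(y, aridity, rep("wet", 20)), "both seasons")
})

test_that("independent components recover mixed sub-Gaussian sources", {
  set.seed(84)
  n <- 500
  S <- cbind(runif(n, -sqrt(3), sqrt(3)), runif(n, -sqrt(3), sqrt(3)))
  A <- matrix(rnorm(12), 2, 6)
  X <- S %*% A + matrix(rnorm(n * 6, 0, 0.01), n)
  r <- ipca(X, m = 2)
  cm <- abs(cor(r$scores, S))
  best <- max(min(cm[1, 1], cm[2, 2]), min(cm[1, 2], cm[2, 1]))
  expect_gt(best, 0.95)
  # uniform sources are platykurtic: negative excess kurtosis
  expect_true(all(r$kurtosis < 0))
  expect_true(all(abs(colMeans(r$scores)) < 1e-10))
  expect_lte(sum(r$explained_variance), 1 + 1e-8)
})

test_that("isotropic Gaussian data yield near-zero component kurtosis", {
  set.seed(85)
  # single draws fluctuate (the cube nonlinearity chases sampling kurtosis),
  # so bound the mean maximal |kurtosis| over replicates; genuinely
  # sub-Gaussian sources sit near -1.2, an order of magnitude away
  mk <- replicate(20, {
    X <- matrix(rnorm(500 * 4), 500)
    max(abs(ipca(X, m = 3)$kurtosis))
  })
  expect_lt(mean(mk), 0.6)
  # and the Gaussian limit tightens with sample size
  expect_lt(max(abs(ipca(matrix(rnorm(4000 * 4), 4000), m = 3)$kurtosis)), 0.4)
})

test_that("sparse components keep exactly keepX traits and degrade to dense", {
  set.seed(86)
  X <- matrix(rnorm(40 * 12), 40)
  colnames(X) <- paste0("t", 1:12)
  r <- sipca(X, m = 3, keepX = 5)
  expect_true(all(colSums(r$loadings != 0) <= 5))
  expect_equal(r$keepX, 5L)
  r1 <- sipca(X, m = 2, keepX = 1)
  expect_true(all(colSums(r1$loadings != 0) == 1))
  # keepX = trait count changes nothing
  set.seed(87); dense <- ipca(X, m = 2)
  set.seed(87); full <- sipca(X, m = 2, keepX = 12)
  expect_equal(abs(full$loadings), abs(dense$loadings), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(sipca(X, m = 2, keepX = 13), "exceeds")
})

test_that("component count follows the largest relative kurtosis drop", {
  expect_identical(select_components_by_kurtosis(c(8, 6.5, 0.4, 0.3)), 2L)
  expect_identical(select_components_by_kurtosis(c(5, 0.1)), 1L)
  expect_warning(k <- select_components_by_kurtosis(c(1, 1, 1)), "flat")
  expect_identical(k, 1L)
  expect_error(select_components_by_kurtosis(2), "at least 2")
})

test_that("MANOVA of scores against aridity calibrates and detects structure", {
  set.seed(88)
  aridity <- 10^seq(0, 1, length.out = 12)
  # strong linear dependence: p tiny
  sc <- cbind(2 * aridity + rnorm(12, 0, 1e-3), -aridity + rnorm(12, 0, 1e-3))
  r <- manova_components(sc, aridity)
  expect_lt(r$p, 1e-6)
  expect_lt(r$statistic, 0.01)     # Wilks near zero
  # m = 1 reduces to the univariate regression F = t^2
  y <- rnorm(12)
  r1 <- manova_components(cbind(y), aridity)
  tval <- summary(lm(y ~ aridity))$coefficients["aridity", "t value"]
  expect_equal(r1$approx_F, tval^2, tolerance = 1e-10)
  # permuted scores: p roughly uniform
  ps <- replicate(60, {
    sc2 <- matrix(rnorm(24), 12, 2)
    manova_components(sc2, aridity)$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
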