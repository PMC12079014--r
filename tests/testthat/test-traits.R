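test_that("mixed trait distance follows the standardize/one-hot construction", {
  # categorical-only mismatch contributes exactly 1 to squared distance
  cc <- matrix(c("x", "y", "x"), 3, 1,
               dimnames = list(c("A", "B", "C"), "strategy"))
  d <- trait_dist(trait_table(categorical = cc))
  expect_equal(d["A", "B"], 1)
  expect_equal(d["A", "C"], 0)   # identical rows
  # quantitative block equals Euclidean distance on z-scores
  set.seed(3)
  q <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("sp", 1:5), NULL))
  d2 <- unclass(trait_dist(trait_table(q)))
  z <- scale(q)
  expect_equal(d2, as.matrix(dist(z)), tolerance = 1e-12, ignore_attr = TRUE)
  # and is Euclidean-embeddable with no missing data
  expect_true(is_euclidean(trait_dist(trait_table(q))))
})

test_that("missing traits trigger availability reweighting, never imputation", {
  q <- matrix(c(0, 3, 1,
                0, 4, NA), 3, 2, dimnames = list(c("A", "B", "C"), NULL))
  d <- trait_dist(trait_table(q))
  z <- scale(q)
  # A-B pair: both traits observed
  expect_equal(unname(d["A", "B"]), sqrt(sum((z[1, ] - z[2, ])^2)),
               ignore_attr = TRUE)
  # A-C pair: one shared trait of two -> squared distance scaled by 2/1
  expect_equal(unname(d["A", "C"])^2, 2 * unname((z[1, 1] - z[3, 1])^2),
               ignore_attr = TRUE)
  # all traits missing for a species is an error
  q2 <- q; q2[3, ] <- NA
  expect_error(trait_dist(trait_table(q2)), "no observed traits")
  # zero-variance trait dropped with a warning
  q3 <- cbind(q, const = 1)
  expect_warning(trait_dist(trait_table(q3)), "zero-variance")
})

test_that("principal coordinates reproduce Euclidean configurations", {
  # collinear points at 0, 2, 6: one positive axis, gaps reproduced
  m <- as.matrix(dist(c(0, 2, 6)))
  dimnames(m) <- list(c("A", "B", "C"), c("A", "B", "C"))
  sp <- trait_pcoa(dist_matrix(m))
  expect_equal(ncol(sp$coordinates), 1)
  expect_equal(sp$correction_applied, "none")
  g <- as.matrix(dist(sp$coordinates[, 1]))
  expect_equal(g, m, tolerance = 1e-10, ignore_attr = TRUE)
  # full re-embedding of random point clouds
  set.seed(13)
  for (i in 1:10) {
    X <- matrix(rnorm(8 * 3), 8)
    D <- as.matrix(dist(X))
    sp2 <- trait_pcoa(dist_matrix(D))
    expect_lt(max(abs(as.matrix(dist(sp2$coordinates)) - D)), 1e-8)
    # axes orthogonal
    G <- crossprod(sp2$coordinates)
    expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  }
})

test_that("classical scaling agrees with an independent ordination implementation", {
  set.seed(14)
  X <- matrix(rnorm(9 * 4), 9)
  D <- as.matrix(dist(X))
  dimnames(D) <- list(paste0("s", 1:9), paste0("s", 1:9))
  ours <- trait_pcoa(dist_matrix(D))
  ref <- ape::pcoa(as.dist(D))
  k <- ncol(ours$coordinates)
  expect_equal(ours$eigenvalues, ref$values$Eigenvalues[seq_len(k)],
               tolerance = 1e-8)
  # same configuration up to axis sign
  expect_equal(abs(unname(ours$coordinates)), abs(unname(ref$vectors[, seq_len(k)])),
               tolerance = 1e-6)
})

test_that("metric violations are repaired by the Lingoes correction", {
  m <- matrix(c(0, 1, 1, 5,
                1, 0, 1, 1,
                1, 1, 0, 1,
                5, 1, 1, 0), 4)
  dimnames(m) <- list(letters[1:4], letters[1:4])
  expect_false(is_euclidean(dist_matrix(m)))
  sp <- trait_pcoa(dist_matrix(m))
  expect_equal(sp$correction_applied, "lingoes")
  expect_true(all(sp$eigenvalues >= -1e-8))
  # truncation warning when asking for more axes than exist
  m2 <- as.matrix(dist(c(0, 2, 6)))
  dimnames(m2) <- list(c("A", "B", "C"), c("A", "B", "C"))
  expect_warning(trait_pcoa(dist_matrix(m2), n_axes = 2), "truncating")
})

test_that("community weighted means are abundance-weighted and bounded", {
  m <- matrix(c(3, 1), 1, 2, dimnames = list("s1", c("A", "B")))
  ct <- community_table(m, aridity = 1, season = "wet", year = 2013)
  tt <- trait_table(matrix(c(2, 6), 2, 1, dimnames = list(c("A", "B"), "t1")))
  expect_equal(cwm(ct, tt)$t1, 3)   # (3*2 + 1*6) / 4
  # single-species site returns that species' value
  m2 <- matrix(c(5, 0), 1, 2, dimnames = list("s1", c("A", "B")))
  ct2 <- community_table(m2, aridity = 1, season = "wet", year = 2013)
  expect_equal(cwm(ct2, tt)$t1, 2)
  # invariance to uniform abundance scaling; bounds; categorical sums
  ct3 <- demo_community(); tt3 <- demo_traits()
  w1 <- cwm(ct3, tt3)
  ct4 <- community_table(ct3$abund * 7L, aridity = ct3$aridity,
                         season = ct3$season, year = ct3$year,
                         position = ct3$position)
  w2 <- cwm(ct4, tt3)
  expect_equal(w1$t1, w2$t1)
  for (s in seq_len(3)) {
    pres <- ct3$species_ids[ct3$abund[s, ] > 0]
    vals <- tt3$quantitative[pres, "t2"]
    expect_gte(w1$t2[s], min(vals, na.rm = TRUE))
    expect_lte(w1$t2[s], max(vals, na.rm = TRUE))
  }
  expect_equal(w1$strategy.x + w1$strategy.y, rep(1, 3))
  # binary-coded trait with equal abundances
  m5 <- matrix(c(1, 1), 1, 2, dimnames = list("s1", c("A", "B")))
  ct5 <- community_table(m5, aridity = 1, season = "wet", year = 2013)
  tt5 <- trait_table(matrix(c(1, 0), 2, 1, dimnames = list(c("A", "B"), "b")))
  expect_equal(cwm(ct5, tt5)$b, 0.5)
})
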