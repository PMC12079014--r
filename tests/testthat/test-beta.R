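test_that("the dimension rule caps axes at 4 and richness - 1", {
  expect_identical(choose_dimensions(10, 12), 4L)
  expect_identical(choose_dimensions(3, 9), 2L)
  expect_identical(choose_dimensions(2, 2), 1L)
  expect_identical(choose_dimensions(5, 100), 4L)
  expect_error(choose_dimensions(1, 5), "richness >= 2")
})

test_that("phylogenetic partition reproduces hand-derived star-tree cases", {
  st <- star_tree(c("A", "B", "C", "D"))
  # disjoint sites: pure turnover
  p <- phylo_beta_pair(st, c("A", "B"), c("C", "D"))
  expect_equal(p$beta_sor, 1); expect_equal(p$beta_sim, 1); expect_equal(p$beta_sne, 0)
  # nested sites: pure nestedness, a=2, b=1, c=0
  p2 <- phylo_beta_pair(st, c("A", "B", "C"), c("A", "B"))
  expect_equal(p2$beta_sim, 0)
  expect_equal(p2$beta_sor, 0.2)
  expect_equal(p2$beta_sne, 0.2)
  # identical sites
  p3 <- phylo_beta_pair(st, c("A", "B"), c("A", "B"))
  expect_equal(p3$beta_sor, 0)
  # symmetry
  p4 <- phylo_beta_pair(tiny_tree(), c("A", "C"), c("B", "C"))
  p5 <- phylo_beta_pair(tiny_tree(), c("B", "C"), c("A", "C"))
  expect_equal(p4$beta_sor, p5$beta_sor)
  expect_equal(p4$beta_sim, p5$beta_sim)
})

test_that("star-tree phylogenetic partition collapses to species-level Sorensen", {
  set.seed(71)
  tips <- paste0("sp", 1:12)
  st <- star_tree(tips)
  for (i in 1:25) {
    sa <- sample(tips, sample(2:10, 1))
    sb <- sample(tips, sample(2:10, 1))
    ref <- brute_sorensen(sa, sb)
    p <- phylo_beta_pair(st, sa, sb)
    tx <- taxonomic_beta_pair(sa, sb)
    expect_equal(p$beta_sor, ref$sor)
    expect_equal(p$beta_sim, ref$sim)
    expect_equal(tx$beta_sor, ref$sor)
    expect_equal(tx$beta_sim, ref$sim)
    # nested sets imply zero turnover
    sub <- sample(sa, 2)
    expect_equal(taxonomic_beta_pair(sa, sub)$beta_sim, 0)
    expect_equal(phylo_beta_pair(st, sa, sub)$beta_sim, 0)
  }
})

test_that("hull volumes and overlaps match geometry computed by hand", {
  sq <- as.matrix(expand.grid(0:1, 0:1))
  expect_equal(hull_volume(sq), 1)
  expect_equal(hull_volume(rbind(c(0, 0), c(1, 0), c(0, 1))), 0.5)
  expect_equal(hull_volume(cbind(c(0, 2, 6))), 6)            # 1-d interval
  expect_equal(hull_volume(rbind(rep(0, 4), diag(4))), 1 / 24)
  # identical hulls share their own volume
  ov <- hull_overlap_volume(sq, sq)
  expect_equal(ov$volume, 1)
  expect_identical(ov$method, "exact")
  # half-overlapping unit squares
  sq2 <- sweep(sq, 2, c(0.5, 0), "+")
  expect_equal(hull_overlap_volume(sq, sq2)$volume, 0.5)
  # disjoint hulls
  expect_equal(hull_overlap_volume(sq, sq + 5)$volume, 0)
})

test_that("functional partition reproduces the square-overlap cases", {
  # synthetic trait space holding two unit squares offset by half a side
  co <- rbind(as.matrix(expand.grid(0:1, 0:1)),
              sweep(as.matrix(expand.grid(0:1, 0:1)), 2, c(0.5, 0), "+"),
              as.matrix(expand.grid(0:1, 0:1)) + 10)
  rownames(co) <- paste0("sp", 1:12)
  colnames(co) <- c("Axis1", "Axis2")
  space <- structure(list(coordinates = co, eigenvalues = c(1, 1),
                          proportion_explained = c(0.5, 0.5),
                          correction_applied = "none"),
                     class = "trait_space")
  a <- paste0("sp", 1:4); b <- paste0("sp", 5:8); far <- paste0("sp", 9:12)
  p <- functional_beta_pair(space, a, b, k = 2)
  expect_equal(p$beta_sor, 0.5)    # V = 0.5, B = C = 0.5
  expect_equal(p$beta_sim, 0.5)
  expect_equal(p$beta_sne, 0)
  # disjoint squares: total turnover
  p2 <- functional_beta_pair(space, a, far, k = 2)
  expect_equal(p2$beta_sor, 1)
  expect_equal(p2$beta_sim, 1)
  # identical species sets
  p3 <- functional_beta_pair(space, a, a, k = 2)
  expect_equal(p3$beta_sor, 0)
  # degenerate (collinear) site is flagged missing
  co2 <- co; co2[5:8, 2] <- 0
  space2 <- space; space2$coordinates <- co2
  p4 <- functional_beta_pair(space2, a, b, k = 2)
  expect_true(p4$degenerate)
  expect_true(is.na(p4$beta_sor))
})

test_that("exact overlap volumes sit within 3 Monte-Carlo standard errors", {
  set.seed(72)
  for (k in 2:4) for (i in 1:5) {
    xa <- matrix(rnorm(10 * k), ncol = k)
    xb <- matrix(rnorm(10 * k), ncol = k) + 0.2
    ex <- hull_overlap_volume(xa, xb)
    expect_identical(ex$method, "exact")
    mc <- hull_overlap_volume(xa, xb, n_mc = 4e4, budget = 1)  # force fallback
    if (mc$se > 0) expect_lt(abs(ex$volume - mc$volume), 3.5 * mc$se)
  }
})

test_that("partition additivity holds to 1e-12 for every kind", {
  set.seed(73)
  tips <- paste0("sp", sprintf("%02d", 1:15))
  tr <- ape::rcoal(15); tr$tip.label <- tips
  co <- matrix(rnorm(30), 15, 2, dimnames = list(tips, NULL))
  space <- structure(list(coordinates = co, eigenvalues = c(1, 1),
                          proportion_explained = c(0.5, 0.5),
                          correction_applied = "none"),
                     class = "trait_space")
  for (i in 1:60) {
    sa <- sample(tips, sample(3:12, 1))
    sb <- sample(tips, sample(3:12, 1))
    for (p in list(taxonomic_beta_pair(sa, sb),
                   phylo_beta_pair(tr, sa, sb),
                   functional_beta_pair(space, sa, sb, k = 2))) {
      if (isTRUE(p$degenerate)) next
      expect_lt(abs(p$beta_sim + p$beta_sne - p$beta_sor), 1e-12)
      expect_gte(p$beta_sim, 0)
      expect_lte(p$beta_sor, 1)
      expect_gte(p$beta_sor, p$beta_sim)
    }
  }
})

test_that("transect summaries return n means and n-1 consecutive values", {
  b <- matrix(c(0, .2, .4,
                .2, 0, .6,
                .4, .6, 0), 3, dimnames = list(c("s1", "s2", "s3"),
                                               c("s1", "s2", "s3")))
  ts <- beta_transect_summary(b)
  expect_equal(unname(ts$mean_pairwise), c(0.3, 0.4, 0.5))
  expect_equal(unname(ts$consecutive), c(0.2, 0.6))
  expect_identical(names(ts$consecutive), c("s1-s2", "s2-s3"))
  # all-zero partitions give all-zero summaries
  z <- matrix(0, 3, 3, dimnames = dimnames(b))
  expect_true(all(unlist(beta_transect_summary(z)[1:2]) == 0))
  bna <- b; bna[1, 3] <- bna[3, 1] <- NA
  expect_error(beta_transect_summary(bna), "missing")
})

test_that("beta SES is zero under a do-nothing null and bounded for identical sites", {
  st <- star_tree(paste0("sp", 1:8))
  obs_fn <- function(tree) phylo_beta_pair(tree, paste0("sp", 1:4), paste0("sp", 3:6))
  r <- beta_ses(st, obs_fn, function(tree) tree, n_null = 10)
  expect_true(r$sor$degenerate)
  expect_equal(r$sor$ses, 0)
  # identical sites: observed 0, so SES can never be positive
  set.seed(74)
  tr <- ape::rcoal(8); tr$tip.label <- paste0("sp", 1:8)
  same_fn <- function(tree) phylo_beta_pair(tree, paste0("sp", 1:3), paste0("sp", 1:3))
  r2 <- beta_ses(tr, same_fn, function(tree) permute_tip_labels(tree), n_null = 30)
  expect_lte(r2$sor$ses, 0)
})
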