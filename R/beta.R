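#' Sorensen-family partition of pairwise beta diversity
#'
#' Total dissimilarity `beta_sor` is split into species (or branch, or
#' volume) replacement `beta_sim` and nestedness-resultant dissimilarity
#' `beta_sne = beta_sor - beta_sim`. With `a` the shared quantity and `b`, `c`
#' the quantities unique to each site:
#' `beta_sor = (b + c) / (2a + b + c)` and
#' `beta_sim = min(b, c) / (a + min(b, c))`.
#'
#' @param a,b,c shared and site-unique quantities (species counts, branch
#'   lengths, or hypervolume)
#' @param kind `"taxonomic"`, `"phylogenetic"` or `"functional"`
#' @return a `beta_partition`: named list `beta_sor`, `beta_sim`, `beta_sne`,
#'   `kind`
#' @export
beta_partition <- function(a, b, c, kind = "taxonomic") {
  if (any(c(a, b, c) < -1e-12)) stop("negative partition quantities")
  a <- max(a, 0); b <- max(b, 0); c <- max(c, 0)
  denom <- 2 * a + b + c
  if (denom == 0) stop("empty comparison: all quantities zero")
  sor <- (b + c) / denom
  mn <- min(b, c)
  sim <- if (a + mn == 0) 0 else mn / (a + mn)
  out <- list(beta_sor = sor, beta_sim = sim, beta_sne = sor - sim, kind = kind)
  class(out) <- "beta_partition"
  out
}

#' @export
print.beta_partition <- function(x, ...) {
  cat(sprintf("%s beta: sor %.4f = sim %.4f + sne %.4f\n",
              x$kind, x$beta_sor, x$beta_sim, x$beta_sne))
  invisible(x)
}

#' Taxonomic (species-level) pairwise partition
#'
#' @param sp_a,sp_b character vectors of species present at each site
#' @return a [beta_partition()] of kind `"taxonomic"`
#' @export
taxonomic_beta_pair <- function(sp_a, sp_b) {
  if (!length(sp_a) || !length(sp_b)) stop("both sites must hold species")
  a <- length(intersect(sp_a, sp_b))
  beta_partition(a, length(setdiff(sp_a, sp_b)), length(setdiff(sp_b, sp_a)),
                 kind = "taxonomic")
}

#' Phylogenetic pairwise partition on shared branch lengths
#'
#' Branch-length analogue of the Sorensen partition: on the subtree induced
#' by the union of the two sites' species (rooted at the union's most recent
#' common ancestor), `a` is the length of branches on root-to-tip paths of
#' both sites, and `b`, `c` the lengths exclusive to each. The workflow
#' applies this to the UPGMA back-transformation of the phylogenetic distance
#' fraction; any rooted tree with branch lengths is accepted.
#'
#' @param tree rooted `phylo` containing all species of both sites
#' @param sp_a,sp_b character vectors of species present at each site
#' @return a [beta_partition()] of kind `"phylogenetic"`
#' @export
phylo_beta_pair <- function(tree, sp_a, sp_b) {
  stopifnot(inherits(tree, "phylo"))
  if (!length(sp_a) || !length(sp_b)) stop("both sites must hold species")
  un <- union(sp_a, sp_b)
  miss <- setdiff(un, tree$tip.label)
  if (length(miss)) stop("species absent from tree: ", paste(miss, collapse = ", "))
  if (length(un) == 1L) return(beta_partition(1, 0, 0, kind = "phylogenetic"))
  sub <- ape::keep.tip(tree, un)
  tips <- sub$tip.label
  in_a <- tips %in% sp_a
  in_b <- tips %in% sp_b
  desc <- phangorn::Descendants(sub, sub$edge[, 2], type = "tips")
  a <- b <- c <- 0
  for (e in seq_len(nrow(sub$edge))) {
    dt <- desc[[e]]
    ha <- any(in_a[dt]); hb <- any(in_b[dt])
    len <- sub$edge.length[e]
    if (ha && hb) a <- a + len
    else if (ha) b <- b + len
    else c <- c + len
  }
  beta_partition(a, b, c, kind = "phylogenetic")
}

#' Dimension rule for hypervolume comparison
#'
#' The number of synthetic-trait axes used to compare two sites is capped at
#' 4 (algebraic limit of the hull machinery) and at the minimum richness of
#' the pair minus one (a hull in k dimensions needs k + 1 affinely
#' independent points).
#'
#' @param richness_a,richness_b species richness of the two sites (both >= 2)
#' @return integer number of dimensions, `min(4, min(richness) - 1)`
#' @examples
#' choose_dimensions(10, 12)  # 4
#' choose_dimensions(3, 9)    # 2
#' @export
choose_dimensions <- function(richness_a, richness_b) {
  if (min(richness_a, richness_b) < 2)
    stop("both sites need richness >= 2")
  as.integer(min(4, min(richness_a, richness_b) - 1))
}

#' Convex-hull volume of a point set
#'
#' Exact volume of the convex hull of points in 1 to 4 dimensions, computed
#' by facet enumeration with recursive facet measures. Degenerate (flat)
#' point sets have volume 0.
#'
#' @param x numeric matrix, points in rows (1-4 columns)
#' @return non-negative volume
#' @export
hull_volume <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) > 4) stop("hull machinery is limited to 4 dimensions")
  .chull_volume(x)
}

#' Volume of the intersection of two convex hulls
#'
#' Exact path: both hulls are converted to half-space form, the vertices of
#' the intersection polytope are enumerated from d-subsets of the pooled
#' hyperplanes, and the vertex set is measured as a hull. When the pooled
#' facet combinatorics exceed `budget` combinations the volume is instead
#' estimated by seeded Monte-Carlo rejection sampling in the intersection of
#' the bounding boxes, with the standard error reported.
#'
#' @param xa,xb numeric matrices of points (same number of columns, <= 4)
#' @param n_mc Monte-Carlo sample size for the fallback (default 1e5)
#' @param budget maximum number of hyperplane combinations for the exact path
#' @return list with `volume`, `method` (`"exact"` or `"mc"`), `se`
#'   (0 for the exact path)
#' @export
hull_overlap_volume <- function(xa, xb, n_mc = 1e5, budget = 2e6) {
  xa <- as.matrix(xa); xb <- as.matrix(xb)
  d <- ncol(xa)
  if (ncol(xb) != d) stop("dimension mismatch")
  if (d > 4) stop("hull machinery is limited to 4 dimensions")
  lo <- pmax(apply(xa, 2, min), apply(xb, 2, min))
  hi <- pmin(apply(xa, 2, max), apply(xb, 2, max))
  if (any(lo >= hi - 1e-14)) return(list(volume = 0, method = "exact", se = 0))
  fa <- .chull_facets(xa); fb <- .chull_facets(xb)
  if (nrow(fa$A) == 0 || nrow(fb$A) == 0)
    return(list(volume = 0, method = "exact", se = 0))
  v <- .chull_intersect_vertices(fa$A, fa$b, fb$A, fb$b, budget)
  if (nrow(v) == 1 && any(is.nan(v))) {
    # combinatorial budget exceeded: Monte-Carlo rejection sampling
    P <- matrix(runif(n_mc * d, rep(lo, each = n_mc), rep(hi, each = n_mc)),
                ncol = d)
    tolc <- 1e-9 * max(abs(c(fa$b, fb$b)), 1)
    inA <- rowSums(P %*% t(fa$A) > rep(fa$b + tolc, each = n_mc)) == 0
    inB <- rowSums(P %*% t(fb$A) > rep(fb$b + tolc, each = n_mc)) == 0
    frac <- mean(inA & inB)
    vbox <- prod(hi - lo)
    return(list(volume = frac * vbox, method = "mc",
                se = vbox * sqrt(frac * (1 - frac) / n_mc)))
  }
  if (nrow(v) < d + 1) return(list(volume = 0, method = "exact", se = 0))
  list(volume = .chull_volume(v), method = "exact", se = 0)
}

#' Functional pairwise partition from hypervolume overlap
#'
#' Convex hulls of the two sites' species in the first `k` synthetic-trait
#' axes; with `V` the intersection volume and `B`, `C` the volumes unique to
#' each hull, the Sorensen-family partition is applied to `(V, B, C)`.
#' Degenerate (zero-volume) hulls are rejected: the pair is returned as
#' missing with the `degenerate` flag set.
#'
#' @param space a `trait_space` from [trait_pcoa()]
#' @param sp_a,sp_b species present at each site
#' @param k number of axes, from [choose_dimensions()]; each site must hold
#'   at least `k + 1` species
#' @param ... passed to [hull_overlap_volume()]
#' @return a [beta_partition()] of kind `"functional"` with extra fields
#'   `volume_a`, `volume_b`, `volume_shared`, `method`, or a structure with
#'   `degenerate = TRUE` and `NA` components when a hull is flat
#' @export
functional_beta_pair <- function(space, sp_a, sp_b, k, ...) {
  stopifnot(inherits(space, "trait_space"))
  co <- space$coordinates
  if (k < 1 || k > min(4, ncol(co))) stop("'k' out of range")
  miss <- setdiff(union(sp_a, sp_b), rownames(co))
  if (length(miss)) stop("species absent from trait space: ",
                         paste(miss, collapse = ", "))
  if (length(sp_a) < k + 1 || length(sp_b) < k + 1)
    stop("each site needs at least k + 1 species")
  xa <- co[sp_a, seq_len(k), drop = FALSE]
  xb <- co[sp_b, seq_len(k), drop = FALSE]
  va <- hull_volume(xa)
  vb <- hull_volume(xb)
  scale_v <- max(va, vb)
  if (scale_v <= 0 || min(va, vb) <= 1e-12 * scale_v) {
    out <- list(beta_sor = NA_real_, beta_sim = NA_real_, beta_sne = NA_real_,
                kind = "functional", degenerate = TRUE)
    class(out) <- "beta_partition"
    return(out)
  }
  ov <- hull_overlap_volume(xa, xb, ...)
  vs <- min(ov$volume, va, vb)
  p <- beta_partition(vs, va - vs, vb - vs, kind = "functional")
  p$volume_a <- va; p$volume_b <- vb; p$volume_shared <- vs
  p$method <- ov$method; p$degenerate <- FALSE
  p
}

#' All pairwise beta partitions of a campaign
#'
#' Computes the Sorensen-family partition for every pair of sites with
#' richness >= 2 (and, for the functional kind, >= k + 1). Sites failing the
#' requirement are dropped with a message.
#'
#' @param comm a [community_table()]
#' @param kind `"taxonomic"`, `"phylogenetic"` or `"functional"`
#' @param tree rooted `phylo` (phylogenetic kind), typically the UPGMA
#'   back-transformation of the phylogenetic distance fraction
#' @param space a `trait_space` (functional kind)
#' @param ... passed to [functional_beta_pair()]
#' @return list of three site-by-site matrices `sor`, `sim`, `sne` (`NA` on
#'   dropped or degenerate pairs) plus `kind` and `n_degenerate`
#' @export
beta_pairwise <- function(comm, kind = c("taxonomic", "phylogenetic", "functional"),
                          tree = NULL, space = NULL, ...) {
  stopifnot(inherits(comm, "community_table"))
  kind <- match.arg(kind)
  sites <- comm$site_ids
  n <- length(sites)
  sor <- sim <- sne <- matrix(NA_real_, n, n, dimnames = list(sites, sites))
  diag(sor) <- diag(sim) <- diag(sne) <- 0
  pres <- lapply(seq_len(n), function(i)
    comm$species_ids[comm$abund[i, ] > 0])
  ndeg <- 0L
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ra <- length(pres[[i]]); rb <- length(pres[[j]])
    if (ra < 1 || rb < 1) next
    p <- switch(kind,
      taxonomic = taxonomic_beta_pair(pres[[i]], pres[[j]]),
      phylogenetic = phylo_beta_pair(tree, pres[[i]], pres[[j]]),
      functional = {
        if (min(ra, rb) < 2) NULL else {
          k <- choose_dimensions(ra, rb)
          functional_beta_pair(space, pres[[i]], pres[[j]], k, ...)
        }
      })
    if (is.null(p)) next
    if (isTRUE(p$degenerate)) { ndeg <- ndeg + 1L; next }
    sor[i, j] <- sor[j, i] <- p$beta_sor
    sim[i, j] <- sim[j, i] <- p$beta_sim
    sne[i, j] <- sne[j, i] <- p$beta_sne
  }
  list(sor = sor, sim = sim, sne = sne, kind = kind, n_degenerate = ndeg)
}

#' Transect summaries of pairwise beta diversity
#'
#' For `n` sites in transect order, returns the mean pairwise dissimilarity
#' of each site against all others (`n` values) and the dissimilarity between
#' consecutive sites (`n - 1` values).
#'
#' @param b square site-by-site dissimilarity matrix (e.g. one component from
#'   [beta_pairwise()])
#' @param transect_order site labels in transect order; default the row names
#' @return list with `mean_pairwise` (named length-`n` vector) and
#'   `consecutive` (length `n - 1`, named "site1-site2")
#' @export
beta_transect_summary <- function(b, transect_order = rownames(b)) {
  b <- as.matrix(b)
  if (any(is.na(b[transect_order, transect_order][upper.tri(b)])))
    stop("missing pairwise values along the transect")
  b <- b[transect_order, transect_order]
  n <- nrow(b)
  mp <- rowSums(b) / (n - 1)
  cons <- b[cbind(seq_len(n - 1), seq(2, n))]
  names(cons) <- paste(transect_order[-n], transect_order[-1], sep = "-")
  list(mean_pairwise = mp, consecutive = cons)
}

#' SES of a beta-diversity partition
#'
#' Applies the null-model machinery to all three partition components of one
#' site pair at once: the partition is recomputed on each null draw and each
#' component standardized against its own null distribution.
#'
#' @param source the observed distance source (tree, trait space, ...)
#' @param partition_fn function mapping a source to a [beta_partition()]
#' @param null_fn function mapping the source to one null draw of it
#' @param n_null number of null draws
#' @return list of three `ses_result` objects: `sor`, `sim`, `sne`
#' @export
beta_ses <- function(source, partition_fn, null_fn, n_null = 100) {
  obs <- partition_fn(source)
  draws <- replicate(n_null, {
    p <- tryCatch(partition_fn(null_fn(source)), error = function(e) NULL)
    if (is.null(p)) c(NA_real_, NA_real_, NA_real_)
    else c(p$beta_sor, p$beta_sim, p$beta_sne)
  })
  comp <- c(sor = "beta_sor", sim = "beta_sim", sne = "beta_sne")
  out <- lapply(seq_along(comp), function(k) {
    vals <- draws[k, ]
    i <- 0
    ses(obs[[comp[k]]],
        metric = function(v) v,
        null_source = function() { i <<- i + 1; vals[i] },
        n_null = n_null)
  })
  names(out) <- names(comp)
  out
}

#' Permute tip labels of a tree among a species pool
#'
#' One draw of the random-tips null on a tree: labels of the pool tips are
#' uniformly permuted; topology and branch lengths are untouched.
#'
#' @param tree a `phylo`
#' @param pool tip labels to permute among themselves; default all tips
#' @return the relabelled `phylo`
#' @export
permute_tip_labels <- function(tree, pool = NULL) {
  if (is.null(pool)) pool <- tree$tip.label
  if (length(pool) < 2) stop("pool must contain at least 2 species")
  i <- match(pool, tree$tip.label)
  if (anyNA(i)) stop("pool species absent from tree")
  tree$tip.label[i] <- pool[sample(length(pool))]
  tree
}
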