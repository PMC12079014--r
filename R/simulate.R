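#' Assembly scenario description
#'
#' Bundles the ground-truth parameters of a synthetic gradient study:
#' a 10-site transect sampled in two seasons of two years, a species pool of
#' ~60 species in two major clades, traits with partial phylogenetic signal,
#' and an assembly rule. Under `"filtering"`, the relative abundance of
#' species i at site s is proportional to
#' `exp(-(x_i - mu_s)^2 / (2 * filter_strength^2))` where `x_i` is the focal
#' trait and the optimum `mu_s` moves along the gradient by `optimum_shift`
#' trait standard deviations (from `-optimum_shift` at the least arid to
#' `+optimum_shift` at the most arid end); the dry season halves the filter
#' width at every site, emulating the homogenization of conditions under
#' drought. `"neutral"` assembles sites uniformly from the pool; under
#' `"repulsion"` a fixed number of species per site is drawn sequentially
#' with probability proportional to the minimal trait distance to the
#' already-chosen set (limiting similarity).
#'
#' @param n_species pool size (default 60)
#' @param n_sites sites along the transect (default 10)
#' @param years campaign years (default 2013:2014)
#' @param assembly `"neutral"`, `"filtering"` or `"repulsion"`
#' @param filter_strength Gaussian filter width in trait sd units
#'   (default 0.5)
#' @param signal fraction of trait variance from Brownian motion on the tree,
#'   in `[0, 1]` (default 0.8)
#' @param optimum_shift movement of the filtered optimum over half the
#'   gradient, in trait sd units (default 1)
#' @param n_traits number of quantitative traits (default 5)
#' @param richness_repulsion species per site under repulsion (default 15)
#' @param logseries_p log-series parameter for per-species individual counts
#'   (default 0.99, strongly uneven dominance)
#' @param seed integer RNG seed
#' @return a named list of class `assembly_scenario`
#' @export
assembly_scenario <- function(n_species = 60, n_sites = 10,
                              years = 2013:2014,
                              assembly = c("neutral", "filtering", "repulsion"),
                              filter_strength = 0.5, signal = 0.8,
                              optimum_shift = 1, n_traits = 5,
                              richness_repulsion = 15, logseries_p = 0.99,
                              seed = 1L) {
  assembly <- match.arg(assembly)
  if (n_species < 2 || n_sites < 1) stop("counts must be positive")
  if (signal < 0 || signal > 1) stop("'signal' must lie in [0, 1]")
  if (filter_strength < 0) stop("'filter_strength' must be >= 0")
  x <- list(n_species = n_species, n_sites = n_sites, years = years,
            assembly = assembly, filter_strength = filter_strength,
            signal = signal, optimum_shift = optimum_shift,
            n_traits = n_traits, richness_repulsion = richness_repulsion,
            logseries_p = logseries_p, seed = as.integer(seed))
  class(x) <- "assembly_scenario"
  x
}

#' Simulate an ultrametric species tree
#'
#' Pure-birth tree rescaled to height 1. With `two_clade = TRUE` (default)
#' the pool is split into two subtrees joined by a basal split at depth
#' `split_depth`, emulating a pool dominated by two major clades
#' (e.g. two subfamilies).
#'
#' @param n_species number of tips (>= 2)
#' @param two_clade build the two-clade topology (default `TRUE`)
#' @param split_depth depth of the basal split as a fraction of tree height
#' @return an ultrametric `phylo` with tips `sp01, sp02, ...`
#' @export
simulate_tree <- function(n_species, two_clade = TRUE, split_depth = 0.5) {
  if (n_species < 2) stop("'n_species' must be >= 2")
  scale_to <- function(tr, h) {
    tr$edge.length <- tr$edge.length * h / max(node_depths(tr))
    tr
  }
  if (!two_clade || n_species < 4) {
    tr <- scale_to(ape::rphylo(n_species, birth = 1, death = 0), 1)
  } else {
    n1 <- floor(n_species / 2)
    t1 <- scale_to(ape::rphylo(n1, 1, 0), 1 - split_depth)
    t2 <- scale_to(ape::rphylo(n_species - n1, 1, 0), 1 - split_depth)
    t1$root.edge <- split_depth
    t2$root.edge <- split_depth
    tr <- ape::bind.tree(t1, t2, position = split_depth)
  }
  tr$tip.label <- sprintf("sp%02d", seq_len(n_species))
  tr
}

#' Simulate traits with partial phylogenetic signal
#'
#' Each quantitative trait is a mixture
#' `sqrt(signal) * BM + sqrt(1 - signal) * N(0, 1)` where BM is a unit-rate
#' Brownian motion on the tree (variance 1 at the tips of a height-1 tree),
#' so `signal` is the fraction of trait variance attributable to phylogeny.
#' Optionally a two-level categorical trait is derived by thresholding an
#' extra latent BM trait at its median, emulating an evolutionarily conserved
#' strategy such as dung relocation behaviour.
#'
#' @param tree ultrametric `phylo`
#' @param n_traits number of quantitative traits
#' @param signal fraction of variance from the tree, in `[0, 1]`
#' @param categorical also derive one categorical trait (default `FALSE`)
#' @return a [trait_table()]
#' @export
simulate_traits <- function(tree, n_traits = 5, signal = 0.5,
                            categorical = FALSE) {
  if (signal < 0 || signal > 1) stop("'signal' must lie in [0, 1]")
  n <- length(tree$tip.label)
  V <- ape::vcv(tree)
  L <- chol(V)
  bm <- t(L) %*% matrix(rnorm(n * n_traits), n)
  X <- sqrt(signal) * bm + sqrt(1 - signal) * matrix(rnorm(n * n_traits), n)
  rownames(X) <- rownames(V)
  X <- X[tree$tip.label, , drop = FALSE]
  colnames(X) <- paste0("trait", seq_len(n_traits))
  cm <- NULL
  if (categorical) {
    lat <- as.vector(t(L) %*% rnorm(n))
    names(lat) <- rownames(V)
    lat <- lat[tree$tip.label]
    cm <- matrix(ifelse(lat > stats::median(lat), "endocoprid", "paracoprid"),
                 ncol = 1, dimnames = list(tree$tip.label, "relocation"))
  }
  trait_table(X, cm, species_ids = tree$tip.label)
}

# log-series individual counts (Fisher), k = 1, 2, ...
rlogseries <- function(n, p = 0.99, kmax = 5000) {
  k <- seq_len(kmax)
  pr <- p^k / k
  sample.int(kmax, n, replace = TRUE, prob = pr)
}

#' Simulate gradient-structured communities
#'
#' Builds one [community_table()] per season and year under the scenario's
#' assembly rule. Aridity values are spaced uniformly on a log scale from 1
#' to 10 along the transect. Per-site total abundance is the sum of
#' log-series individual counts over the pool (strongly uneven dominance);
#' individuals are then drawn multinomially with the assembly-rule
#' probabilities. Years are independent draws from the same expected
#' composition. A draw leaving a site with fewer than 2 species is resampled
#' (up to 20 times) with a warning.
#'
#' @param scenario an [assembly_scenario()]
#' @param tree the species tree (from [simulate_tree()])
#' @param traits the trait table (from [simulate_traits()]); the first
#'   quantitative trait is the focal filtered trait
#' @return named list of `community_table` objects
#'   (`wet_<year>`, `dry_<year>`)
#' @export
simulate_communities <- function(scenario, tree, traits) {
  stopifnot(inherits(scenario, "assembly_scenario"))
  sp <- tree$tip.label
  n_sp <- length(sp)
  x <- as.vector(scale(traits$quantitative[sp, 1]))
  Xall <- scale(traits$quantitative[sp, , drop = FALSE])
  Df <- as.matrix(dist(Xall))
  n_sites <- scenario$n_sites
  aridity <- 10^seq(0, 1, length.out = n_sites)
  u <- if (n_sites == 1) 0.5 else seq(0, 1, length.out = n_sites)
  out <- list()
  for (season in c("wet", "dry")) {
    w <- scenario$filter_strength
    if (season == "dry") w <- w / 2
    # expected per-site composition, fixed across years
    probs <- vector("list", n_sites)
    for (s in seq_len(n_sites)) {
      probs[[s]] <- switch(scenario$assembly,
        neutral = rep(1 / n_sp, n_sp),
        filtering = {
          mu <- scenario$optimum_shift * (2 * u[s] - 1)
          p <- exp(-(x - mu)^2 / (2 * max(w, 1e-8)^2))
          p / sum(p)
        },
        repulsion = {
          k <- min(scenario$richness_repulsion, n_sp)
          chosen <- sample.int(n_sp, 1)
          while (length(chosen) < k) {
            cand <- setdiff(seq_len(n_sp), chosen)
            pr <- vapply(cand, function(j) min(Df[j, chosen]), numeric(1))
            chosen <- c(chosen, cand[sample.int(length(cand), 1,
                                                prob = pr + 1e-12)])
          }
          p <- numeric(n_sp)
          p[chosen] <- 1 / k
          p
        })
    }
    for (year in scenario$years) {
      ab <- matrix(0L, n_sites, n_sp,
                   dimnames = list(sprintf("site%02d", seq_len(n_sites)), sp))
      for (s in seq_len(n_sites)) {
        N <- sum(rlogseries(n_sp, scenario$logseries_p))
        for (try in seq_len(20)) {
          a <- as.vector(rmultinom(1, N, probs[[s]]))
          if (sum(a > 0) >= 2) break
          if (try == 20) warning("site resampling limit reached; keeping draw")
        }
        ab[s, ] <- a
      }
      out[[paste(season, year, sep = "_")]] <-
        community_table(ab, aridity = aridity, season = season, year = year,
                        position = seq_len(n_sites))
    }
  }
  out
}

#' Simulate a full synthetic study
#'
#' Seeds the RNG from the scenario, then simulates the tree, the traits
#' (with one categorical trait), and all campaigns, giving a closed loop
#' with the analysis pipeline: the outputs are the exact objects the
#' readers produce from files. Fixed seed implies bit-identical output.
#'
#' @param scenario an [assembly_scenario()]
#' @return list with `tree`, `traits`, `campaigns` (list of
#'   [community_table()]), `scenario`
#' @examples
#' sim <- simulate_study(assembly_scenario(n_species = 20, seed = 42))
#' names(sim$campaigns)
#' @export
simulate_study <- function(scenario = assembly_scenario()) {
  set.seed(scenario$seed)
  tree <- simulate_tree(scenario$n_species)
  traits <- simulate_traits(tree, n_traits = scenario$n_traits,
                            signal = scenario$signal, categorical = TRUE)
  campaigns <- simulate_communities(scenario, tree, traits)
  list(tree = tree, traits = traits, campaigns = campaigns,
       scenario = scenario)
}
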