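#' Decouple functional from phylogenetic species dissimilarity
#'
#' Separates species dissimilarity into the whole phylogenetic fraction
#' (`Pdist`, returned as the unaltered input phylogenetic distance) and the
#' phylogeny-independent functional fraction (`dcFdist`). Both matrices are
#' projected to principal coordinates; the functional coordinates are then
#' regressed (multivariate least squares) on the retained phylogenetic
#' coordinate axes and `dcFdist` is the Euclidean distance among the residual
#' functional coordinates, which is Euclidean-embeddable by construction. The
#' shared fraction `jointFPdist` is the proportion of total functional
#' variance explained by the phylogenetic axes; it is the diagnostic for how
#' redundant the two facets are (small values mean traits carry information
#' beyond phylogeny).
#'
#' Phylogenetic predictor axes are selected by the broken-stick rule on the
#' positive eigenvalues (capped at `n_species - 2` so residual degrees of
#' freedom remain); using every positive axis would saturate the regression
#' and drive `jointFPdist` to 1 for any trait set.
#'
#' @param fdist functional [dist_matrix()] (e.g. from [trait_dist()])
#' @param pdist phylogenetic [dist_matrix()] (e.g. from [cophenetic_dist()]),
#'   same species in the same order
#' @param axis_rule `"broken_stick"` (default) or `"all_positive"` for the
#'   saturating variant (capped at `n - 2`)
#' @return a `decouple_result`: list with `Pdist`, `dcFdist`, `jointFPdist`,
#'   `n_axes_phylo`, `n_axes_fun`, `residual_ratio` (residual / total
#'   functional variance, an instability diagnostic)
#' @examples
#' tr <- ape::rcoal(12)
#' pd <- cophenetic_dist(tr)
#' X <- matrix(rnorm(36), 12, dimnames = list(tr$tip.label, NULL))
#' dec <- decouple_dist(dist_matrix(as.matrix(dist(X))), pd)
#' dec$jointFPdist
#' @export
decouple_dist <- function(fdist, pdist, axis_rule = c("broken_stick", "all_positive")) {
  axis_rule <- match.arg(axis_rule)
  Fm <- as_matrix(fdist); Pm <- as_matrix(pdist)
  if (!identical(rownames(Fm), rownames(Pm)))
    stop("functional and phylogenetic matrices must share species in the same order")
  n <- nrow(Fm)
  if (n < 3) stop("need at least 3 species")
  sp_p <- trait_pcoa(Pm)
  sp_f <- trait_pcoa(Fm)
  ev <- sp_p$eigenvalues
  keep <- if (axis_rule == "broken_stick") {
    prop <- ev / sum(ev)
    bs <- rev(cumsum(1 / rev(seq_along(ev)))) / length(ev)
    k <- 0
    for (i in seq_along(ev)) if (prop[i] > bs[i]) k <- i else break
    max(k, 1)
  } else length(ev)
  keep <- min(keep, n - 2)
  if (keep >= n - 1)
    stop("phylogenetic coordinates saturate the regression (rank >= n - 1)")
  P <- sp_p$coordinates[, seq_len(keep), drop = FALSE]
  Fc <- sp_f$coordinates
  R <- resid(lm(Fc ~ P))
  dcF <- dist_matrix(as.matrix(dist(R)))
  totF <- sum(Fc^2)
  out <- list(Pdist = dist_matrix(Pm),
              dcFdist = dcF,
              jointFPdist = max(0, min(1, 1 - sum(R^2) / totF)),
              n_axes_phylo = keep,
              n_axes_fun = ncol(Fc),
              residual_ratio = sum(R^2) / totF)
  class(out) <- "decouple_result"
  out
}

#' @export
print.decouple_result <- function(x, ...) {
  cat("Decoupled species dissimilarity\n")
  cat(sprintf("  jointFPdist (shared fraction): %.3f\n", x$jointFPdist))
  cat(sprintf("  phylogenetic predictor axes:   %d\n", x$n_axes_phylo))
  cat(sprintf("  functional axes:               %d\n", x$n_axes_fun))
  cat(sprintf("  residual/total variance:       %.3f\n", x$residual_ratio))
  invisible(x)
}

#' Decouple across a set of trees
#'
#' Repeats the decoupling once per tree of a tree set (posterior sample or
#' synthetic) and summarizes `jointFPdist` across trees; downstream metrics
#' computed per tree can then be averaged with an uncertainty interval.
#'
#' @param fdist functional [dist_matrix()]
#' @param trees list of `phylo` objects sharing the species of `fdist`
#' @param ... passed to [decouple_dist()]
#' @return list with `results` (one `decouple_result` per tree) and
#'   `jointFPdist` (named vector: mean, se)
#' @export
decouple_over_trees <- function(fdist, trees, ...) {
  sp <- rownames(as_matrix(fdist))
  res <- lapply(trees, function(tr) {
    pd <- cophenetic_dist(prune_to_pool(tr, sp))
    pd <- dist_matrix(as_matrix(pd)[sp, sp])
    decouple_dist(fdist, pd, ...)
  })
  j <- vapply(res, function(r) r$jointFPdist, numeric(1))
  list(results = res,
       jointFPdist = c(mean = mean(j), se = sd(j) / sqrt(length(j))))
}
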