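#' Cophenetic distances between tips
#'
#' Pairwise path lengths (sum of branch lengths) between all tips of a rooted
#' tree. For an ultrametric tree the result is an ultrametric distance matrix
#' and is Euclidean-embeddable; it is the phylogenetic distance `Pdist` used
#' by the decoupling and beta-diversity machinery.
#'
#' @param tree a rooted `phylo` with branch lengths
#' @return a [dist_matrix()] over the tip labels
#' @export
cophenetic_dist <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2) stop("tree needs at least 2 tips")
  dist_matrix(stats::cophenetic(tree))
}

#' Prune a tree to a species pool
#'
#' Induced subtree on the pool: path lengths between retained tips are
#' preserved exactly, degree-2 nodes are suppressed with their branch lengths
#' summed.
#'
#' @param tree a `phylo`
#' @param pool character vector of tip labels to keep (at least 2)
#' @return the pruned `phylo`
#' @export
prune_to_pool <- function(tree, pool) {
  stopifnot(inherits(tree, "phylo"))
  miss <- setdiff(pool, tree$tip.label)
  if (length(miss)) stop("pool species absent from tree: ", paste(miss, collapse = ", "))
  if (length(pool) < 2) stop("pool must contain at least 2 species")
  ape::keep.tip(tree, pool)
}

#' Height of each node above the root
#' @noRd
node_depths <- function(tree) ape::node.depth.edgelength(tree)

#' Ultrametricity check with relative tolerance
#'
#' @param tree a `phylo`
#' @param tol relative tolerance on root-to-tip path spread (default 1e-6)
#' @return logical
#' @export
is_ultrametric_tol <- function(tree, tol = 1e-6) {
  d <- node_depths(tree)[seq_along(tree$tip.label)]
  (max(d) - min(d)) <= tol * max(d)
}

#' Randomly insert unplaced species into a tree
#'
#' Species missing from a phylogeny but assignable to a clade on taxonomic
#' grounds are grafted at random: for each species, an attachment branch is
#' drawn uniformly among the branches of its anchor clade (the clade spanned
#' by the anchor tips; when the anchor is a single tip, its terminal branch),
#' the attachment point is drawn uniformly along that branch, and the new
#' pendant branch is given exactly the length that keeps the tree ultrametric.
#'
#' @param tree rooted ultrametric `phylo`
#' @param assignments named list: element names are the species to insert,
#'   values are character vectors of anchor tip labels defining the clade
#' @return the augmented `phylo` (original tips unchanged)
#' @export
insert_missing_taxa <- function(tree, assignments) {
  stopifnot(inherits(tree, "phylo"))
  if (!length(assignments)) return(tree)
  if (is.null(names(assignments)) || any(names(assignments) == ""))
    stop("'assignments' must be a named list (names = species to insert)")
  for (sp in names(assignments)) {
    anchor <- assignments[[sp]]
    miss <- setdiff(anchor, tree$tip.label)
    if (length(miss)) stop("anchor tips absent from tree: ", paste(miss, collapse = ", "))
    depth <- node_depths(tree)
    H <- max(depth[seq_along(tree$tip.label)])
    if (length(anchor) == 1L) {
      child <- match(anchor, tree$tip.label)
      cand <- which(tree$edge[, 2] == child)
    } else {
      mrca <- ape::getMRCA(tree, anchor)
      clade_nodes <- clade_descendants(tree, mrca)
      cand <- which(tree$edge[, 1] %in% c(mrca, clade_nodes))
      if (!length(cand)) stop("anchor clade of '", sp, "' has no attachable branch")
    }
    e <- if (length(cand) == 1L) cand else sample(cand, 1L)
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    len <- tree$edge.length[e]
    # attachment depth uniform along the branch
    at <- depth[par] + runif(1) * len
    pendant <- H - at
    tree <- phytools::bind.tip(tree, sp, edge.length = pendant,
                               where = child, position = depth[child] - at)
  }
  tree
}

# internal nodes strictly inside the clade rooted at 'node' (excludes the node itself)
clade_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, node, type = "all")
  desc[desc > ntip]
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomerative clustering with node heights equal to half
#' the between-cluster average distance at each merge, so the cophenetic
#' distance on the output tree equals the merge-level average distance. When
#' the input is itself ultrametric the input distances are reproduced exactly.
#' Before clustering, labels are put in lexicographic order so that merge
#' ties resolve the same way on every run.
#'
#' @param d a [dist_matrix()] or `dist`
#' @return an ultrametric `phylo`
#' @export
upgma_tree <- function(d) {
  D <- as_matrix(d)
  if (nrow(D) < 2) stop("need at least 2 labels")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8, check.attributes = FALSE)))
    stop("distance matrix must be symmetric")
  o <- order(rownames(D))
  D <- D[o, o]
  if (nrow(D) == 2) {
    txt <- sprintf("(%s:%.10g,%s:%.10g);", rownames(D)[1], D[1, 2] / 2,
                   rownames(D)[2], D[1, 2] / 2)
    return(ape::read.tree(text = txt))
  }
  hc <- hclust(as.dist(D), method = "average")
  ape::as.phylo(hc)
}

#' Read and write Newick tree files
#'
#' Multi-tree files hold one Newick string per line; quoted labels and branch
#' lengths are supported.
#'
#' @param path file path
#' @return `read_trees()`: a list of `phylo` objects
#' @export
read_trees <- function(path) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "phylo")) tr <- list(tr)
  unclass(tr)
}

#' @rdname read_trees
#' @param trees a `phylo` or list of `phylo`
#' @export
write_trees <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  class(trees) <- "multiPhylo"
  ape::write.tree(trees, file = path)
  invisible(unclass(trees))
}
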