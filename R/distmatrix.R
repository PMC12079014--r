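#' Species distance matrices
#'
#' A `dist_matrix` is a labelled symmetric matrix of pairwise species
#' dissimilarities with a zero diagonal, optionally carrying a flag recording
#' whether the configuration is Euclidean-embeddable (all eigenvalues of the
#' double-centred Gower matrix non-negative within tolerance). Both the
#' phylogenetic distance (`Pdist`, cophenetic path lengths) and the decoupled
#' functional distance (`dcFdist`) are stored this way.
#'
#' @param x square numeric matrix or `dist` object with labels
#' @param check if `TRUE` (default), validate symmetry and the zero diagonal
#' @return a `dist_matrix`: a numeric matrix with class attribute and, after
#'   [is_euclidean()] has been called, a logical `euclidean` attribute
#' @examples
#' d <- dist_matrix(as.matrix(dist(matrix(rnorm(12), 4))))
#' is_euclidean(d)
#' @export
dist_matrix <- function(x, check = TRUE) {
  if (inherits(x, "dist")) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) stop("'x' must be a numeric matrix or dist")
  if (is.null(rownames(x))) {
    lab <- paste0("sp", seq_len(nrow(x)))
    dimnames(x) <- list(lab, lab)
  }
  if (is.null(colnames(x))) colnames(x) <- rownames(x)
  if (check) {
    if (nrow(x) != ncol(x)) stop("distance matrix must be square")
    if (!isTRUE(all.equal(x, t(x), tolerance = 1e-8, check.attributes = FALSE)))
      stop("distance matrix must be symmetric")
    if (any(abs(diag(x)) > 1e-10)) stop("distance matrix must have a zero diagonal")
    if (any(x < -1e-10)) stop("distances must be non-negative")
    x <- (x + t(x)) / 2
    diag(x) <- 0
  }
  class(x) <- c("dist_matrix", "matrix", "array")
  x
}

#' @rdname dist_matrix
#' @param d a `dist_matrix` or square symmetric matrix
#' @param tol relative eigenvalue tolerance for Euclidean embeddability
#' @export
is_euclidean <- function(d, tol = 1e-8) {
  D <- unclass(as_matrix(d))
  n <- nrow(D)
  G <- -0.5 * D^2
  G <- sweep(G, 1, rowMeans(G))
  G <- sweep(G, 2, colMeans(G))
  ev <- eigen((G + t(G)) / 2, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), 1e-300)
  min(ev) >= -tol * scale
}

as_matrix <- function(d) {
  if (inherits(d, "dist")) as.matrix(d) else unclass(d)
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("Species distance matrix:", nrow(x), "labels\n")
  cat("  range [", format(min(x[upper.tri(x)])), ",", format(max(x)), "]\n")
  invisible(x)
}

# Gower double-centring and eigen-decomposition shared by pcoa-type code
gower_eigen <- function(D) {
  G <- -0.5 * D^2
  G <- sweep(G, 1, rowMeans(G))
  G <- sweep(G, 2, colMeans(G))
  eigen((G + t(G)) / 2, symmetric = TRUE)
}
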