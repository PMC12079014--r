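#' Euclidean species trait distance for mixed data
#'
#' Builds a species-pairwise functional distance that is Euclidean-embeddable
#' by construction: quantitative traits are standardized to zero mean and unit
#' variance, categorical traits are one-hot encoded with each indicator scaled
#' by `1/sqrt(2)` so that a single-level mismatch contributes exactly 1 to the
#' squared distance, and the pairwise Euclidean distance is taken over the
#' concatenated vector. Sporadic missing values are handled by
#' availability weighting: the squared distance of a pair is rescaled by
#' (number of traits) / (number of traits observed in both species). A
#' square-root Gower alternative is available for comparison.
#'
#' @param traits a [trait_table()]
#' @param method `"mixed"` (default, the construction above) or `"gower"`
#'   (range-scaled Gower dissimilarity followed by a square root)
#' @return a [dist_matrix()]
#' @export
trait_dist <- function(traits, method = c("mixed", "gower")) {
  stopifnot(inherits(traits, "trait_table"))
  method <- match.arg(method)
  sp <- traits$species_ids
  n <- length(sp)
  if (n < 2) stop("need at least 2 species")
  qm <- traits$quantitative
  cm <- traits$categorical
  if (!is.null(qm)) {
    v <- apply(qm, 2, var, na.rm = TRUE)
    if (any(v < 1e-12, na.rm = TRUE)) {
      warning("dropping zero-variance quantitative trait(s): ",
              paste(colnames(qm)[which(v < 1e-12)], collapse = ", "))
      qm <- qm[, which(v >= 1e-12), drop = FALSE]
      if (ncol(qm) == 0) qm <- NULL
    }
  }
  n_q <- if (is.null(qm)) 0 else ncol(qm)
  n_c <- if (is.null(cm)) 0 else ncol(cm)
  if (n_q + n_c == 0) stop("no usable trait left")
  obs <- matrix(TRUE, n, n_q + n_c)
  sq <- array(0, c(n, n, n_q + n_c))   # per-trait squared contribution
  rng <- numeric(n_q + n_c)
  k <- 0
  if (n_q > 0) {
    z <- scale(qm)
    for (j in seq_len(n_q)) {
      k <- k + 1
      obs[, k] <- !is.na(z[, j])
      dj <- outer(z[, j], z[, j], "-")^2
      dj[is.na(dj)] <- 0
      sq[, , k] <- dj
      rj <- diff(range(qm[, j], na.rm = TRUE))
      rng[k] <- if (rj > 0) rj else 1
    }
  }
  if (n_c > 0) {
    for (j in seq_len(n_c)) {
      k <- k + 1
      obs[, k] <- !is.na(cm[, j])
      neq <- outer(cm[, j], cm[, j], "!=") * 1
      neq[is.na(neq)] <- 0
      sq[, , k] <- neq   # mismatch contributes (1/sqrt(2))^2 per indicator x 2 = 1
      rng[k] <- 1
    }
  }
  if (any(rowSums(obs) == 0))
    stop("species with no observed traits: ",
         paste(sp[rowSums(obs) == 0], collapse = ", "))
  shared <- tcrossprod(obs * 1)        # traits observed in both members of a pair
  if (any(shared[upper.tri(shared)] == 0))
    stop("species pair(s) with no shared observed trait")
  Tn <- n_q + n_c
  if (method == "mixed") {
    d2 <- apply(sq, c(1, 2), sum) * Tn / shared
    D <- sqrt(pmax(d2, 0))
  } else {
    # Gower: per-trait dissimilarity in [0,1] (quant: |diff|/range), averaged
    # over shared traits, then sqrt to improve Euclidean embeddability
    g <- matrix(0, n, n)
    for (j in seq_len(Tn)) {
      g <- g + if (j <= n_q) {
        dj <- abs(outer(qm[, j], qm[, j], "-")) / rng[j]
        dj[is.na(dj)] <- 0
        dj
      } else sq[, , j]
    }
    D <- sqrt(g / shared)
  }
  dimnames(D) <- list(sp, sp)
  diag(D) <- 0
  dist_matrix(D)
}

#' Principal coordinates of a species distance matrix
#'
#' Classical scaling of the double-centred distance matrix; the retained
#' eigenvectors serve as orthogonal synthetic traits for hypervolume
#' computation. If any eigenvalue is meaningfully negative the Lingoes
#' correction (additive constant on squared distances) is applied and
#' flagged. Axis signs are fixed by making each axis's largest-magnitude
#' coordinate positive, so results are reproducible across platforms.
#'
#' @param d a [dist_matrix()] or `dist`
#' @param n_axes number of axes to return; `NULL` (default) returns all
#'   positive-eigenvalue axes. If fewer positive axes exist than requested the
#'   result is truncated with a warning.
#' @param tol relative tolerance below which negative eigenvalues are treated
#'   as numerical zero
#' @return a `trait_space`: list with `coordinates` (species x axes),
#'   `eigenvalues`, `proportion_explained`, `correction_applied`
#' @export
trait_pcoa <- function(d, n_axes = NULL, tol = 1e-8) {
  D <- as_matrix(d)
  n <- nrow(D)
  if (n < 2) stop("need at least 2 species")
  eg <- gower_eigen(D)
  ev <- eg$values
  scale_ev <- max(abs(ev))
  correction <- "none"
  if (min(ev) < -tol * scale_ev) {
    # Lingoes: add 2*c1 to all squared distances (off-diagonal), c1 = -min eig
    c1 <- -min(ev)
    D2 <- D^2 + 2 * c1
    diag(D2) <- 0
    eg <- gower_eigen(sqrt(D2))
    ev <- eg$values
    correction <- "lingoes"
  }
  pos <- which(ev > tol * max(abs(ev)))
  if (!length(pos)) stop("no positive eigenvalue: degenerate configuration")
  if (!is.null(n_axes)) {
    if (n_axes < 1) stop("'n_axes' must be >= 1")
    if (n_axes > length(pos)) {
      warning("only ", length(pos), " positive axes available; truncating")
      n_axes <- length(pos)
    }
    pos <- pos[seq_len(n_axes)]
  }
  co <- eg$vectors[, pos, drop = FALSE] %*% diag(sqrt(ev[pos]), length(pos))
  for (j in seq_len(ncol(co))) {
    i <- which.max(abs(co[, j]))
    if (co[i, j] < 0) co[, j] <- -co[, j]
  }
  rownames(co) <- rownames(D)
  colnames(co) <- paste0("Axis", seq_len(ncol(co)))
  out <- list(coordinates = co,
              eigenvalues = ev[pos],
              proportion_explained = ev[pos] / sum(ev[ev > 0]),
              correction_applied = correction)
  class(out) <- "trait_space"
  out
}

#' @export
print.trait_space <- function(x, ...) {
  cat("Trait space:", nrow(x$coordinates), "species,", ncol(x$coordinates),
      "axes (correction:", x$correction_applied, ")\n")
  cat("  explained:", paste(sprintf("%.1f%%", 100 * x$proportion_explained[
    seq_len(min(4, length(x$proportion_explained)))]), collapse = " "), "...\n")
  invisible(x)
}

#' Community weighted means
#'
#' Abundance-weighted mean of each quantitative trait per site, and the
#' abundance-weighted proportion of each level of each categorical trait.
#' For a quantitative trait the weighting is restricted to species with an
#' observed value; categorical level proportions are computed over species
#' with an observed level, so the level columns of one trait sum to 1.
#'
#' @param comm a [community_table()]
#' @param traits a [trait_table()] covering the community's species
#' @return data frame: one row per site with `site`, `season`, `year`,
#'   `aridity`, then one column per quantitative trait and per categorical
#'   trait level (`trait.level`)
#' @export
cwm <- function(comm, traits) {
  stopifnot(inherits(comm, "community_table"), inherits(traits, "trait_table"))
  miss <- setdiff(comm$species_ids, traits$species_ids)
  if (length(miss)) stop("species lacking traits: ", paste(miss, collapse = ", "))
  ab <- comm$abund
  if (any(rowSums(ab) == 0)) stop("site(s) with zero total abundance: ",
                                  paste(comm$site_ids[rowSums(ab) == 0], collapse = ", "))
  out <- data.frame(site = comm$site_ids, season = comm$season,
                    year = comm$year, aridity = comm$aridity,
                    stringsAsFactors = FALSE)
  qm <- traits$quantitative
  if (!is.null(qm)) {
    qm <- qm[comm$species_ids, , drop = FALSE]
    for (j in colnames(qm)) {
      x <- qm[, j]
      ok <- !is.na(x)
      w <- ab[, ok, drop = FALSE]
      out[[j]] <- as.vector(w %*% x[ok]) / rowSums(w)
    }
  }
  cm <- traits$categorical
  if (!is.null(cm)) {
    cm <- cm[comm$species_ids, , drop = FALSE]
    for (j in colnames(cm)) {
      lv <- cm[, j]
      ok <- !is.na(lv)
      tot <- rowSums(ab[, ok, drop = FALSE])
      for (l in sort(unique(lv[ok]))) {
        out[[paste(j, l, sep = ".")]] <-
          rowSums(ab[, ok & lv == l, drop = FALSE]) / tot
      }
    }
  }
  out
}
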