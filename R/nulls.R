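#' Randomization null models for distance-based metrics
#'
#' Both null models keep the community matrix untouched — observed and
#' virtual communities have identical richness and abundance distributions —
#' and randomize only the mapping of species labels onto the distance source.
#'
#' `random_tips_null()` draws one uniformly random relabelling of the tips of
#' the species-pool tree (equivalently, a joint row/column permutation of the
#' pool's phylogenetic distance matrix): it asks what diversity would look
#' like if the species were differently related. `random_traits_null()` does
#' the same on a (decoupled) functional distance matrix: what if species had
#' different trait values.
#'
#' @param d a [dist_matrix()] over at least the pool species
#' @param pool character vector of pool species (length >= 2) among which
#'   labels are permuted
#' @return a `dist_matrix` with permuted labels; the multiset of pairwise
#'   distances is identical to the input's
#' @export
random_tips_null <- function(d, pool = NULL) {
  permute_dist_labels(d, pool)
}

#' @rdname random_tips_null
#' @export
random_traits_null <- function(d, pool = NULL) {
  permute_dist_labels(d, pool)
}

permute_dist_labels <- function(d, pool = NULL) {
  D <- as_matrix(d)
  if (is.null(pool)) pool <- rownames(D)
  if (length(pool) < 2) stop("pool must contain at least 2 species")
  miss <- setdiff(pool, rownames(D))
  if (length(miss)) stop("pool species absent from matrix: ",
                         paste(miss, collapse = ", "))
  i <- match(pool, rownames(D))
  perm <- sample(length(i))
  lab <- rownames(D)
  lab[i] <- pool[perm]
  dimnames(D) <- list(lab, lab)
  o <- match(rownames(as_matrix(d)), lab)
  dist_matrix(D[o, o], check = FALSE)
}

#' Standardized effect size against a null distribution
#'
#' Runs a metric on `n_null` draws from a null source and standardizes the
#' observed value: `ses = (observed - avgExp) / sdExp` with the sample
#' (n-1) standard deviation. The two-sided rank p-value includes the observed
#' value among the ranked set. Null draws on which the metric is undefined
#' (signalled by `NA` or an error) are excluded and counted; more than 10%
#' exclusions abort the computation.
#'
#' @param observed the observed metric value
#' @param metric function of one argument (a null draw) returning a number
#' @param null_source function of no arguments returning one null draw
#' @param n_null number of null draws (default 100)
#' @return a `ses_result`: list with `observed`, `null_values`, `avgExp`,
#'   `sdExp`, `ses`, `p_rank`, `degenerate`, `n_excluded`
#' @examples
#' set.seed(1)
#' r <- ses(5, function(x) mean(x), function() rnorm(10, 3))
#' r$ses
#' @export
ses <- function(observed, metric, null_source, n_null = 100) {
  if (n_null < 2) stop("'n_null' must be >= 2")
  vals <- vapply(seq_len(n_null), function(i) {
    v <- tryCatch(metric(null_source()), error = function(e) NA_real_)
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  excl <- sum(is.na(vals))
  if (excl > 0.1 * n_null)
    stop("metric undefined on ", excl, " of ", n_null, " null draws")
  vals_ok <- vals[!is.na(vals)]
  avg <- mean(vals_ok)
  sdv <- sd(vals_ok)
  degenerate <- !is.finite(sdv) || sdv == 0
  s <- if (degenerate) 0 else (observed - avg) / sdv
  r <- sum(vals_ok <= observed) + 1
  m <- length(vals_ok)
  p <- 2 * min(r, m + 2 - r) / (m + 1)
  p <- min(max(p, 1 / (m + 1)), 1)
  out <- list(observed = observed, null_values = vals, avgExp = avg,
              sdExp = sdv, ses = s, p_rank = p, degenerate = degenerate,
              n_excluded = excl)
  class(out) <- "ses_result"
  out
}

#' @export
print.ses_result <- function(x, ...) {
  cat(sprintf("SES: %.3f (obs %.4g, null %.4g +- %.4g, rank p %.3g%s)\n",
              x$ses, x$observed, x$avgExp, x$sdExp, x$p_rank,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Per-site SES of alpha diversity
#'
#' Convenience wrapper: for every site with richness >= 2, computes the SES
#' of abundance-weighted MPD and MNTD against the label-permutation null over
#' the species pool.
#'
#' @param comm a [community_table()]
#' @param d a [dist_matrix()] (phylogenetic or decoupled functional)
#' @param pool pool species; default all species in `d`
#' @param n_null null draws per site (default 100)
#' @param metrics which metrics to compute
#' @return data frame with one row per site and metric: `site`, `season`,
#'   `year`, `aridity`, `metric`, `observed`, `avgExp`, `sdExp`, `ses`,
#'   `p_rank`
#' @export
ses_alpha <- function(comm, d, pool = NULL, n_null = 100,
                      metrics = c("mpd", "mntd")) {
  stopifnot(inherits(comm, "community_table"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  D <- as_matrix(d)
  if (is.null(pool)) pool <- rownames(D)
  rows <- list()
  for (i in seq_along(comm$site_ids)) {
    a <- setNames(comm$abund[i, ], comm$species_ids)
    a <- a[names(a) %in% rownames(D)]
    if (sum(a > 0) < 2) next
    for (m in metrics) {
      fn <- if (m == "mpd") mpd_aw else mntd_aw
      obs <- fn(a, d)
      r <- ses(obs, function(dd) fn(a, dd),
               function() permute_dist_labels(d, pool), n_null = n_null)
      rows[[length(rows) + 1]] <- data.frame(
        site = comm$site_ids[i], season = comm$season, year = comm$year,
        aridity = comm$aridity[i], metric = m, observed = r$observed,
        avgExp = r$avgExp, sdExp = r$sdExp, ses = r$ses, p_rank = r$p_rank,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Significance summary across a tree set
#'
#' For per-tree SES values of one site/metric, reports the mean, a 95%
#' interval due to phylogenetic uncertainty, and the fraction of trees with
#' `|ses|` above a threshold as well as with rank p below alpha.
#'
#' @param ses_values numeric vector, one SES per tree
#' @param p_values optional numeric vector of rank p-values per tree
#' @param threshold SES magnitude threshold (default 1.96)
#' @param alpha rank-p threshold (default 0.05)
#' @return named numeric vector: `mean`, `lo95`, `hi95`, `frac_ses`,
#'   `frac_p` (the last `NA` when `p_values` is missing)
#' @export
summarize_tree_ses <- function(ses_values, p_values = NULL, threshold = 1.96,
                               alpha = 0.05) {
  q <- quantile(ses_values, c(0.025, 0.975), names = FALSE)
  c(mean = mean(ses_values), lo95 = q[1], hi95 = q[2],
    frac_ses = mean(abs(ses_values) >= threshold),
    frac_p = if (is.null(p_values)) NA_real_ else mean(p_values < alpha))
}
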