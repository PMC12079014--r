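#' Build a community table for one sampling campaign
#'
#' A community table holds the site-by-species abundance matrix of one
#' campaign (one season of one year) together with the site metadata needed
#' downstream: the aridity value of each site and the position of the site
#' along the transect (position 1 = least arid end). Sites are stored in
#' transect order, which is always taken from the explicit `position` column,
#' never inferred from labels.
#'
#' @param abund non-negative integer matrix, sites in rows, species in columns,
#'   with row and column names
#' @param aridity positive numeric vector, one value per site
#' @param season `"wet"` or `"dry"`
#' @param year integer year of the campaign
#' @param position integer transect position of each site
#' @return a `community_table` (list with elements `abund`, `site_ids`,
#'   `species_ids`, `aridity`, `season`, `year`, `position`)
#' @examples
#' m <- matrix(c(1, 2, 0, 0, 1, 3), 2, 3, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("A", "B", "C")))
#' ct <- community_table(m, aridity = c(1, 2), season = "wet", year = 2013,
#'                       position = 1:2)
#' richness(ct)
#' @export
community_table <- function(abund, aridity, season, year, position = seq_len(nrow(abund))) {
  if (!is.matrix(abund) || !is.numeric(abund)) stop("'abund' must be a numeric matrix")
  if (is.null(rownames(abund)) || is.null(colnames(abund)))
    stop("'abund' needs site row names and species column names")
  if (anyDuplicated(rownames(abund))) stop("duplicate site labels")
  if (anyDuplicated(colnames(abund))) stop("duplicate species labels")
  if (any(!is.finite(abund)) || any(abund < 0))
    stop("abundances must be finite and non-negative")
  storage.mode(abund) <- "double"
  season <- match.arg(season, c("wet", "dry"))
  if (length(aridity) != nrow(abund)) stop("one aridity value per site required")
  if (any(aridity <= 0)) stop("aridity must be positive")
  if (length(position) != nrow(abund) || anyDuplicated(position))
    stop("'position' must be a permutation of distinct site ranks")
  o <- order(position)
  x <- list(abund = abund[o, , drop = FALSE],
            site_ids = rownames(abund)[o],
            species_ids = colnames(abund),
            aridity = as.numeric(aridity)[o],
            season = season, year = as.integer(year),
            position = as.integer(position)[o])
  class(x) <- "community_table"
  x
}

#' @rdname community_table
#' @param x a `community_table`
#' @export
richness <- function(x) {
  stopifnot(inherits(x, "community_table"))
  setNames(rowSums(x$abund > 0), x$site_ids)
}

#' @export
print.community_table <- function(x, ...) {
  cat("Community table:", length(x$site_ids), "sites x", length(x$species_ids),
      "species |", x$season, x$year, "\n")
  cat("  richness:", paste(richness(x), collapse = " "), "\n")
  cat("  aridity range: [", format(min(x$aridity)), ",", format(max(x$aridity)), "]\n")
  invisible(x)
}

#' Read a community table from delimited text
#'
#' The abundance file has one header row of species labels and one row per
#' site (first column = site label). The metadata file maps each site to its
#' aridity value, season, year and integer transect position. Files ending in
#' `.tsv` are read as tab-separated, anything else as comma-separated.
#' Missing values may be written as empty fields or `"NA"`.
#'
#' @param path abundance matrix file
#' @param metadata_path site metadata file with columns
#'   `site`, `aridity`, `season`, `year`, `position`
#' @return a [community_table()]
#' @export
read_community <- function(path, metadata_path) {
  ab <- read_delim_auto(path)
  if (anyDuplicated(colnames(ab)[-1])) stop("duplicate species labels in ", path)
  if (anyDuplicated(ab[[1]])) stop("duplicate site labels in ", path)
  m <- as.matrix(ab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric abundance values in ", path)
  rownames(m) <- as.character(ab[[1]])
  md <- read_delim_auto(metadata_path)
  need <- c("site", "aridity", "season", "year", "position")
  if (!all(need %in% names(md))) stop("metadata must have columns: ", paste(need, collapse = ", "))
  miss <- setdiff(rownames(m), as.character(md$site))
  if (length(miss)) stop("sites missing from metadata: ", paste(miss, collapse = ", "))
  md <- md[match(rownames(m), as.character(md$site)), ]
  season <- unique(md$season); year <- unique(md$year)
  if (length(season) != 1L || length(year) != 1L)
    stop("a community file holds one campaign: season and year must be constant")
  community_table(m, aridity = md$aridity, season = season, year = year,
                  position = md$position)
}

#' @rdname read_community
#' @param comm a `community_table`
#' @param metadata_path path for the site metadata written alongside
#' @export
write_community <- function(comm, path, metadata_path) {
  df <- data.frame(site = comm$site_ids, comm$abund, check.names = FALSE)
  write_delim_auto(df, path)
  md <- data.frame(site = comm$site_ids, aridity = comm$aridity,
                   season = comm$season, year = comm$year,
                   position = comm$position)
  write_delim_auto(md, metadata_path)
  invisible(comm)
}

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  read.csv(path, sep = sep, check.names = FALSE, na.strings = c("", "NA"),
           stringsAsFactors = FALSE)
}

write_delim_auto <- function(df, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE, na = "NA")
}

#' Build a species trait table
#'
#' Holds quantitative traits (numeric, possibly with missing values) and
#' categorical traits (character levels) per species, plus per-trait coverage:
#' the fraction of species with a non-missing value. Individual-level tables
#' (several measured specimens per species) are collapsed to species means for
#' quantitative traits and to the modal level for categorical traits before
#' analysis.
#'
#' @param quantitative numeric matrix or data frame, species x traits
#'   (may be `NULL`)
#' @param categorical character matrix or data frame, species x traits
#'   (may be `NULL`)
#' @param species_ids species labels; defaults to the row names
#' @return a `trait_table` (list with `species_ids`, `quantitative`,
#'   `categorical`, `coverage`)
#' @export
trait_table <- function(quantitative = NULL, categorical = NULL, species_ids = NULL) {
  qm <- if (!is.null(quantitative)) as.matrix(quantitative) else NULL
  cm <- if (!is.null(categorical)) as.matrix(categorical) else NULL
  if (is.null(qm) && is.null(cm)) stop("at least one trait block required")
  if (is.null(species_ids))
    species_ids <- rownames(if (!is.null(qm)) qm else cm)
  if (is.null(species_ids)) stop("species labels required")
  if (anyDuplicated(species_ids)) stop("duplicate species labels")
  n <- length(species_ids)
  if (!is.null(qm)) {
    storage.mode(qm) <- "double"
    if (nrow(qm) != n) stop("quantitative block does not match species_ids")
    if (any(is.infinite(qm))) stop("quantitative traits must be finite or missing")
    rownames(qm) <- species_ids
    if (is.null(colnames(qm))) colnames(qm) <- paste0("q", seq_len(ncol(qm)))
  }
  if (!is.null(cm)) {
    if (nrow(cm) != n) stop("categorical block does not match species_ids")
    rownames(cm) <- species_ids
    if (is.null(colnames(cm))) colnames(cm) <- paste0("c", seq_len(ncol(cm)))
  }
  cov <- c(if (!is.null(qm)) colMeans(!is.na(qm)),
           if (!is.null(cm)) colMeans(!is.na(cm)))
  x <- list(species_ids = species_ids, quantitative = qm, categorical = cm,
            coverage = cov)
  class(x) <- "trait_table"
  x
}

#' @export
print.trait_table <- function(x, ...) {
  cat("Trait table:", length(x$species_ids), "species |",
      if (is.null(x$quantitative)) 0 else ncol(x$quantitative), "quantitative,",
      if (is.null(x$categorical)) 0 else ncol(x$categorical), "categorical traits\n")
  cat("  coverage range: [", format(min(x$coverage)), ",", format(max(x$coverage)), "]\n")
  invisible(x)
}

#' Read a trait table from delimited text
#'
#' First column = species label; remaining numeric columns become quantitative
#' traits and character columns categorical traits. If a species appears on
#' several rows the table is treated as individual-level and collapsed:
#' quantitative traits to the species mean over measured individuals,
#' categorical traits to the modal (most frequent) level.
#'
#' @param path trait file (`.csv` or `.tsv`)
#' @return a [trait_table()]
#' @export
read_traits <- function(path) {
  df <- read_delim_auto(path)
  sp <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  is_q <- vapply(df, is.numeric, logical(1))
  if (anyDuplicated(sp)) {
    usp <- unique(sp)
    qm <- if (any(is_q)) {
      do.call(rbind, lapply(usp, function(s) {
        colMeans(df[sp == s, is_q, drop = FALSE], na.rm = TRUE)
      }))
    } else NULL
    if (!is.null(qm)) qm[is.nan(qm)] <- NA_real_
    cm <- if (any(!is_q)) {
      do.call(rbind, lapply(usp, function(s) {
        vapply(df[sp == s, !is_q, drop = FALSE], modal_level, character(1))
      }))
    } else NULL
    if (!is.null(qm)) rownames(qm) <- usp
    if (!is.null(cm)) rownames(cm) <- usp
    trait_table(qm, cm, species_ids = usp)
  } else {
    qm <- if (any(is_q)) as.matrix(df[, is_q, drop = FALSE]) else NULL
    cm <- if (any(!is_q)) as.matrix(df[, !is_q, drop = FALSE]) else NULL
    if (!is.null(qm)) rownames(qm) <- sp
    if (!is.null(cm)) rownames(cm) <- sp
    trait_table(qm, cm, species_ids = sp)
  }
}

modal_level <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_character_)
  tab <- sort(table(x), decreasing = TRUE)
  names(tab)[1]
}

#' @rdname read_traits
#' @param traits a `trait_table`
#' @export
write_traits <- function(traits, path) {
  df <- data.frame(species = traits$species_ids, check.names = FALSE)
  if (!is.null(traits$quantitative)) df <- cbind(df, traits$quantitative)
  if (!is.null(traits$categorical)) df <- cbind(df, traits$categorical)
  write_delim_auto(df, path)
  invisible(traits)
}

#' Discard traits measured for too few species
#'
#' Traits whose coverage (fraction of species with a non-missing value) falls
#' below the threshold are dropped; the names of dropped traits are reported
#' as a message. The operation is idempotent.
#'
#' @param traits a [trait_table()]
#' @param threshold minimum coverage in `(0, 1]`; default `0.8`
#' @return the filtered `trait_table`
#' @export
filter_traits_by_coverage <- function(traits, threshold = 0.8) {
  stopifnot(inherits(traits, "trait_table"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("'threshold' must lie in (0, 1]")
  keep <- names(traits$coverage)[traits$coverage >= threshold]
  dropped <- setdiff(names(traits$coverage), keep)
  if (length(dropped))
    message("dropping ", length(dropped), " low-coverage trait(s): ",
            paste(dropped, collapse = ", "))
  qm <- traits$quantitative
  cm <- traits$categorical
  if (!is.null(qm)) qm <- qm[, intersect(colnames(qm), keep), drop = FALSE]
  if (!is.null(cm)) cm <- cm[, intersect(colnames(cm), keep), drop = FALSE]
  if ((is.null(qm) || ncol(qm) == 0) && (is.null(cm) || ncol(cm) == 0))
    stop("all traits dropped at coverage threshold ", threshold)
  trait_table(if (!is.null(qm) && ncol(qm)) qm else NULL,
              if (!is.null(cm) && ncol(cm)) cm else NULL,
              species_ids = traits$species_ids)
}

#' Remove species whose quantitative traits could not be measured
#'
#' Species with no observed quantitative trait at all (typically species known
#' from one or two specimens) are removed from both the community and the
#' trait table. Abundances of removed species are dropped, not redistributed.
#' A site emptied by the removal is kept with richness 0 and a warning; such
#' sites are excluded from diversity metrics downstream.
#'
#' @param comm a [community_table()]
#' @param traits a [trait_table()] covering the community's species
#' @param min_measured minimum number of observed quantitative traits for a
#'   species to be retained (default 1)
#' @return list with elements `comm` and `traits`
#' @export
filter_rare_species <- function(comm, traits, min_measured = 1) {
  stopifnot(inherits(comm, "community_table"), inherits(traits, "trait_table"))
  if (min_measured < 0) stop("'min_measured' must be >= 0")
  if (is.null(traits$quantitative)) return(list(comm = comm, traits = traits))
  n_obs <- rowSums(!is.na(traits$quantitative))
  keep_sp <- traits$species_ids[n_obs >= min_measured]
  drop_sp <- setdiff(traits$species_ids, keep_sp)
  if (length(drop_sp))
    message("removing ", length(drop_sp), " species with unmeasured traits: ",
            paste(drop_sp, collapse = ", "))
  keep_comm <- intersect(comm$species_ids, keep_sp)
  ab <- comm$abund[, keep_comm, drop = FALSE]
  if (any(rowSums(ab > 0) == 0 & richness(comm) > 0))
    warning("species removal emptied site(s): ",
            paste(comm$site_ids[rowSums(ab > 0) == 0], collapse = ", "))
  comm2 <- community_table(ab, aridity = comm$aridity, season = comm$season,
                           year = comm$year, position = comm$position)
  qm <- traits$quantitative[keep_sp, , drop = FALSE]
  cm <- if (!is.null(traits$categorical)) traits$categorical[keep_sp, , drop = FALSE]
  list(comm = comm2, traits = trait_table(qm, cm, species_ids = keep_sp))
}

#' Seasonal species pool
#'
#' The species pool is the set of species recorded (abundance > 0) at any site
#' of any campaign of the requested season; null models and SES are computed
#' against this pool.
#'
#' @param campaigns list of [community_table()] objects
#' @param season `"wet"` or `"dry"`
#' @return character vector of species labels
#' @export
species_pool <- function(campaigns, season) {
  season <- match.arg(season, c("wet", "dry"))
  if (inherits(campaigns, "community_table")) campaigns <- list(campaigns)
  sel <- Filter(function(x) x$season == season, campaigns)
  if (!length(sel)) stop("no campaign of season '", season, "' supplied")
  sort(unique(unlist(lapply(sel, function(x)
    x$species_ids[colSums(x$abund) > 0]))))
}

#' Analysis configuration
#'
#' Bundles the run parameters shared across the pipeline: number of null-model
#' randomizations, number of phylogenetic trees, Mantel permutations, the
#' trait-coverage threshold, the sparsity level of the sparse independent
#' component analysis, and the familywise alpha with the size of the test
#' family used for Bonferroni correction.
#'
#' @param n_null null-model randomizations (default 100)
#' @param n_trees trees drawn to propagate phylogenetic uncertainty
#' @param n_perm_mantel Mantel permutations (default 999)
#' @param trait_coverage_threshold coverage cut-off in `(0, 1]`
#' @param keepX variables retained per sparse component (default 5)
#' @param alpha_family familywise significance level
#' @param n_tests_family number of tests in the Bonferroni family
#' @param rng_seed integer seed recorded in the run manifest
#' @return a named list of class `analysis_config`
#' @export
analysis_config <- function(n_null = 100, n_trees = 1000, n_perm_mantel = 999,
                            trait_coverage_threshold = 0.8, keepX = 5,
                            alpha_family = 0.05, n_tests_family = 4,
                            rng_seed = 1L) {
  cfg <- list(n_null = n_null, n_trees = n_trees, n_perm_mantel = n_perm_mantel,
              trait_coverage_threshold = trait_coverage_threshold,
              keepX = keepX, alpha_family = alpha_family,
              n_tests_family = n_tests_family, rng_seed = as.integer(rng_seed))
  counts <- c("n_null", "n_trees", "n_perm_mantel", "keepX", "n_tests_family")
  if (any(unlist(cfg[counts]) < 1)) stop("all counts must be >= 1")
  if (cfg$trait_coverage_threshold <= 0 || cfg$trait_coverage_threshold > 1)
    stop("'trait_coverage_threshold' must lie in (0, 1]")
  if (cfg$alpha_family <= 0 || cfg$alpha_family > 1)
    stop("'alpha_family' must lie in (0, 1]")
  class(cfg) <- "analysis_config"
  cfg
}
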