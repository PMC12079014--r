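#' Mantel test with Spearman rank correlation
#'
#' Correlation between the off-diagonal elements of two distance matrices,
#' assessed by jointly permuting the row/column order of the second matrix.
#' The permutation p-value is one-sided (upper) by default, matching the
#' usual question "are the matrices positively associated"; a two-sided
#' p-value is available.
#'
#' @param d1,d2 distance matrices with identical labels
#' @param n_perm number of permutations (>= 99, default 999)
#' @param alternative `"greater"` (default) or `"two.sided"`
#' @return a `mantel_result`: list with `rho`, `p_perm`, `n_perm`,
#'   `alternative`
#' @export
mantel_spearman <- function(d1, d2, n_perm = 999,
                            alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n_perm < 99) stop("'n_perm' must be >= 99")
  M1 <- as_matrix(d1); M2 <- as_matrix(d2)
  if (!identical(rownames(M1), rownames(M2)))
    stop("matrices must share labels in the same order")
  v1 <- M1[lower.tri(M1)]; v2 <- M2[lower.tri(M2)]
  if (var(v1) == 0 || var(v2) == 0) stop("zero variance in a distance triangle")
  res <- vegan::mantel(as.dist(M1), as.dist(M2), method = "spearman",
                       permutations = n_perm)
  p <- res$signif
  if (alternative == "two.sided") {
    perm <- res$perm
    p <- min(1, (sum(abs(perm) >= abs(res$statistic)) + 1) / (length(perm) + 1))
  }
  out <- list(rho = unname(res$statistic), p_perm = p, n_perm = n_perm,
              alternative = alternative)
  class(out) <- "mantel_result"
  out
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel (Spearman): rho = %.4f, p = %.4g (%s, %d permutations)\n",
              x$rho, x$p_perm, x$alternative, x$n_perm))
  invisible(x)
}

#' Paired t test
#'
#' Two-sided paired t test on site- or pair-matched measurements, e.g. the
#' 45 pairwise beta diversities of a 10-site gradient compared between the
#' wet and the dry season (df = 44).
#'
#' @param x,y paired numeric vectors of equal length
#' @return list with `t`, `df`, `p`, `mean_diff`
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must be paired (equal length)")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  if (sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, df = length(x) - 1L, p = 1, mean_diff = 0))
    stop("zero-variance non-zero differences")
  }
  tt <- t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate))
}

#' Bonferroni-corrected per-test threshold
#'
#' @param alpha familywise significance level
#' @param n_tests number of tests in the family
#' @return `alpha / n_tests`
#' @examples
#' bonferroni_threshold(0.05, 4)  # 0.0125
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha <= 1, n_tests >= 1)
  alpha / n_tests
}

#' Quadratic aridity-by-season linear model
#'
#' Ordinary least squares of a diversity response (typically a mean SES) on
#' log10-transformed aridity, its square, season, and their interactions:
#' `y ~ la * season + la2 * season` with `la` centred after the log
#' transform to tame the collinearity of the linear and quadratic terms.
#' Residual normality (Shapiro-Wilk) and homoscedasticity (Breusch-Pagan)
#' are checked; if the Breusch-Pagan test rejects at 0.05, HC3 sandwich
#' standard errors replace the OLS ones and the result is flagged.
#'
#' @param response numeric response per observation
#' @param aridity positive aridity values (log10 applied internally)
#' @param season factor or character with two levels, wet as reference
#' @param center centre log-aridity before squaring (default `TRUE`)
#' @return a `gradient_lm`: list with `coefficients` (term, estimate, se, t,
#'   p), `robust_se_used`, `shapiro_p`, `bp_p`, `r_squared`, `model` (the
#'   underlying `lm`)
#' @export
fit_gradient_lm <- function(response, aridity, season, center = TRUE) {
  if (any(aridity <= 0)) stop("aridity must be positive for the log transform")
  season <- factor(season)
  if (nlevels(season) != 2) stop("both seasons must be present")
  if ("wet" %in% levels(season)) season <- stats::relevel(season, "wet")
  la <- log10(aridity)
  if (center) la <- la - mean(la)
  la2 <- la^2
  dat <- data.frame(y = response, la = la, la2 = la2, season = season)
  fit <- lm(y ~ la * season + la2 * season, data = dat)
  if (qr(fit)$rank < length(coef(fit))) stop("rank-deficient design")
  sh <- tryCatch(shapiro.test(resid(fit))$p.value, error = function(e) NA_real_)
  bp <- lmtest::bptest(fit)$p.value
  robust <- is.finite(bp) && bp < 0.05
  ct <- if (robust) {
    lmtest::coeftest(fit, vcov = sandwich::vcovHC(fit, type = "HC3"))
  } else {
    summary(fit)$coefficients
  }
  co <- data.frame(term = rownames(ct), estimate = ct[, 1], se = ct[, 2],
                   t = ct[, 3], p = ct[, 4], row.names = NULL,
                   stringsAsFactors = FALSE)
  out <- list(coefficients = co, robust_se_used = robust, shapiro_p = sh,
              bp_p = unname(bp), r_squared = summary(fit)$r.squared,
              model = fit)
  class(out) <- "gradient_lm"
  out
}

#' @export
print.gradient_lm <- function(x, digits = 4, ...) {
  cat("Quadratic aridity x season model",
      if (x$robust_se_used) "(HC3 robust SEs)" else "", "\n")
  co <- x$coefficients
  co[, -1] <- signif(co[, -1], digits)
  print(co, row.names = FALSE)
  cat(sprintf("R^2 = %.3f | Shapiro p = %.3g | Breusch-Pagan p = %.3g\n",
              x$r_squared, x$shapiro_p, x$bp_p))
  invisible(x)
}

# excess kurtosis
excess_kurtosis <- function(x) {
  x <- x - mean(x)
  mean(x^4) / mean(x^2)^2 - 3
}

#' Independent principal component analysis of community weighted means
#'
#' Principal components are extracted by singular value decomposition of the
#' scaled data, then rotated by a deflationary fixed-point independent
#' component algorithm with the cube (kurtosis-seeking) nonlinearity so that
#' the component scores are as statistically independent as possible.
#' Components are ordered by decreasing magnitude of the excess kurtosis of
#' their scores, and signs are fixed by making each component's
#' largest-magnitude loading positive.
#'
#' @param X numeric site-by-trait matrix (e.g. CWM values); scaled internally
#' @param m number of components (<= min(dim))
#' @param max_iter maximum fixed-point iterations per component
#' @param tol convergence tolerance on the unmixing vector
#' @return an `ipca_result`: list with `scores` (site x m), `loadings`
#'   (trait x m, unit columns), `kurtosis` (excess, per component),
#'   `explained_variance`, `converged`, `keepX` (`NA` for the dense variant)
#' @export
ipca <- function(X, m = 2, max_iter = 1000, tol = 1e-6) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("missing values in 'X'")
  if (m < 1 || m > min(dim(X))) stop("'m' must lie in [1, min(dim(X))]")
  Xs <- scale(X)
  if (any(!is.finite(Xs))) stop("constant column cannot be scaled")
  n <- nrow(Xs)
  sv <- svd(Xs, nu = m, nv = m)
  if (sum(sv$d > 1e-10 * sv$d[1]) < m) stop("'m' exceeds the rank of 'X'")
  Z <- sv$u * sqrt(n - 1)              # whitened scores, unit variance
  converged <- TRUE
  if (m == 1) {
    W <- matrix(1, 1, 1)
  } else {
    W <- matrix(0, m, m)
    for (j in seq_len(m)) {
      w <- rnorm(m); w <- w / sqrt(sum(w^2))
      for (it in seq_len(max_iter)) {
        wx <- Z %*% w
        w_new <- colMeans(Z * as.vector(wx)^3) - 3 * w
        if (j > 1) {
          prev <- W[seq_len(j - 1), , drop = FALSE]
          w_new <- w_new - as.vector(t(prev) %*% (prev %*% w_new))
        }
        w_new <- w_new / sqrt(sum(w_new^2))
        if (abs(abs(sum(w_new * w)) - 1) < tol) { w <- w_new; break }
        w <- w_new
        if (it == max_iter) converged <- FALSE
      }
      W[j, ] <- w
    }
  }
  # back to trait space: scores = Xs %*% loadings exactly
  C <- sv$v %*% diag(1 / sv$d[seq_len(m)], m) %*% t(W) * sqrt(n - 1)
  L <- sweep(C, 2, sqrt(colSums(C^2)), "/")
  S <- Xs %*% L
  kurt <- apply(S, 2, excess_kurtosis)
  o <- order(abs(kurt), decreasing = TRUE)
  L <- L[, o, drop = FALSE]; S <- S[, o, drop = FALSE]; kurt <- kurt[o]
  for (j in seq_len(m)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) { L[, j] <- -L[, j]; S[, j] <- -S[, j] }
  }
  evar <- vapply(seq_len(m), function(j) {
    s <- S[, j]
    a <- crossprod(Xs, s) / sum(s^2)
    sum((s %*% t(a))^2) / sum(Xs^2)
  }, numeric(1))
  rownames(L) <- colnames(X)
  colnames(L) <- colnames(S) <- paste0("IPC", seq_len(m))
  rownames(S) <- rownames(X)
  out <- list(scores = S, loadings = L, kurtosis = kurt,
              explained_variance = evar, converged = converged,
              keepX = NA_integer_)
  class(out) <- "ipca_result"
  out
}

#' Sparse independent principal component analysis
#'
#' As [ipca()], then each loading vector is sparsified: only the `keepX`
#' largest-magnitude traits are retained, soft-thresholded by the magnitude
#' of the first excluded trait, and the rest set exactly to zero. Scores are
#' re-projected on the sparse loadings and components re-ordered by the
#' kurtosis of the new scores.
#'
#' @inheritParams ipca
#' @param keepX number of traits retained per component (default 5)
#' @return an `ipca_result` with at most `keepX` nonzero loadings per
#'   component
#' @export
sipca <- function(X, m = 2, keepX = 5, max_iter = 1000, tol = 1e-6) {
  X <- as.matrix(X)
  if (keepX < 1) stop("'keepX' must be >= 1")
  if (keepX > ncol(X)) stop("'keepX' exceeds the number of traits")
  res <- ipca(X, m = m, max_iter = max_iter, tol = tol)
  L <- res$loadings
  p <- nrow(L)
  if (keepX < p) {
    for (j in seq_len(ncol(L))) {
      l <- L[, j]
      lambda <- sort(abs(l), decreasing = TRUE)[keepX + 1]
      l <- sign(l) * pmax(abs(l) - lambda, 0)
      nrm <- sqrt(sum(l^2))
      L[, j] <- if (nrm > 0) l / nrm else l
    }
  }
  Xs <- scale(X)
  S <- Xs %*% L
  kurt <- apply(S, 2, excess_kurtosis)
  o <- order(abs(kurt), decreasing = TRUE)
  L <- L[, o, drop = FALSE]; S <- S[, o, drop = FALSE]; kurt <- kurt[o]
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) { L[, j] <- -L[, j]; S[, j] <- -S[, j] }
  }
  evar <- vapply(seq_len(ncol(S)), function(j) {
    s <- S[, j]
    a <- crossprod(Xs, s) / sum(s^2)
    sum((s %*% t(a))^2) / sum(Xs^2)
  }, numeric(1))
  colnames(L) <- colnames(S) <- paste0("sIPC", seq_len(ncol(L)))
  res$loadings <- L; res$scores <- S; res$kurtosis <- kurt
  res$explained_variance <- evar; res$keepX <- as.integer(keepX)
  res
}

#' @export
print.ipca_result <- function(x, ...) {
  sparse <- !is.na(x$keepX)
  cat(if (sparse) "Sparse independent" else "Independent",
      "principal components:", ncol(x$scores), "component(s)\n")
  cat("  |excess kurtosis|:", paste(sprintf("%.2f", abs(x$kurtosis)), collapse = " "), "\n")
  cat("  explained variance:", paste(sprintf("%.1f%%", 100 * x$explained_variance),
                                     collapse = " "), "\n")
  if (sparse) cat("  keepX:", x$keepX, "traits per component\n")
  if (!x$converged) cat("  note: fixed-point iteration did not fully converge\n")
  invisible(x)
}

#' Choose the number of components from a kurtosis profile
#'
#' Sorts the component kurtosis magnitudes in decreasing order and returns
#' the count just before the largest relative drop; ties resolve toward fewer
#' components. A flat profile returns 1 with a warning.
#'
#' @param kurtosis numeric vector of component (excess) kurtosis values
#' @return integer number of components to retain
#' @examples
#' select_components_by_kurtosis(c(8, 6.5, 0.4, 0.3))  # 2
#' @export
select_components_by_kurtosis <- function(kurtosis) {
  if (length(kurtosis) < 2) stop("need at least 2 components")
  k <- sort(abs(kurtosis), decreasing = TRUE)
  ratio <- vapply(seq_len(length(k) - 1), function(i) {
    if (k[i + 1] <= .Machine$double.eps) {
      if (k[i] <= .Machine$double.eps) 1 else Inf
    } else k[i] / k[i + 1]
  }, numeric(1))
  if (all(ratio <= 1 + 1e-12)) {
    warning("flat kurtosis profile; retaining 1 component")
    return(1L)
  }
  as.integer(which.max(ratio))
}

#' MANOVA of component scores against aridity
#'
#' Multivariate regression of the (S)IPCA site scores on the aridity value,
#' summarized by Wilks' lambda with Rao's F approximation (Pillai's trace
#' available as an option). With one component this reduces to the univariate
#' regression F test.
#'
#' @param scores site-by-m component score matrix
#' @param aridity numeric aridity per site
#' @param test `"Wilks"` (default) or `"Pillai"`
#' @return list with `statistic`, `approx_F`, `df` (num, den), `p`, `test`
#' @export
manova_components <- function(scores, aridity, test = c("Wilks", "Pillai")) {
  test <- match.arg(test)
  scores <- as.matrix(scores)
  m <- ncol(scores); n <- nrow(scores)
  if (length(aridity) != n) stop("one aridity value per site required")
  if (n <= m + 1) stop("need more sites than components + 1")
  if (m == 1) {
    fit <- lm(scores[, 1] ~ aridity)
    fs <- summary(fit)$fstatistic
    return(list(statistic = unname(fs[1]), approx_F = unname(fs[1]),
                df = unname(fs[2:3]), p = unname(pf(fs[1], fs[2], fs[3],
                                                    lower.tail = FALSE)),
                test = "F"))
  }
  fit <- lm(scores ~ aridity)
  an <- anova(fit, test = test)
  row <- an["aridity", ]
  list(statistic = row[[test]], approx_F = row[["approx F"]],
       df = c(row[["num Df"]], row[["den Df"]]), p = row[["Pr(>F)"]],
       test = test)
}
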