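---
title: "Decoupled phylogenetic and functional community assembly: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoupled phylogenetic and functional community assembly: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecodecouple)
```

This vignette documents the statistical machinery in `ecodecouple`, the
assumptions behind each stage, the choices that were genuinely open and how
they were settled, and what the synthetic-data validation does and does not
demonstrate.

## The decoupling model

Trait variation and phylogenetic relatedness are correlated whenever traits
evolve with phylogenetic signal, so community metrics computed on a trait
distance and on a cophenetic distance are partially redundant. The
decoupling procedure separates them with an explicit priority for
phylogeny:

1. Project the phylogenetic distance matrix (cophenetic path lengths on an
   ultrametric tree, in time units) to principal coordinates.
2. Project the functional distance matrix to principal coordinates.
3. Regress the functional coordinates on the retained phylogenetic axes by
   multivariate least squares.
4. `dcFdist` is the Euclidean distance among the residual coordinates — the
   trait structure that phylogeny cannot predict — and is
   Euclidean-embeddable by construction (residuals are an explicit point
   configuration).
5. `jointFPdist` is the fraction of total functional variance explained by
   the regression, in `[0, 1]`.

The asymmetry is deliberate: only trait variation independent of
relatedness survives, so the phylogenetic side can stand in for unmeasured
conserved traits. No reciprocal "decoupled phylogenetic" matrix is
produced.

### How many phylogenetic predictor axes?

This was the central open design question. A cophenetic matrix of `n`
species has up to `n - 1` positive principal-coordinate axes; regressing
`n` points on `n - 2` predictors explains essentially everything
(`E[R^2] ~ (n - 2)/(n - 1)`) no matter what the traits are, which would
drive `jointFPdist` to 1 even for traits simulated with zero phylogenetic
signal. The package therefore retains the axes selected by the
**broken-stick rule** on the positive eigenvalues (capped at `n - 2`): the
axes that carry more variance than expected from a random partition, which
for realistic trees is a handful of axes describing the deep clade
structure. Under this rule, simulated tree-independent traits give
`jointFPdist` around 0.03–0.16 with `Mantel(dcFdist, Fdist) > 0.9`, and the
shared fraction rises monotonically as the simulated Brownian signal goes
from 0 to 1. The saturating variant remains available as
`decouple_dist(..., axis_rule = "all_positive")` for comparison.

The residual-to-total variance ratio is reported as a stability
diagnostic: when almost all functional variance is absorbed by the
phylogenetic axes, downstream analyses of `dcFdist` rest on a sliver of
variance and should be interpreted cautiously (decoupled functional *beta*
diversity is particularly affected; the package surfaces hull-degeneracy
counts rather than attempting any stabilization).

## Trait space

Mixed trait data become a Euclidean distance by construction: quantitative
traits are standardized (z-scores, so all traits are in sd units),
categorical traits are one-hot encoded with indicators scaled by
`1/sqrt(2)` so one level mismatch adds exactly 1 to the squared distance.
The encoding of categorical traits into a Euclidean frame was an open
choice; this construction was preferred over Gower because it is Euclidean
by design (no correction needed when data are complete), with a
`method = "gower"` switch for comparison. Sporadic missing values are
handled by availability weighting (squared distance rescaled by the number
of traits over the number shared), never by imputation; traits measured for
less than 80% of species are expected to be dropped beforehand
(`filter_traits_by_coverage`, threshold 0.8 by default).

Principal coordinates use classical scaling with the Lingoes correction
(additive on squared distances) applied only when a meaningful negative
eigenvalue appears; Lingoes was preferred over Cailliez as the standard,
deterministic choice that preserves the ordination structure. Axis signs
are fixed by making each axis's largest-magnitude coordinate positive, so
runs are reproducible across platforms.

## Alpha diversity and null models

MPD and MNTD are abundance-weighted; richness-1 sites are reported as
missing, not zero, because a zero would mimic perfect clustering. Both
nulls permute labels only — tip names on the pool tree, or species names on
the (decoupled) functional matrix — so observed and virtual communities
share identical richness and abundance distributions by construction. SES
uses the sample (n−1) standard deviation and 100 randomizations by
default; the two-sided rank p-value includes the observed value
(`p = 2 min(r, n+1-r)/(n+1)`). Per-tree SES values across a tree set are
summarized by the mean, a 95% interval attributable to phylogenetic
uncertainty, and two significance fractions (`|SES| >= 1.96` and rank
`p < 0.05`), since a single per-tree significance rule is not canonical.

## Beta diversity

All partitions are Sorensen-family: `beta_sor = (b+c)/(2a+b+c)`,
`beta_sim = min(b,c)/(a+min(b,c))`, `beta_sne = beta_sor - beta_sim`, with
`(a, b, c)` counted as species, branch length, or hypervolume.

* **Phylogenetic.** Shared and unique branch lengths are counted on the
  subtree induced by the union of the two sites, rooted at the union's most
  recent common ancestor — lineages absent from both sites never inflate
  the shared fraction. The workflow applies this to the UPGMA
  back-transformation of `Pdist` (ties broken deterministically by
  lexicographic label order; the original tree can be supplied instead).
* **Functional.** Incidence-only convex hulls on the first
  `k = min(4, min richness - 1)` synthetic-trait axes. Intersection volumes
  are exact: both hulls are converted to half-space form by facet
  enumeration and the intersection polytope's vertices are enumerated from
  d-subsets of the pooled hyperplanes. When the pooled combinatorics exceed
  a budget (2e6 combinations), a seeded Monte-Carlo rejection sampler in
  the intersection of the bounding boxes takes over and reports its
  standard error. Flat (zero-volume) hulls are flagged missing rather than
  forced; sites with fewer than `k + 1` species are dropped with a logged
  count.

Numerical tolerances: facet classification at `1e-9` relative to the
coordinate scale; partition additivity holds to `1e-12` by construction
and is asserted over thousands of random pairs in the tests.

## Gradient statistics

Quadratic aridity models use `log10` aridity centred before squaring (an
open choice, made to tame the collinearity of the linear and quadratic
terms; a raw option exists). Residual normality (Shapiro–Wilk) and
homoscedasticity (Breusch–Pagan) are checked; a Breusch–Pagan rejection at
0.05 switches the reported standard errors to HC3 sandwich estimates with a
flag. Mantel tests use Spearman rank correlation with joint row/column
permutations; familywise error is controlled by Bonferroni
(`alpha / n_tests`, e.g. 0.0125 for a four-model family at 0.05).

Independent principal components: the scaled data are whitened by SVD and
rotated by a deflationary fixed-point ICA with the cube (kurtosis-seeking)
nonlinearity, tolerance `1e-6`, at most 1000 iterations, seeded by the
caller. ICA is applied in the whitened **score** space so that the
component scores — the quantities later regressed on aridity — are the
maximally independent ones; kurtosis is accordingly measured on scores,
components are ordered by decreasing `|excess kurtosis|`, and the number
retained follows the largest relative drop in that profile. The sparse
variant keeps the `keepX` (default 5) largest-magnitude traits per loading,
soft-thresholded by the first excluded magnitude, and re-projects the
scores. One caveat documented by the tests: with Gaussian data the cube
nonlinearity chases sampling kurtosis, so single components can show
`|excess|` up to ~1 at 500 observations even though the mean over
replicates stays below 0.6 and shrinks with sample size — kurtosis
magnitudes should be read comparatively, not as absolute evidence of
non-Gaussian structure.

## The synthetic-data generator

`assembly_scenario()` fixes the study conditions: 10 sites with aridity
spaced uniformly on a log scale over one decade (so the `log10` transform
used by the gradient models is natural), two seasons in each of two years,
and a pool of 60 species in two major clades joined at half the tree
height — mirroring a fauna dominated by two subfamilies. Traits mix
Brownian motion on the tree with independent noise
(`sqrt(signal) * BM + sqrt(1 - signal) * N(0,1)`; `signal = 0.8` by
default), and a two-level categorical trait is thresholded from a latent
Brownian trait to emulate a conserved strategy. Per-site totals are sums of
Fisher log-series individual counts (`p = 0.99`, giving the strongly uneven
dominance typical of such assemblages, roughly a thousand individuals per
site); years are independent multinomial draws from the same expected
composition, emulating resampling noise.

Assembly rules:

* *neutral* — uniform multinomial from the pool;
* *filtering* — relative abundance `exp(-(x_i - mu_s)^2 / (2 w^2))` on the
  focal trait, with `w = filter_strength` (in trait sd units, default 0.5)
  and the optimum moving linearly from `-optimum_shift` to `+optimum_shift`
  sd across the transect; the dry season halves `w` at every site,
  emulating the homogenization of conditions under drought;
* *repulsion* — a fixed number of species (default 15) drawn sequentially
  with probability proportional to the minimal trait distance to the
  already-chosen set, then uniform abundances.

What passing tests show — and what they do not. The generator validates
calibration (neutral SES is centred with unit spread) and directional
recovery (filtering produces clustering, repulsion overdispersion), with a
closed simulate-write-read-analyze loop. It does not emulate spatial
autocorrelation, dispersal limitation, resource dynamics, intraspecific
trait variation, or observational error in abundance counts, so passing
recovery tests here does not certify performance on field data with those
features.

One recovery subtlety worth recording: under filtering, the *functional*
SES MPD is negative at essentially every site, but the *phylogenetic* SES
MPD — while strongly negative on average — is weak at mid-gradient sites.
There the trait optimum sits where the two clades' trait distributions
overlap most, so the filter admits trait-converged species from both
clades and lineage-level clustering genuinely fades. The recovery test
therefore measures the mechanism on the trait distance it acts on and
checks the lineage-level signal at the mean; this is a property of
trait convergence across deep clades, not an artefact.

## Problem sizes and runtime choices

The validation suite runs at deliberately modest sizes chosen to keep the
full battery fast while leaving ample statistical resolution: 100 random
communities and trees for the oracle equivalences, 50 seeded polytope pairs
(17/17/16 in 2/3/4 dimensions) for the hull cross-check, 1000 random pairs
per kind for partition additivity, 200 neutral sites and 20 replicate
gradients at 100 randomizations each for calibration and recovery, and
Monte-Carlo samples of 4e4 points where the exact path is cross-checked.

## Known limitations

* Hull machinery is limited to 4 dimensions (as is the dimension rule that
  feeds it); facet enumeration is brute force and relies on the pair-level
  budget to switch to Monte-Carlo for very rich sites.
* Decoupled functional beta diversity inherits the instability of
  `dcFdist` when the shared fraction is large; diagnostics are reported,
  no stabilization is attempted.
* Aridity is treated as an arbitrary positive covariate supplied in
  metadata; no units are assumed beyond positivity (required by the log
  transform).
* Trees are inputs (or simulated); no inference, dating, or polytomy
  resolution is performed beyond what random taxon insertion creates.
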