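---
title: "CoexNets: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CoexNets: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CoexNets)
```

# The problem

Coexpression analysis asks which genes move together across a compendium
of expression profiles. Which *association measure* is used to quantify
"moving together" changes the resulting network and hence the biology one
can read off it. CoexNets implements eight measures under one calling
convention -- Pearson's r, Spearman's rho, Kendall's tau-b, the Pinto da
Costa--Soares weighted rank coefficient, Hoeffding's D, squared distance
covariance, and the Theil-Sen and rank Theil-Sen slopes -- together with
the downstream machinery their comparison needs: genome-wide partner
ranking, transcription-factor (TF) coordination networks built from
top-list overlaps, the greedy Triple-Link cluster decomposition, and
evaluation layers that score results against pathway co-membership,
positive-gene sets and marginal normality. A synthetic-data generator
with planted ground truth makes every stage testable without external
microarray downloads.

# The association measures and their null tests

All eight measures share the contract: two aligned expression vectors in,
an `AssociationResult` out (statistic, two-sided p-value for the
independence null, n, extras). Constant vectors raise a typed
`degenerateInputError` -- never `NaN` -- because genome-wide drivers must
distinguish "failed" from "zero association".

* **Pearson / Spearman.** r is the sample correlation; rho is r applied
  to average-tie ranks. Both p-values come from
  `t = r * sqrt((n-2)/(1-r^2))` on `n-2` degrees of freedom. For
  Spearman this t approximation (rather than the exact permutation
  distribution) is the convention used in the comparison this package
  supports, and it keeps the two measures' p-values directly comparable.
* **Kendall.** tau-b with tie correction. The p-value uses the normal
  approximation of the concordance score; without ties its variance
  reduces to the textbook `2(2n+5)/(9n(n-1))` form, with ties the
  standard tie-corrected variance is used. Agreement with
  `cor.test(..., method = "kendall", exact = FALSE)` is exact and is
  asserted in the test suite.
* **Weighted rank.** `rW = 1 - 6 * sum(d_i^2 ((n-R_i+1)+(n-S_i+1))) /
  (n^4+n^3-n^2-n)` up-weights disagreement among top ranks, which is
  where coexpression screens operate. Its permutation null has mean 0;
  rather than transcribing a published asymptotic variance we compute
  the *exact* null variance for each n: `rW` is (affinely) a linear
  permutation statistic `T = sum_i a[R_i, S_i]`, whose exact variance
  under uniform permutations is `sum(d_ij^2)/(n-1)` for the doubly
  centered coefficient matrix `d`. The test suite verifies this against
  exhaustive enumeration of all permutations at n = 4; the value is
  memoised per n. Ties are handled by average ranks in the statistic;
  the null is computed for the untied case.
* **Hoeffding's D.** Computed from univariate ranks R, S and the
  bivariate rank Q (points to the lower-left of each observation, ties
  counted half) through the classical D1/D2/D3 sums. D is 0 in
  expectation under independence, 1 at perfect monotone dependence in
  either direction, and at least -0.5 on untied data. The default
  p-value is the conservative bound `min(1, Var0(D)/D^2)` with
  `Var0(D) = 2(n^2+5n-32)/(9n(n-1)(n-3)(n-4))` -- a one-sided
  Chebyshev-type bound. We verified the variance constant by exhaustive
  permutation enumeration at n = 5, 6, 7 before freezing it. Being a
  bound, it compresses the attainable p range (large-compendium screens
  see Hoeffding p confined to a few decades); when calibrated p-values
  matter, `hoeffdingP = "permutation"` gives an add-one-corrected
  permutation p.
* **Distance covariance.** Squared dCov from double-centered Euclidean
  distance matrices; zero exactly when one vector is constant, and at
  the population level zero iff independence. The test permutes one
  sample's distance matrix; the permutation statistic is symmetrised
  over the two arguments so `dcov(x, y)` and `dcov(y, x)` give the same
  p under one seed. The add-one correction keeps p > 0, and the seed is
  mandatory so results are reproducible.
* **Theil-Sen and rank Theil-Sen.** The slope is the median of all
  pairwise slopes, pairs with tied x excluded (the standard
  convention); the intercept `median(y - slope * x)` rides along in
  `extras`. No p-value is canonically attached to the estimator, so we
  adopt the convention of its reference implementation (the `mblm`
  package): a one-sample Wilcoxon signed-rank test that the slope
  multiset has median zero (normal approximation; an all-zero multiset
  gives p = 1). Rank Theil-Sen is, definitionally, Theil-Sen on the
  rank-transformed data -- which also makes it invariant under strictly
  monotone transforms of either variable. Note Theil-Sen is a
  *regression*, not a correlation: `theil_sen(x, y)` is not the
  reciprocal of `theil_sen(y, x)`.

The Theil-Sen breakdown point is exposed as `theilSenBreakdown()`: the
median over pairs breaks when contaminated pairs reach half of all
pairs, i.e. `1 - (1-e)^2 = 1/2`, solved numerically to
`e = 1 - 1/sqrt(2)` (about 29.3%).

# Ranking, coordination networks and Triple-Link

`associateAll()` pairs a query against every other gene and sorts by
p ascending with a *total* tie-break order (|statistic| descending, then
partner id), so downstream overlap counts never depend on storage order
or parallel scheduling. For distance covariance the per-pair permutation
seed is derived from the master seed and the sorted gene-id pair
(`pairSeed()`), for the same reason.

Two TFs are connected in the coordination network when their top-100
lists share strictly more than k = 30 genes (both parameters
adjustable); the overlap count is the edge weight. Triple-Link then
decomposes the network greedily: seed at the heaviest remaining edge,
admit a third member with significant links to both seeds, admit later
members with at least three significant links into the cluster, emit and
remove, repeat. "Significant" means an overlap at least
`mean + multiplier * SD` of the nonzero upper-triangle entries, computed
once on the full matrix.

Numerical conventions worth stating:

* Threshold statistics use the *nonzero* entries only; genome-scale
  matrices are overwhelmingly zero and including the zeros would
  collapse the threshold. With a single (or uniform) nonzero value the
  SD contribution is 0 and the threshold equals that value.
* The significance comparison is *inclusive* (`>=`). In a network whose
  stored overlaps are exactly tied -- the zero-noise planted benchmark
  produces exactly this -- the SD is 0, the threshold equals every edge,
  and a strict comparison could never admit a third member. The edge
  rule itself ("more than k in common") stays strict.
* Seed ties break lexicographically by sorted pair id; growth ties by
  most significant links, then summed overlap, then id. The multiplier
  defaults to 1 and is exposed as a knob.
* An all-zero matrix decomposes to singletons (no threshold exists);
  pairs that attract no third member are emitted as size-2 clusters.

# The synthetic-data generator

`simulateExpression()` plants pathway blocks: each block shares a latent
factor, each gene is a strictly increasing link function of it
(identity, cube, sinh, exp, signed square root) plus independent noise,
standardised, and the whole matrix is mapped affinely into the 3--14
log2-intensity range typical of RMA-normalised arrays. The latent-factor
construction -- rather than a multivariate-normal draw -- is deliberate:
monotone *nonlinear* dependence is exactly the regime that separates
rank measures from Pearson, so the generator must be able to produce it.
Outliers are injected post-link as +/- 6 SD spikes at a per-cell rate,
and a lognormal marginal option exponentiates values (a monotone map:
rank-based results unchanged, Shapiro-Wilk rejections guaranteed).

`simulateTFCoordination()` plants coordinated TF groups: group factors
are made mutually orthogonal (and orthogonal to a global activity
factor) by a QR step, group TFs and their shared targets follow the
group factor, and TFs additionally load on the global factor in
proportion to the noise level, with a housekeeping block riding the
global factor. The housekeeping/global layer reproduces a feature of
real compendia that matters structurally: coordination networks always
carry many *weak* edges, and the Triple-Link mean+SD threshold only
discriminates when they exist.

Default study conditions (chosen once, stated here): 1000 genes, 60
samples, 5 TF groups of 8 TFs, 40 shared targets per group, 60
housekeeping genes, top-list length 100, k = 30, noise SD 0.5 relative
to unit-variance factors. 5 x 8 with n = 100 mirrors a small TF family
complement at desk scale; noise 0.5 puts within-group rank correlations
around 0.6--0.9, the regime noisy public compendia occupy.

What the generator does *not* emulate: probe-level artifacts, RMA
itself, negative regulation (links are increasing), batch structure, and
realistic pathway overlap topology. Passing the planted-recovery tests
therefore shows the pipeline implements its specification, not that any
particular measure will win on a given real compendium.

## A known limitation of the threshold rule

At zero noise the planted network is exactly tie-flat (all within-group
overlaps equal, nothing else stored) and recovery is exact by
construction. At realistic noise (around 0.5) the weak-edge background
appears and recovery is again essentially perfect. In between -- nearly
noise-free but not exactly -- the synthetic network contains *only*
strong edges with small spread: the mean+SD threshold then lands inside
the within-group distribution and Triple-Link over-splits groups. This
is a genuine property of the matrix-level threshold on
weak-edge-free networks, not a code path peculiarity; real compendia do
not occupy that regime. Consequently recovery quality is *not* monotone
in the noise level, and the package documents rather than hides this.

# Evaluation layers

Pathway scoring labels a gene pair S (shares at least one pathway), D
(both annotated, disjoint pathway sets) or N (either gene unannotated);
"same pathway" means at least one shared id because genes are multiply
assigned. Top-100/500 counts conserve their cutoff. The slice confusion
contract: top-100 against a 900-pair slice (next = 101--1000, middle =
centered on the list midpoint, bottom = last 900) with slice counts
divided by 9 before ratios; top-500 against 500-pair slices used
directly. Ratios with empty denominators are reported `NA`, never 0.
Pooled pair lists are de-duplicated by sorted gene-id key before
threshold-style tallies. The middle-slice placement (centered) and the
de-duplication rule are conventions this package fixes where the
procedure's description leaves them open.

Normality profiling wraps Shapiro-Wilk (5 <= n <= 5000) with the
convention p < 0.01 means non-normal -- stated once and used everywhere,
since the two phrasings of this call in the source material conflict;
the package follows the table-footnote reading. The ten-category r/rho
classifier uses delta = 0.1 with boundary cases (equality with delta,
zero correlations) assigned to group II and the non-negative branch
respectively: the printed classifier uses strict inequalities, and these
measure-zero cases must land somewhere deterministic.

# Problem sizes and verification

The test suite verifies (sizes chosen as the package's own desk-scale
study conditions): oracle agreement of all eight statistics against
brute-force enumeration on 200 random vectors (n <= 30, tolerance
1e-10); exhaustive-enumeration checks of the weighted-rank and Hoeffding
nulls at small n; type-I error at alpha = 0.05 within [0.04, 0.06] for
Pearson/Spearman/Kendall over 5000 null replicates at n = 50, with the
empirical tau variance within 5% of theory; Kolmogorov-Smirnov
uniformity of 1000 dcov permutation p-values (999 permutations each);
exact and near-exact planted-group recovery at noise 0 and 0.5; the
Spearman-over-Pearson advantage under 20% outlier contamination across
200 replicates; and the hand-tallied slice-confusion fixtures including
the divide-by-nine rule. `scripts/acceptance.R` recomputes the same
quantities from scratch against the installed package and writes them as
JSON.
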