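#' Available association method identifiers
#'
#' @return Character vector of the eight method ids understood by
#'   [associationTest()] and [associateAll()].
#' @export
assocMethods <- function() {
  c("pearson", "spearman", "kendall", "weighted_rank",
    "hoeffding", "dcov", "theil_sen", "rank_theil_sen")
}

#' Rank-transform an expression vector
#'
#' Ranks in ascending order with the average-rank convention for ties:
#' tied values receive the mean of the positions they occupy, so the
#' ranks always sum to n(n+1)/2.
#'
#' @param x Numeric vector of finite values.
#' @return Numeric vector of (possibly fractional) ranks.
#' @examples
#' rankTransform(c(5, 5, 7))   # 1.5 1.5 3
#' @export
rankTransform <- function(x) {
  checkFinite(x, "x")
  if (length(x) < 1L) coexError("empty vector", "invalidInputError")
  rank(x, ties.method = "average")
}

#' Pairwise gene association with an independence test
#'
#' Computes one of eight association statistics between two aligned
#' expression vectors together with a two-sided p-value under the null
#' of independence:
#'
#' * `pearson` -- sample correlation r; p from t = r * sqrt((n-2)/(1-r^2))
#'   on n-2 degrees of freedom.
#' * `spearman` -- Pearson correlation of the average-tie ranks; p from
#'   the same t approximation applied to rho.
#' * `kendall` -- tau (tie-corrected tau-b when ties exist); p from the
#'   normal approximation, using the null variance
#'   2(2n+5)/(9n(n-1)) for untied data and the standard tie-corrected
#'   variance of the concordance score otherwise.
#' * `weighted_rank` -- the Pinto da Costa-Soares coefficient
#'   rW = 1 - 6 * sum(d_i^2 * ((n-R_i+1) + (n-S_i+1))) / (n^4+n^3-n^2-n),
#'   which up-weights disagreements among the top ranks; p from a normal
#'   approximation whose null variance is computed *exactly* for each n
#'   from the linear permutation-statistic identity (and verified by
#'   exhaustive enumeration in the test suite).
#' * `hoeffding` -- Hoeffding's D from univariate ranks R, S and the
#'   bivariate rank Q (number of points southwest of each observation)
#'   through the D1/D2/D3 sums; D is 0 in expectation under independence
#'   and reaches 1 at perfect monotone dependence (either direction).
#'   The default p-value is the conservative Chebyshev-type bound
#'   min(1, Var0(D)/D^2) with Var0(D) = 2(n^2+5n-32)/(9n(n-1)(n-3)(n-4));
#'   this compresses the attainable p range, so a calibrated permutation
#'   p is available via `hoeffdingP = "permutation"`.
#' * `dcov` -- squared distance covariance from double-centered Euclidean
#'   distance matrices; p from a permutation test of n * dCov^2 with the
#'   add-one correction (p + 1/(nPerm+1) resolution, never exactly 0).
#' * `theil_sen` -- median of all pairwise slopes (y_j-y_i)/(x_j-x_i),
#'   pairs with equal x excluded; the intercept median(y - slope * x) is
#'   returned in `extras`.  The p-value is a one-sample Wilcoxon
#'   signed-rank test that the slope multiset has median zero, matching
#'   the reference implementation in the mblm package.
#' * `rank_theil_sen` -- `theil_sen` applied to the rank-transformed
#'   observations.
#'
#' All tests are two-sided.  Constant input raises a typed
#' `degenerateInputError` rather than returning `NaN`.
#'
#' @param x,y Numeric vectors of equal length (n >= 4; n >= 5 for
#'   `hoeffding`), sample-aligned.
#' @param method One of [assocMethods()].
#' @param nPerm Number of permutations for `dcov` (and for
#'   `hoeffdingP = "permutation"`); must be at least 99.
#' @param seed Integer seed for the permutation test; required for
#'   `dcov` so results are reproducible.
#' @param hoeffdingP `"bound"` (default) or `"permutation"`.
#' @return An [AssociationResult-class].
#' @examples
#' x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
#' statistic(associationTest(x, y, "kendall"))
#' @export
associationTest <- function(x, y, method = assocMethods(),
                            nPerm = 999L, seed = NULL,
                            hoeffdingP = c("bound", "permutation")) {
  method <- match.arg(method)
  hoeffdingP <- match.arg(hoeffdingP)
  checkFinite(x, "x"); checkFinite(y, "y")
  if (length(x) != length(y))
    coexError("'x' and 'y' must have equal length", "invalidInputError")
  n <- length(x)
  nMin <- if (method == "hoeffding") 5L else 4L
  if (n < nMin)
    coexError(sprintf("method '%s' needs at least %d observations",
                      method, nMin), "invalidInputError")
  switch(method,
    pearson       = pearsonTest(x, y),
    spearman      = spearmanTest(x, y),
    kendall       = kendallTest(x, y),
    weighted_rank = weightedRankTest(x, y),
    hoeffding     = hoeffdingTest(x, y, hoeffdingP, nPerm, seed),
    dcov          = dcovTest(x, y, nPerm, seed),
    theil_sen     = theilSenTest(x, y),
    rank_theil_sen = theilSenTest(rankTransform(x), rankTransform(y),
                                  method = "rank_theil_sen"))
}

newAssoc <- function(method, statistic, pValue, n, extras = list()) {
  new("AssociationResult", method = method,
      statistic = as.numeric(statistic),
      pValue = as.numeric(min(max(pValue, 0), 1)),
      nObs = as.integer(n), extras = extras)
}

# ---- Pearson / Spearman -------------------------------------------------

corT <- function(r, n) {
  # two-sided p from t = r * sqrt((n-2)/(1-r^2)) on n-2 df
  if (1 - r^2 <= 0) return(0)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tval), df = n - 2)
}

pearsonTest <- function(x, y) {
  if (isConstant(x) || isConstant(y))
    coexError("constant vector: Pearson correlation undefined",
              "degenerateInputError")
  n <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  r <- min(max(r, -1), 1)
  newAssoc("pearson", r, corT(r, n), n)
}

spearmanTest <- function(x, y) {
  if (isConstant(x) || isConstant(y))
    coexError("constant vector: rank variance is zero",
              "degenerateInputError")
  res <- pearsonTest(rankTransform(x), rankTransform(y))
  newAssoc("spearman", res@statistic, res@pValue, res@nObs)
}

# ---- Kendall ------------------------------------------------------------

kendallTest <- function(x, y) {
  if (isConstant(x) || isConstant(y))
    coexError("all pairs tied in one variable", "degenerateInputError")
  n <- length(x)
  sx <- sign(outer(x, x, "-")); sy <- sign(outer(y, y, "-"))
  ut <- upper.tri(sx)
  S <- sum(sx[ut] * sy[ut])                    # concordant minus discordant
  tx <- tieSizes(x); ty <- tieSizes(y)
  n0 <- n * (n - 1) / 2
  n1 <- sum(tx * (tx - 1) / 2); n2 <- sum(ty * (ty - 1) / 2)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))
  # null variance of S; reduces to n(n-1)(2n+5)/18 without ties
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5)); vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  varS <- (v0 - vt - vu) / 18 +
    sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1)) +
    sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
  z <- S / sqrt(varS)
  newAssoc("kendall", tau, 2 * stats::pnorm(-abs(z)), n,
           extras = list(concordanceScore = S))
}

# ---- Weighted rank ------------------------------------------------------

# exact null variance of rW at sample size n under uniform random
# permutations: rW = 1 - 6 T / Dn with T = sum_i a[R_i, S_i] a linear
# permutation statistic, so Var(T) = sum(d^2)/(n-1) with d the doubly
# centered coefficient matrix.  Memoised per n.
rWNullCache <- new.env(parent = emptyenv())
rWNullVar <- function(n) {
  key <- as.character(n)
  if (!is.null(rWNullCache[[key]])) return(rWNullCache[[key]])
  Dn <- n^4 + n^3 - n^2 - n
  a <- outer(seq_len(n), seq_len(n),
             function(r, s) (r - s)^2 * (2 * n + 2 - r - s))
  d <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  v <- 36 * (sum(d^2) / (n - 1)) / Dn^2
  rWNullCache[[key]] <- v
  v
}

weightedRankStat <- function(R, S) {
  n <- length(R)
  1 - 6 * sum((R - S)^2 * ((n - R + 1) + (n - S + 1))) /
    (n^4 + n^3 - n^2 - n)
}

weightedRankTest <- function(x, y) {
  if (isConstant(x) || isConstant(y))
    coexError("constant vector: ranks are all tied", "degenerateInputError")
  n <- length(x)
  rw <- weightedRankStat(rankTransform(x), rankTransform(y))
  z <- rw / sqrt(rWNullVar(n))
  newAssoc("weighted_rank", rw, 2 * stats::pnorm(-abs(z)), n)
}

# ---- Hoeffding ----------------------------------------------------------

hoeffdingD <- function(x, y) {
  n <- length(x)
  R <- rank(x, ties.method = "average")
  S <- rank(y, ties.method = "average")
  # bivariate rank: points strictly southwest, ties counted half
  cx <- outer(x, x, function(a, b) (b < a) + 0.5 * (b == a))
  cy <- outer(y, y, function(a, b) (b < a) + 0.5 * (b == a))
  Q <- rowSums(cx * cy) - 0.25          # remove the self term (0.5 * 0.5)
  D1 <- sum(Q * (Q - 1))
  D2 <- sum((R - 1) * (R - 2) * (S - 1) * (S - 2))
  D3 <- sum((R - 2) * (S - 2) * Q)
  30 * ((n - 2) * (n - 3) * D1 + D2 - 2 * (n - 2) * D3) /
    (n * (n - 1) * (n - 2) * (n - 3) * (n - 4))
}

hoeffdingNullVar <- function(n) {
  2 * (n^2 + 5 * n - 32) / (9 * n * (n - 1) * (n - 3) * (n - 4))
}

hoeffdingTest <- function(x, y, pMode, nPerm, seed) {
  if (isConstant(x) || isConstant(y))
    coexError("constant vector: ranks are all tied", "degenerateInputError")
  n <- length(x)
  D <- hoeffdingD(x, y)
  if (pMode == "bound") {
    # one-sided Chebyshev-type bound P(D >= d) <= Var0(D)/d^2; conservative,
    # so attainable p-values are compressed toward a narrow range
    p <- if (D > 0) min(1, hoeffdingNullVar(n) / D^2) else 1
  } else {
    if (nPerm < 99L)
      coexError("nPerm must be >= 99", "configurationError")
    perm <- withSeed(seed, vapply(seq_len(nPerm), function(i)
      hoeffdingD(x, sample(y)), numeric(1)))
    p <- (1 + sum(perm >= D)) / (nPerm + 1)
  }
  newAssoc("hoeffding", D, p, n)
}

# ---- Distance covariance ------------------------------------------------

centeredDist <- function(x) {
  a <- abs(outer(x, x, "-"))
  sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
}

dcovTest <- function(x, y, nPerm, seed) {
  if (nPerm < 99L)
    coexError("nPerm must be >= 99 for a usable p resolution",
              "configurationError")
  if (is.null(seed))
    coexError("dcov permutation test requires an explicit seed",
              "configurationError")
  n <- length(x)
  A <- centeredDist(x); B <- centeredDist(y)
  v2 <- mean(A * B)                     # squared distance covariance
  v2 <- max(v2, 0)
  obs <- n * v2
  # exactly one sample's distance matrix is permuted (the observed value
  # is the identity permutation, so the p-value is exchangeable-uniform);
  # which one is chosen canonically from the data, not the argument
  # order, so dcov(x, y) and dcov(y, x) agree under one seed
  if (vectorBefore(y, x)) { tmp <- A; A <- B; B <- tmp }
  exceed <- withSeed(seed, {
    cnt <- 0L
    for (i in seq_len(nPerm)) {
      p <- sample.int(n)
      if (sum(A[p, p] * B) / n >= obs) cnt <- cnt + 1L
    }
    cnt
  })
  newAssoc("dcov", v2, (1 + exceed) / (nPerm + 1), n,
           extras = list(nPerm = as.integer(nPerm)))
}

# ---- Theil-Sen ----------------------------------------------------------

pairwiseSlopes <- function(x, y) {
  n <- length(x)
  dx <- outer(x, x, "-"); dy <- outer(y, y, "-")
  ut <- upper.tri(dx)
  keep <- ut & dx != 0
  dy[keep] / dx[keep]
}

theilSenTest <- function(x, y, method = "theil_sen") {
  slopes <- pairwiseSlopes(x, y)
  if (length(slopes) == 0L)
    coexError("all x values equal: no pairwise slopes", "degenerateInputError")
  slope <- stats::median(slopes)
  intercept <- stats::median(y - slope * x)
  nz <- slopes[slopes != 0]
  p <- if (length(nz) == 0L) 1 else
    suppressWarnings(stats::wilcox.test(slopes, mu = 0,
                                        exact = FALSE)$p.value)
  newAssoc(method, slope, p, length(x),
           extras = list(intercept = intercept,
                         nSlopes = length(slopes)))
}

#' Asymptotic breakdown fraction of the Theil-Sen slope
#'
#' The Theil-Sen slope is the median over all C(n, 2) pairwise slopes, so
#' it can be driven arbitrarily far only once the pairs touching a
#' contaminated point make up at least half of all pairs.  If a fraction
#' e of the n points is contaminated, the clean pairs number
#' C((1-e) n, 2), so asymptotically the estimator breaks when
#' 1 - (1-e)^2 >= 1/2.  This function solves that pair-counting
#' condition numerically and returns the smallest such e,
#' 1 - 1/sqrt(2) (about 29.3%).
#'
#' @return Breakdown fraction in (0, 1).
#' @examples
#' round(100 * theilSenBreakdown(), 1)  # 29.3
#' @export
theilSenBreakdown <- function() {
  stats::uniroot(function(e) (1 - (1 - e)^2) - 0.5,
                 interval = c(0, 1), tol = 1e-12)$root
}
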