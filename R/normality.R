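# marginal normality of expression vectors and the ten-category
# classification of gene pairs by Spearman-versus-Pearson behaviour

#' Shapiro-Wilk normality call for an expression vector
#'
#' Wraps the standard Shapiro-Wilk test and adds the dichotomous call
#' used throughout the evaluation: p < alpha means non-normal, so
#' `isNormal` is `TRUE` exactly when `p >= alpha` (alpha defaults to the
#' stringent 0.01 used in the study).
#'
#' @param x Numeric vector, 5 <= n <= 5000, non-constant.
#' @param alpha Significance level for the normality call.
#' @return List with `w`, `p.value`, `isNormal`.
#' @export
testNormality <- function(x, alpha = 0.01) {
  checkFinite(x, "x")
  if (length(x) < 5L || length(x) > 5000L)
    coexError("Shapiro-Wilk needs 5 <= n <= 5000", "invalidInputError")
  if (isConstant(x))
    coexError("constant vector has no distribution shape",
              "degenerateInputError")
  sw <- stats::shapiro.test(x)
  list(w = unname(sw$statistic), p.value = sw$p.value,
       isNormal = sw$p.value >= alpha)
}

#' Classify a gene pair by its Pearson r and Spearman rho
#'
#' Ten exhaustive categories in three groups: group I when
#' `rho - r > delta` (rank correlation clearly larger), group II when
#' `|r - rho| <= delta`, group III when `r - rho > delta`.  Within each
#' group the subcategory follows the sign pattern of r and rho:
#'
#' | category | group | pattern |
#' |---|---|---|
#' | 1 | I | r < 0, rho < 0 |
#' | 2 | I | r < 0, rho >= 0 |
#' | 3 | I | r >= 0, rho >= 0 |
#' | 4 | II | r < 0, rho < 0 |
#' | 5 | II | r < 0, rho >= 0 |
#' | 6 | II | r >= 0, rho < 0 |
#' | 7 | II | r >= 0, rho >= 0 |
#' | 8 | III | r < 0, rho < 0 |
#' | 9 | III | r >= 0, rho < 0 |
#' | 10 | III | r >= 0, rho >= 0 |
#'
#' Boundary convention: exact equality `|r - rho| == delta` falls in
#' group II, and a zero correlation is treated as the non-negative
#' branch; the remaining sign patterns are impossible given the group
#' constraint.
#'
#' @param r Pearson correlation in `[-1, 1]`.
#' @param rho Spearman correlation in `[-1, 1]`.
#' @param delta Width of the "approximately equal" band (default 0.1).
#' @return List with integer `category` (1-10) and `group`
#'   (`"I"`, `"II"`, `"III"`).
#' @examples
#' classifyPair(-0.3, -0.1)$category  # 1
#' classifyPair(0.5, 0.55)$category   # 7
#' classifyPair(0.68, 0.40)$category  # 10
#' @export
classifyPair <- function(r, rho, delta = 0.1) {
  if (abs(r) > 1 || abs(rho) > 1)
    coexError("correlations must lie in [-1, 1]", "invalidInputError")
  rNeg <- r < 0; sNeg <- rho < 0
  if (rho - r > delta) {
    group <- "I"
    category <- if (rNeg && sNeg) 1L else if (rNeg) 2L else 3L
  } else if (r - rho > delta) {
    group <- "III"
    category <- if (rNeg && sNeg) 8L else if (sNeg) 9L else 10L
  } else {
    group <- "II"
    category <- if (rNeg && sNeg) 4L else if (rNeg) 5L
                else if (sNeg) 6L else 7L
  }
  list(category = category, group = group)
}

#' Classify many pairs at once
#'
#' @param r,rho Numeric vectors of equal length.
#' @param delta Band width as in [classifyPair()].
#' @return Data frame with columns `category` and `group`.
#' @export
classifyPairs <- function(r, rho, delta = 0.1) {
  res <- mapply(function(a, b) classifyPair(a, b, delta), r, rho,
                SIMPLIFY = FALSE)
  data.frame(category = vapply(res, `[[`, integer(1), "category"),
             group = vapply(res, `[[`, character(1), "group"),
             stringsAsFactors = FALSE)
}

#' Fraction of normally distributed genes among top coexpression partners
#'
#' Ranks all partners of `query` with [associateAll()], keeps the top
#' `k`, and returns the fraction whose expression vector passes the
#' Shapiro-Wilk normality call at `alpha`.
#'
#' @inheritParams associateAll
#' @param k Number of top partners to profile (study value: 500).
#' @param alpha Normality significance level.
#' @return Numeric fraction in `[0, 1]`.
#' @export
normalFractionTopK <- function(mat, query, method = assocMethods(),
                               k = 500L, alpha = 0.01, nPerm = 999L,
                               seed = NULL) {
  method <- match.arg(method)
  mat <- asExprMatrix(mat)
  ranked <- associateAll(mat, query, method, nPerm = nPerm, seed = seed)
  if (nrow(ranked) < k)
    warning(sprintf("only %d partners available (k = %d)", nrow(ranked), k))
  top <- topN(ranked, k)
  calls <- vapply(top, function(g)
    testNormality(mat[g, ], alpha)$isNormal, logical(1))
  mean(calls)
}
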