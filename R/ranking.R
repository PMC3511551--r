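# genome-wide ranking of coexpression partners for one query gene

# extract a plain genes x samples matrix from supported containers
asExprMatrix <- function(mat) {
  if (methods::is(mat, "SummarizedExperiment")) {
    # accept the standard Bioconductor container without importing it
    mat <- SummarizedExperiment::assay(mat)
  }
  mat <- as.matrix(mat)
  if (is.null(rownames(mat)))
    coexError("expression matrix needs gene ids as rownames",
              "invalidInputError")
  if (anyDuplicated(rownames(mat)))
    coexError("duplicate gene ids in expression matrix", "invalidInputError")
  if (!is.numeric(mat) || anyNA(mat) || any(!is.finite(mat)))
    coexError("expression matrix must be numeric and finite",
              "invalidInputError")
  if (ncol(mat) < 5L)
    coexError("at least 5 samples required", "invalidInputError")
  mat
}

#' Rank all genes by association with a query gene
#'
#' Pairs `query` against every other gene of the matrix with the chosen
#' association measure and returns the list sorted by p-value ascending,
#' with ties broken by absolute statistic descending and then by partner
#' id (lexicographic), so the ordering is a deterministic total order.
#' Genes whose expression is constant across samples cannot be scored;
#' they are skipped with a message.
#'
#' For `dcov`, the permutation seed of each pair is derived from the
#' master `seed` and the two gene ids via [pairSeed()], so p-values do
#' not depend on the order in which partners are processed.
#'
#' @param mat Numeric genes x samples matrix with gene ids as rownames
#'   (a `SummarizedExperiment` is also accepted).
#' @param query Gene id present in `mat`.
#' @param method One of [assocMethods()].
#' @param nPerm,seed,hoeffdingP Passed to [associationTest()].
#' @return A `data.frame` with columns `partner`, `statistic`, `p.value`
#'   and attributes `query`, `method`.
#' @examples
#' m <- simulateExpression(simConfig(nGenes = 30, nSamples = 20, seed = 1))
#' head(associateAll(m$matrix, rownames(m$matrix)[1], "spearman"))
#' @export
associateAll <- function(mat, query, method = assocMethods(),
                         nPerm = 999L, seed = NULL,
                         hoeffdingP = c("bound", "permutation")) {
  method <- match.arg(method)
  hoeffdingP <- match.arg(hoeffdingP)
  mat <- asExprMatrix(mat)
  if (!query %in% rownames(mat))
    coexError(sprintf("query gene '%s' not in matrix", query), "lookupError")
  qv <- mat[query, ]
  if (isConstant(qv))
    coexError("query gene has constant expression", "degenerateInputError")
  partners <- setdiff(rownames(mat), query)
  keep <- partners[!apply(mat[partners, , drop = FALSE], 1, isConstant)]
  dropped <- setdiff(partners, keep)
  if (length(dropped))
    message(sprintf("skipping %d constant gene(s): %s", length(dropped),
                    paste(utils::head(dropped, 5L), collapse = ", ")))
  if (length(keep) == 0L) {
    out <- data.frame(partner = character(), statistic = numeric(),
                      p.value = numeric(), stringsAsFactors = FALSE)
  } else if (method %in% c("pearson", "spearman")) {
    # closed-form measures vectorise over all partners at once
    pm <- mat[keep, , drop = FALSE]
    if (method == "spearman") {
      qv <- rankTransform(qv)
      pm <- t(apply(pm, 1, rankTransform))
    }
    r <- as.numeric(stats::cor(qv, t(pm)))
    r <- pmin(pmax(r, -1), 1)
    n <- ncol(mat)
    tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- ifelse(1 - r^2 <= 0, 0, 2 * stats::pt(-abs(tval), df = n - 2))
    out <- data.frame(partner = keep, statistic = r, p.value = p,
                      stringsAsFactors = FALSE)
  } else {
    res <- lapply(keep, function(g) {
      s <- if (method == "dcov" && !is.null(seed))
        pairSeed(seed, query, g) else seed
      associationTest(qv, mat[g, ], method, nPerm = nPerm, seed = s,
                      hoeffdingP = hoeffdingP)
    })
    out <- data.frame(partner = keep,
                      statistic = vapply(res, statistic, numeric(1)),
                      p.value = vapply(res, pValue, numeric(1)),
                      stringsAsFactors = FALSE)
  }
  ord <- order(out$p.value, -abs(out$statistic), out$partner,
               method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "query") <- query
  attr(out, "method") <- method
  out
}

#' Head of a ranked pair list
#'
#' Returns the first `n` partner ids of a ranked list produced by
#' [associateAll()], preserving order.  Shorter lists are returned whole.
#'
#' @param ranked A ranked pair `data.frame` from [associateAll()] (or any
#'   data frame with a `partner` column ordered by significance).
#' @param n Maximum number of partners (>= 1).
#' @return Character vector of at most `n` partner ids.
#' @export
topN <- function(ranked, n = 100L) {
  if (n < 1L) coexError("n must be >= 1", "configurationError")
  utils::head(ranked$partner, n)
}
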