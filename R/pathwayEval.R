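# scoring ranked gene-pair lists against pathway membership, and
# clusters against positive-gene sets

#' Label a gene pair by pathway co-membership
#'
#' `"S"` if the two genes share at least one pathway, `"N"` if either
#' gene is assigned to no pathway, `"D"` otherwise (both assigned, but to
#' disjoint pathway sets).  The three labels are exhaustive and mutually
#' exclusive.
#'
#' @param g1,g2 Distinct gene ids.
#' @param map Pathway map: named list, gene id -> character vector of
#'   pathway ids (see [readPathwayMap()]).
#' @return One of `"S"`, `"D"`, `"N"`.
#' @export
labelPair <- function(g1, g2, map) {
  if (identical(g1, g2))
    coexError("a pair must consist of two distinct genes",
              "invalidPairError")
  p1 <- map[[g1]]; p2 <- map[[g2]]
  if (is.null(p1) || is.null(p2) || !length(p1) || !length(p2)) return("N")
  if (length(intersect(p1, p2))) "S" else "D"
}

#' Label every row of a gene-pair table
#'
#' @param pairs Data frame with columns `gene1` and `gene2` (a ranked
#'   pair list from [associateAll()] can be converted by adding the
#'   query as `gene1` and renaming `partner` to `gene2`).
#' @param map Pathway map as in [labelPair()].
#' @return `pairs` with an added character column `label`.
#' @export
labelPairs <- function(pairs, map) {
  pairs$label <- vapply(seq_len(nrow(pairs)), function(i)
    labelPair(pairs$gene1[i], pairs$gene2[i], map), character(1))
  pairs
}

#' De-duplicate unordered gene pairs
#'
#' A pair reached from two different query genes appears twice in pooled
#' ranked lists.  Rows are reduced to unique unordered pairs keyed by the
#' sorted gene ids, keeping the first occurrence (the most significant
#' one when the input is sorted by p-value).
#'
#' @param pairs Data frame with columns `gene1`, `gene2`.
#' @return The de-duplicated data frame.
#' @export
dedupePairs <- function(pairs) {
  key <- ifelse(pairs$gene1 < pairs$gene2,
                paste(pairs$gene1, pairs$gene2, sep = "\r"),
                paste(pairs$gene2, pairs$gene1, sep = "\r"))
  out <- pairs[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' S/D/N counts among the top pairs
#'
#' Tallies the S, D and N labels over the first `cutoff` pairs of a
#' p-sorted labeled list; counts always sum to the number of pairs
#' actually examined.
#'
#' @param labels Character vector of `"S"`/`"D"`/`"N"` labels, ordered by
#'   ascending p-value.
#' @param cutoff Number of top pairs to examine (the study used 100 and
#'   500).  If the list is shorter a warning is raised and the whole
#'   list is counted.
#' @return Named integer vector `c(S = , D = , N = )`.
#' @export
topCounts <- function(labels, cutoff = 100L) {
  if (length(labels) < cutoff) {
    warning(sprintf("list has only %d pairs; counting all of them",
                    length(labels)))
    cutoff <- length(labels)
  }
  head <- labels[seq_len(cutoff)]
  c(S = sum(head == "S"), D = sum(head == "D"), N = sum(head == "N"))
}

sliceIndices <- function(L, topCutoff, slice, sliceLen) {
  idx <- switch(slice,
    next_ = (topCutoff + 1L):(topCutoff + sliceLen),
    middle = {
      start <- floor((L - sliceLen) / 2) + 1L
      start:(start + sliceLen - 1L)
    },
    bottom = (L - sliceLen + 1L):L)
  if (min(idx) < 1L || max(idx) > L)
    coexError("list too short for the requested slice", "sliceError")
  idx
}

#' Confusion metrics between the top pairs and a deeper slice
#'
#' Compares the top of a p-sorted labeled pair list against one of three
#' deeper slices to obtain sensitivity, specificity and accuracy for a
#' target label (same-pathway `"S"` or different-pathway `"D"`).
#'
#' With `topCutoff = 100` the slices hold 900 pairs -- `"next"` is pairs
#' 101-1000, `"middle"` is 900 pairs centered on the list midpoint,
#' `"bottom"` is the last 900 -- and, because the slice is nine times the
#' top, slice counts are divided by 9 before the ratios are formed.  With
#' `topCutoff = 500` the slices hold 500 pairs (`"next"` = 501-1000) and
#' the counts are used directly.
#'
#' TP is the number of target-label pairs in the top, FP the remainder
#' of the top; FN is the (rescaled) count of target-label pairs in the
#' slice and TN the (rescaled) remainder of the slice.  Ratios with zero
#' denominators are reported as `NA`, never as 0.
#'
#' @param labels Character vector of labels ordered by ascending p.
#' @param topCutoff 100 or 500.
#' @param slice `"next"`, `"middle"` or `"bottom"`.
#' @param target `"S"` or `"D"`.
#' @return Data frame row with `tp`, `fp`, `fn`, `tn`, `sensitivity`,
#'   `specificity`, `accuracy`.
#' @export
sliceConfusion <- function(labels, topCutoff = 100L,
                           slice = c("next", "middle", "bottom"),
                           target = c("S", "D")) {
  slice <- match.arg(slice)
  target <- match.arg(target)
  if (!topCutoff %in% c(100L, 500L))
    coexError("topCutoff must be 100 or 500", "configurationError")
  L <- length(labels)
  if (L < topCutoff)
    coexError("list shorter than topCutoff", "sliceError")
  sliceLen <- if (topCutoff == 100L) 900L else 500L
  div <- if (topCutoff == 100L) 9 else 1
  top <- labels[seq_len(topCutoff)]
  sl <- labels[sliceIndices(L, topCutoff,
                            if (slice == "next") "next_" else slice,
                            sliceLen)]
  tp <- sum(top == target)
  fp <- topCutoff - tp
  fn <- sum(sl == target) / div
  tn <- (sliceLen - sum(sl == target)) / div
  ratio <- function(a, b) if (a + b == 0) NA_real_ else a / (a + b)
  data.frame(tp = tp, fp = fp, fn = fn, tn = tn,
             sensitivity = ratio(tp, fn),
             specificity = ratio(tn, fp),
             accuracy = if (tp + fp + tn + fn == 0) NA_real_
                        else (tp + tn) / (tp + fp + tn + fn))
}

#' Fraction of same-pathway pairs below a p-value threshold
#'
#' Restricts a labeled pair list to pairs with `p < threshold` and
#' returns the fraction labeled `"S"` together with the number retained;
#' `(0, 0)` when no pair survives.
#'
#' @param labels Character vector of `"S"`/`"D"`/`"N"` labels.
#' @param p Numeric p-values aligned with `labels`.
#' @param threshold P-value threshold in `(0, 1]`.
#' @return Named list `fraction_same_pathway`, `n_pairs`.
#' @export
pvalueCutoffFraction <- function(labels, p, threshold) {
  if (threshold <= 0 || threshold > 1)
    coexError("threshold must be in (0, 1]", "configurationError")
  keep <- p < threshold
  n <- sum(keep)
  list(fraction_same_pathway = if (n == 0) 0 else sum(labels[keep] == "S") / n,
       n_pairs = n)
}

#' Positive-gene content of Triple-Link clusters
#'
#' For each cluster and each named positive-gene set, counts the members
#' found in the set; the per-cluster totals pool all sets (a member in
#' several sets is counted once) and are also expressed as a percentage
#' of cluster size.
#'
#' @param res A [TripleLinkResult-class].
#' @param positives Named list of character vectors of positive gene ids.
#' @return Data frame with one row per cluster: `cluster_index`, `size`,
#'   `n_positive`, `percent_positive`, plus one hit-count column per
#'   positive set.
#' @export
clusterPositiveStats <- function(res, positives) {
  cls <- clusters(res)
  if (is.null(names(positives)))
    names(positives) <- paste0("set", seq_along(positives))
  rows <- lapply(seq_along(cls), function(i) {
    cl <- cls[[i]]
    hits <- vapply(positives, function(s) sum(cl %in% s), integer(1))
    allPos <- unique(unlist(positives))
    npos <- sum(cl %in% allPos)
    cbind(data.frame(cluster_index = i, size = length(cl),
                     n_positive = npos,
                     percent_positive = 100 * npos / length(cl)),
          as.data.frame(as.list(hits)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cluster_index = integer(), size = integer(),
                      n_positive = integer(), percent_positive = numeric())
  rownames(out) <- NULL
  out
}
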