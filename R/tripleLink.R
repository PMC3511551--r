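# greedy Triple-Link decomposition of a coordination network

#' Significance threshold of a coordination matrix
#'
#' Mean plus `multiplier` standard deviations (sample SD) of the nonzero
#' upper-triangle overlaps.  Zeros are structural absences -- genome-scale
#' coordination matrices are overwhelmingly empty -- so they are excluded;
#' with a single nonzero entry the SD is taken as 0.
#'
#' @param cm A [CoordinationMatrix-class].
#' @param multiplier SD multiplier (default 1).
#' @return Numeric threshold.
#' @export
significanceThreshold <- function(cm, multiplier = 1) {
  m <- overlapMatrix(cm)
  nz <- m[upper.tri(m) & m > 0]
  if (length(nz) == 0L)
    coexError("coordination matrix has no edges", "emptyNetworkError")
  s <- if (length(nz) > 1L) stats::sd(nz) else 0
  mean(nz) + multiplier * s
}

#' Decompose a coordination network with Triple-Link
#'
#' Greedy extraction of TF clusters from a [CoordinationMatrix-class]:
#'
#' 1. Seed with the remaining pair of highest overlap (ties broken by
#'    lexicographic pair id); the seed pair joins unconditionally.
#' 2. A third member must have a significant connectivity to *both*
#'    seeds; every later member needs at least three significant
#'    connectivities to TFs already in the cluster.
#' 3. When no admissible candidate remains the cluster is emitted, its
#'    TFs are removed from the matrix, and extraction restarts at 1
#'    while any connected pair remains.  TFs never joined are reported
#'    as singletons.
#'
#' A connectivity is significant when the overlap is at least the
#' matrix-level threshold of [significanceThreshold()] (computed once,
#' not per round).  The comparison is inclusive so that a matrix of
#' identical overlaps -- where the SD is 0 and the threshold equals every
#' edge -- still grows clusters.  Among several admissible candidates the
#' one with the most significant links wins, then the largest summed
#' overlap into the cluster, then the lexicographically smallest id.
#' Because seeds are taken in decreasing overlap order, cluster 1 is
#' always at least as tightly coordinated as cluster 2, and so on.
#'
#' @param cm A [CoordinationMatrix-class].
#' @param multiplier SD multiplier for the significance threshold.
#' @return A [TripleLinkResult-class].
#' @export
tripleLinkDecompose <- function(cm, multiplier = 1) {
  m <- overlapMatrix(cm)
  if (all(m == 0))
    return(new("TripleLinkResult", clusters = list(),
               seedOverlaps = numeric(), singletons = rownames(m),
               threshold = NA_real_, multiplier = multiplier))
  thr <- significanceThreshold(cm, multiplier)
  active <- rownames(m)
  clusterList <- list()
  seedOv <- numeric()
  while (length(active) >= 2L) {
    sub <- m[active, active, drop = FALSE]
    best <- max(sub[upper.tri(sub)])
    if (best <= 0) break
    idx <- which(upper.tri(sub) & sub == best, arr.ind = TRUE)
    pairIds <- cbind(active[idx[, 1]], active[idx[, 2]])
    pairKey <- apply(pairIds, 1, function(p) paste(sort(p), collapse = "\r"))
    seed <- sort(pairIds[order(pairKey)[1], ])
    cl <- seed
    repeat {
      cand <- setdiff(active, cl)
      if (length(cand) == 0L) break
      links <- m[cand, cl, drop = FALSE]
      nSig <- rowSums(links >= thr)
      admissible <- if (length(cl) == 2L) nSig == 2L else nSig >= 3L
      if (!any(admissible)) break
      cand <- cand[admissible]
      sumOv <- rowSums(links[admissible, , drop = FALSE])
      ord <- order(-nSig[admissible], -sumOv, cand, method = "radix")
      cl <- c(cl, cand[ord[1]])
    }
    clusterList[[length(clusterList) + 1L]] <- cl
    seedOv <- c(seedOv, best)
    active <- setdiff(active, cl)
  }
  new("TripleLinkResult", clusters = clusterList, seedOverlaps = seedOv,
      singletons = active, threshold = thr, multiplier = multiplier)
}

#' Write a Triple-Link cluster report
#'
#' `writeClusterReport()` writes one TSV row per cluster member
#' (`cluster_index`, `member_rank`, `tf_id`, `n_significant_links`,
#' counted within the member's cluster); `writeClusterJSON()` writes the
#' same content as JSON together with the threshold and multiplier so a
#' run can be reproduced.
#'
#' @param res A [TripleLinkResult-class].
#' @param cm The [CoordinationMatrix-class] it came from.
#' @param path Output file.
#' @return `path`, invisibly.
#' @name clusterReport
NULL

clusterReportTable <- function(res, cm) {
  m <- overlapMatrix(cm)
  thr <- threshold(res)
  if (length(clusters(res)) == 0L)
    return(data.frame(cluster_index = integer(), member_rank = integer(),
                      tf_id = character(), n_significant_links = integer(),
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_along(clusters(res)), function(i) {
    cl <- clusters(res)[[i]]
    data.frame(cluster_index = i,
               member_rank = seq_along(cl),
               tf_id = cl,
               n_significant_links = vapply(cl, function(tf)
                 sum(m[tf, setdiff(cl, tf)] >= thr), integer(1)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @rdname clusterReport
#' @export
writeClusterReport <- function(res, cm, path) {
  utils::write.table(clusterReportTable(res, cm), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname clusterReport
#' @export
writeClusterJSON <- function(res, cm, path) {
  payload <- list(
    parameters = list(nTop = nTop(cm), kMin = kMin(cm),
                      threshold = threshold(res),
                      multiplier = res@multiplier),
    clusters = lapply(seq_along(clusters(res)), function(i)
      list(index = i, seed_overlap = seedOverlaps(res)[i],
           members = clusters(res)[[i]])),
    singletons = singletons(res))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
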