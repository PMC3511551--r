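#' @import methods
NULL

#' AssociationResult: one pairwise association test
#'
#' Container for the result of applying one of the eight association
#' measures to a pair of expression vectors: the statistic, a two-sided
#' p-value for the independence null, the number of paired observations
#' and method-specific extras (e.g. the Theil-Sen intercept or the
#' permutation count used by distance covariance).
#'
#' @slot method Single string, one of [assocMethods()].
#' @slot statistic Numeric statistic on the method's native scale.
#' @slot pValue Two-sided p-value in `[0, 1]`.
#' @slot nObs Integer number of paired observations.
#' @slot extras Named list of method-specific values.
#'
#' @aliases AssociationResult
#' @exportClass AssociationResult
setClass("AssociationResult",
  representation(method = "character", statistic = "numeric",
                 pValue = "numeric", nObs = "integer", extras = "list"),
  validity = function(object) {
    msg <- NULL
    if (length(object@method) != 1L)
      msg <- c(msg, "'method' must be a single string")
    if (length(object@pValue) == 1L &&
        (object@pValue < 0 || object@pValue > 1))
      msg <- c(msg, "'pValue' must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' CoordinationMatrix: TF-by-TF shared-coexpression counts
#'
#' Symmetric integer matrix whose entry (i, j) is the number of genes
#' shared by the top-N coexpression lists of TF i and TF j, stored only
#' when the overlap strictly exceeds `kMin`; all other entries, and the
#' diagonal, are zero.  Interpreted as a graph this is the coordination
#' network of the transcription factors.
#'
#' @slot overlaps Symmetric integer matrix with TF ids as dimnames.
#' @slot nTop Integer, length of the top lists the overlaps came from.
#' @slot kMin Integer, overlaps must exceed this to be stored.
#'
#' @aliases CoordinationMatrix
#' @exportClass CoordinationMatrix
setClass("CoordinationMatrix",
  representation(overlaps = "matrix", nTop = "integer", kMin = "integer"),
  validity = function(object) {
    m <- object@overlaps
    msg <- NULL
    if (nrow(m) != ncol(m)) msg <- c(msg, "'overlaps' must be square")
    if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
      msg <- c(msg, "'overlaps' needs identical row/col TF ids")
    if (nrow(m) > 0L) {
      if (!isTRUE(all.equal(m, t(m)))) msg <- c(msg, "'overlaps' must be symmetric")
      if (any(diag(m) != 0)) msg <- c(msg, "diagonal must be zero")
      nz <- m[m != 0]
      if (length(nz) && (any(nz <= object@kMin) || any(nz > object@nTop)))
        msg <- c(msg, "stored overlaps must satisfy kMin < value <= nTop")
    }
    if (is.null(msg)) TRUE else msg
  })

#' TripleLinkResult: ordered clusters from a coordination network
#'
#' Result of the greedy Triple-Link decomposition: clusters in extraction
#' order (members ordered as joined, the seed pair first), the seed-pair
#' overlap of each cluster, the TFs never placed in any cluster, and the
#' significance threshold used for cluster growth.
#'
#' @slot clusters List of character vectors of TF ids.
#' @slot seedOverlaps Numeric vector, one seed overlap per cluster.
#' @slot singletons Character vector of unclustered TF ids.
#' @slot threshold Numeric significance threshold (mean + multiplier * SD
#'   of the nonzero upper-triangle overlaps).
#' @slot multiplier Numeric SD multiplier used for the threshold.
#'
#' @aliases TripleLinkResult
#' @exportClass TripleLinkResult
setClass("TripleLinkResult",
  representation(clusters = "list", seedOverlaps = "numeric",
                 singletons = "character", threshold = "numeric",
                 multiplier = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@clusters) != length(object@seedOverlaps))
      msg <- c(msg, "one seed overlap per cluster required")
    all_ids <- c(unlist(object@clusters), object@singletons)
    if (anyDuplicated(all_ids))
      msg <- c(msg, "clusters and singletons must partition the TF set")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "AssociationResult", function(object) {
  cat(sprintf("AssociationResult [%s]: statistic = %.6g, p = %.4g, n = %d\n",
              object@method, object@statistic, object@pValue, object@nObs))
  if (length(object@extras))
    cat("  extras:", paste(names(object@extras), collapse = ", "), "\n")
})

setMethod("show", "CoordinationMatrix", function(object) {
  nz <- sum(object@overlaps[upper.tri(object@overlaps)] > 0)
  cat(sprintf("CoordinationMatrix: %d TFs, %d edges (nTop = %d, kMin = %d)\n",
              nrow(object@overlaps), nz, object@nTop, object@kMin))
})

setMethod("show", "TripleLinkResult", function(object) {
  cat(sprintf("TripleLinkResult: %d clusters, %d singletons, threshold = %.4g\n",
              length(object@clusters), length(object@singletons),
              object@threshold))
  k <- min(5L, length(object@clusters))
  for (i in seq_len(k))
    cat(sprintf("  cluster %d (seed overlap %g): %s\n", i,
                object@seedOverlaps[i],
                paste(utils::head(object@clusters[[i]], 8L), collapse = ", ")))
  if (length(object@clusters) > k) cat("  ...\n")
})

#' Accessors for CoexNets S4 objects
#'
#' `statistic()`, `pValue()`, `methodId()` and `nObs()` read the slots of
#' an [AssociationResult-class]; `overlapMatrix()`, `tfIds()`, `nTop()`
#' and `kMin()` read a [CoordinationMatrix-class]; `clusters()`,
#' `singletons()`, `seedOverlaps()` and `threshold()` read a
#' [TripleLinkResult-class].
#'
#' @param x An object of the documented class.
#' @return The slot value.
#' @name accessors
#' @aliases statistic pValue methodId nObs overlapMatrix tfIds nTop kMin
#'   clusters singletons seedOverlaps threshold
NULL

#' @rdname accessors
#' @export
setGeneric("statistic", function(x) standardGeneric("statistic"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("methodId", function(x) standardGeneric("methodId"))
#' @rdname accessors
#' @export
setGeneric("nObs", function(x) standardGeneric("nObs"))
#' @rdname accessors
#' @export
setGeneric("overlapMatrix", function(x) standardGeneric("overlapMatrix"))
#' @rdname accessors
#' @export
setGeneric("tfIds", function(x) standardGeneric("tfIds"))
#' @rdname accessors
#' @export
setGeneric("nTop", function(x) standardGeneric("nTop"))
#' @rdname accessors
#' @export
setGeneric("kMin", function(x) standardGeneric("kMin"))
#' @rdname accessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))
#' @rdname accessors
#' @export
setGeneric("singletons", function(x) standardGeneric("singletons"))
#' @rdname accessors
#' @export
setGeneric("seedOverlaps", function(x) standardGeneric("seedOverlaps"))
#' @rdname accessors
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))

#' @rdname accessors
setMethod("statistic", "AssociationResult", function(x) x@statistic)
#' @rdname accessors
setMethod("pValue", "AssociationResult", function(x) x@pValue)
#' @rdname accessors
setMethod("methodId", "AssociationResult", function(x) x@method)
#' @rdname accessors
setMethod("nObs", "AssociationResult", function(x) x@nObs)
#' @rdname accessors
setMethod("overlapMatrix", "CoordinationMatrix", function(x) x@overlaps)
#' @rdname accessors
setMethod("tfIds", "CoordinationMatrix", function(x) rownames(x@overlaps))
#' @rdname accessors
setMethod("nTop", "CoordinationMatrix", function(x) x@nTop)
#' @rdname accessors
setMethod("kMin", "CoordinationMatrix", function(x) x@kMin)
#' @rdname accessors
setMethod("clusters", "TripleLinkResult", function(x) x@clusters)
#' @rdname accessors
setMethod("singletons", "TripleLinkResult", function(x) x@singletons)
#' @rdname accessors
setMethod("seedOverlaps", "TripleLinkResult", function(x) x@seedOverlaps)
#' @rdname accessors
setMethod("threshold", "TripleLinkResult", function(x) x@threshold)
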