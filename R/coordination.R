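# TF x TF coordination network from top-N coexpression list overlaps

#' Build a TF coordination matrix from top-N lists
#'
#' Two TFs are connected when their top-N most coexpressed gene lists
#' share strictly more than `kMin` genes; the stored edge weight is the
#' overlap count itself, and pairs at or below `kMin` (including exactly
#' `kMin`) get 0.  Lists may include other TFs -- the intersections count
#' them -- but a TF never occurs in its own list, so the diagonal is 0.
#'
#' @param topLists Named list of character vectors, one top-N list per
#'   TF, all built with the same method and the same `nTop`.
#' @param nTop The common top-list length the lists were cut at.  Lists
#'   may be shorter (small genomes) but never longer.
#' @param kMin Minimum overlap; edges require overlap > kMin (strict).
#' @return A [CoordinationMatrix-class].
#' @examples
#' lists <- list(A = c("g1", "g2", "g3"), B = c("g2", "g3", "g4"))
#' buildCoordinationMatrix(lists, nTop = 3, kMin = 1)
#' @export
buildCoordinationMatrix <- function(topLists, nTop = 100L, kMin = 30L) {
  if (is.null(names(topLists)) || anyDuplicated(names(topLists)))
    coexError("topLists must be uniquely named by TF id",
              "configurationError")
  if (kMin >= nTop)
    coexError("kMin must be smaller than nTop", "configurationError")
  lens <- lengths(topLists)
  if (any(lens > nTop))
    coexError("a top list is longer than nTop; lists must share one nTop",
              "configurationError")
  tfs <- names(topLists)
  m <- length(tfs)
  # indicator matrix over the union of listed genes gives all pairwise
  # intersection sizes in one crossproduct
  genes <- unique(unlist(topLists, use.names = FALSE))
  ov <- matrix(0L, m, m, dimnames = list(tfs, tfs))
  if (length(genes) && m > 1L) {
    ind <- matrix(0L, m, length(genes), dimnames = list(tfs, genes))
    for (i in seq_len(m)) ind[i, topLists[[i]]] <- 1L
    cnt <- tcrossprod(ind)
    cnt[cnt <= kMin] <- 0L
    diag(cnt) <- 0L
    ov[] <- as.integer(cnt)
  }
  new("CoordinationMatrix", overlaps = ov,
      nTop = as.integer(nTop), kMin = as.integer(kMin))
}

#' Coordination network straight from an expression matrix
#'
#' Convenience pipeline: ranks partners for every TF with
#' [associateAll()], cuts each list at `nTop` and counts overlaps with
#' [buildCoordinationMatrix()].
#'
#' @param mat Genes x samples expression matrix (TFs are rows too).
#' @param tfs Character vector of TF ids, all present in `mat`.
#' @inheritParams associateAll
#' @inheritParams buildCoordinationMatrix
#' @return A [CoordinationMatrix-class].
#' @export
coordinationFromExpression <- function(mat, tfs, method = "spearman",
                                       nTop = 100L, kMin = 30L,
                                       nPerm = 999L, seed = NULL) {
  mat <- asExprMatrix(mat)
  missing <- setdiff(tfs, rownames(mat))
  if (length(missing))
    coexError(sprintf("TFs not in matrix: %s",
                      paste(utils::head(missing, 5L), collapse = ", ")),
              "lookupError")
  lists <- lapply(tfs, function(tf)
    topN(associateAll(mat, tf, method, nPerm = nPerm, seed = seed), nTop))
  names(lists) <- tfs
  buildCoordinationMatrix(lists, nTop = nTop, kMin = kMin)
}

#' Write / read a coordination matrix
#'
#' `writeCoordinationEdges()` writes the nonzero upper-triangle as a
#' three-column TSV (`tf_a`, `tf_b`, `overlap`); the matching reader
#' needs the full TF id set to restore isolated TFs.
#' `writeCoordinationMatrix()` / `readCoordinationMatrix()` round-trip
#' the full square matrix.  Both formats are lossless.
#'
#' @param cm A [CoordinationMatrix-class].
#' @param path File path.
#' @param tfs For `readCoordinationEdges`: all TF ids (isolated included).
#' @param nTop,kMin Parameters to restore on read.
#' @return The reader returns a [CoordinationMatrix-class]; writers
#'   return `path` invisibly.
#' @name coordinationIO
NULL

#' @rdname coordinationIO
#' @export
writeCoordinationEdges <- function(cm, path) {
  m <- overlapMatrix(cm)
  idx <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  df <- data.frame(tf_a = rownames(m)[idx[, 1]],
                   tf_b = colnames(m)[idx[, 2]],
                   overlap = m[idx],
                   stringsAsFactors = FALSE)
  df <- df[order(df$tf_a, df$tf_b), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname coordinationIO
#' @export
readCoordinationEdges <- function(path, tfs, nTop = 100L, kMin = 30L) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  m <- matrix(0L, length(tfs), length(tfs), dimnames = list(tfs, tfs))
  if (nrow(df)) {
    m[cbind(df$tf_a, df$tf_b)] <- as.integer(df$overlap)
    m[cbind(df$tf_b, df$tf_a)] <- as.integer(df$overlap)
  }
  new("CoordinationMatrix", overlaps = m,
      nTop = as.integer(nTop), kMin = as.integer(kMin))
}

#' @rdname coordinationIO
#' @export
writeCoordinationMatrix <- function(cm, path) {
  m <- overlapMatrix(cm)
  hdr <- paste(c(sprintf("#nTop=%d kMin=%d", nTop(cm), kMin(cm))),
               collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(cbind(tf = rownames(m), as.data.frame(m)), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname coordinationIO
#' @export
readCoordinationMatrix <- function(path) {
  hdr <- readLines(path, n = 1L)
  par <- regmatches(hdr, gregexpr("[0-9]+", hdr))[[1]]
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  new("CoordinationMatrix", overlaps = m,
      nTop = as.integer(par[1]), kMin = as.integer(par[2]))
}
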