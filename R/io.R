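# readers and writers for the tab-delimited interchange formats

#' Read a normalized expression matrix
#'
#' Expects a tab-delimited file with a header row of sample ids and the
#' gene id in the first column; values are log2-scale normalized
#' intensities.  Duplicate gene ids and non-numeric or missing cells are
#' rejected with a parse error naming the offending location.  Gene ids
#' are trimmed of surrounding whitespace but never case-folded (probe
#' and locus id conventions differ by case; silent folding risks false
#' joins).
#'
#' @param path Path to the TSV file.
#' @return Numeric genes x samples matrix with dimnames.
#' @export
readExpressionMatrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L)
    coexError("expression file needs a gene id column plus samples",
              "parseError")
  ids <- trimws(df[[1]])
  if (anyDuplicated(ids))
    coexError(sprintf("duplicate gene id '%s' (line %d)",
                      ids[which(duplicated(ids))[1]],
                      which(duplicated(ids))[1] + 1L),
              "parseError")
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    coexError(sprintf("non-numeric or missing value at line %d, column '%s'",
                      bad[1, 1] + 1L, colnames(df)[bad[1, 2] + 1L]),
              "parseError")
  }
  dimnames(num) <- list(ids, colnames(df)[-1])
  num
}

#' Write an expression matrix as TSV
#'
#' @param mat Genes x samples matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(mat, path) {
  df <- cbind(gene = rownames(mat), as.data.frame(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pathway membership flat file
#'
#' Parses tab-delimited records `pathway_id<TAB>pathway_name<TAB>gene_id`
#' (the layout of AraCyc-style flat-file dumps).  A gene may appear under
#' several pathways; all assignments are kept.  Identifiers are trimmed
#' of surrounding whitespace, case preserved.  Records with an empty
#' gene id are skipped with a warning; lines with fewer than three
#' fields are a parse error.
#'
#' @param path Path to the flat file.
#' @return Named list mapping gene id to a character vector of pathway
#'   ids (the `map` argument of [labelPair()]).
#' @export
readPathwayMap <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty pathway file: returning an empty map")
    return(structure(list(), names = character()))
  }
  # count separators rather than fields so a trailing tab (empty gene id)
  # is distinguishable from a genuinely truncated record
  nTabs <- lengths(gregexpr("\t", lines, fixed = TRUE)) -
    !grepl("\t", lines, fixed = TRUE)
  if (any(nTabs < 2L))
    coexError(sprintf("malformed pathway record at line %d",
                      which(nTabs < 2L)[1]), "parseError")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  pw <- trimws(vapply(parts, `[[`, character(1), 1L))
  gene <- trimws(vapply(parts, function(p)
    if (length(p) >= 3L) p[[3L]] else "", character(1)))
  empty <- !nzchar(gene)
  if (any(empty)) {
    warning(sprintf("skipping %d record(s) with empty gene id", sum(empty)))
    pw <- pw[!empty]; gene <- gene[!empty]
  }
  lapply(split(pw, gene), unique)
}

#' Write / read a ranked pair list
#'
#' The TSV carries `query`, `partner`, `statistic`, `p.value` and `rank`
#' plus a comment header recording the method, so a written list can be
#' read back into an identical object.
#'
#' @param ranked Ranked pair data frame from [associateAll()].
#' @param path File path (a `.gz` suffix writes through a gzip
#'   connection).
#' @return `readRankedPairs()` returns the ranked data frame with its
#'   `query`/`method` attributes restored; the writer returns `path`
#'   invisibly.
#' @name rankedPairsIO
NULL

#' @rdname rankedPairsIO
#' @export
writeRankedPairs <- function(ranked, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#query=%s method=%s", attr(ranked, "query"),
                     attr(ranked, "method")), con)
  out <- data.frame(query = attr(ranked, "query"),
                    partner = ranked$partner,
                    statistic = ranked$statistic,
                    p.value = ranked$p.value,
                    rank = seq_len(nrow(ranked)))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname rankedPairsIO
#' @export
readRankedPairs <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  hdr <- strsplit(sub("^#", "", lines[1]), " ")[[1]]
  meta <- vapply(strsplit(hdr, "="), `[[`, character(1), 2L)
  df <- utils::read.table(text = lines[-1], sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  out <- df[, c("partner", "statistic", "p.value")]
  attr(out, "query") <- meta[1]
  attr(out, "method") <- meta[2]
  out
}

#' Write simulation ground truth as JSON
#'
#' @param truth The `truth` element returned by the simulators.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
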