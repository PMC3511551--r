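# internal helpers shared across modules

# typed condition so callers can distinguish bad data from bad configuration
coexError <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "coexError")))
}

# run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never clobber user state
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

#' Deterministic per-pair seed
#'
#' Derives a reproducible permutation-test seed for a gene pair from a
#' master seed.  The derivation is symmetric in the two identifiers, so
#' the p-value for a pair does not depend on which gene was the query or
#' on the order in which pairs are processed (e.g. under parallel
#' scheduling).
#'
#' @param seed Integer master seed.
#' @param id1,id2 Gene identifiers.
#' @return An integer in `[0, 2^31 - 1)` usable with [set.seed()].
#' @examples
#' pairSeed(1L, "AT1G01010", "AT1G01030") == pairSeed(1L, "AT1G01030", "AT1G01010")
#' @export
pairSeed <- function(seed, id1, id2) {
  ids <- sort(c(as.character(id1), as.character(id2)))
  key <- paste(ids, collapse = "\r")
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# strict lexicographic order on numeric vectors (first differing element
# decides); used to pick a canonical argument independent of call order
vectorBefore <- function(a, b) {
  i <- which(a != b)
  if (length(i) == 0L) return(FALSE)
  a[i[1]] < b[i[1]]
}

# constant-vector test used by several entry points
isConstant <- function(x) {
  length(x) < 2L || max(x) - min(x) == 0
}

checkFinite <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    coexError(sprintf("'%s' must be numeric and finite", name),
              "invalidInputError")
  }
  invisible(x)
}

# sizes of tie groups (only groups of size > 1)
tieSizes <- function(x) {
  tab <- table(x)
  as.integer(tab[tab > 1L])
}
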