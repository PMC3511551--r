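# synthetic expression data with planted pathway blocks and coordinated
# TF groups, emulating the statistical structure of RMA-normalised
# microarray compendia: log2-scale values in roughly [3, 14], monotone
# (possibly nonlinear) within-block dependence, heavy-tailed marginals
# and outliers on demand

#' Simulation configuration
#'
#' Bundles and validates the parameters shared by
#' [simulateExpression()] and [simulateTFCoordination()].
#'
#' @param nGenes Total number of genes (rows).
#' @param nSamples Number of samples (columns); at least 8.
#' @param nPathways Number of planted pathway blocks.
#' @param blockSize Genes per pathway block.
#' @param nTfs Number of transcription factors (TF simulation).
#' @param nTfGroups Number of coordinated TF groups; must divide `nTfs`.
#' @param targetsPerGroup Shared target genes driven by each TF group.
#' @param hkGenes Housekeeping genes tied to a global activity factor;
#'   they provide the broad, weakly shared expression program that real
#'   compendia always contain.
#' @param dependence Link-function family for planted genes:
#'   `"linear"`, `"monotone_nonlinear"` or `"mixed"`.
#' @param noiseSd Gene-level noise SD relative to the unit-variance
#'   latent factors.
#' @param outlierRate Per-cell probability of replacing a value with a
#'   +/- 6 SD spike.
#' @param marginal Marginal shape: `"normal"`, `"lognormal"` (values are
#'   exponentiated, a strictly monotone map, so rank-based dependence is
#'   untouched while Shapiro-Wilk rejects), or `"mixed"` (half the
#'   genes each).
#' @param seed Integer seed; identical configurations give identical
#'   matrices.
#' @return A validated list of class `"SimulationConfig"`.
#' @export
simConfig <- function(nGenes = 1000L, nSamples = 60L, nPathways = 10L,
                      blockSize = 12L, nTfs = 40L, nTfGroups = 5L,
                      targetsPerGroup = 40L, hkGenes = 60L,
                      dependence = c("monotone_nonlinear", "linear", "mixed"),
                      noiseSd = 0.5, outlierRate = 0,
                      marginal = c("normal", "lognormal", "mixed"),
                      seed = 1L) {
  dependence <- match.arg(dependence)
  marginal <- match.arg(marginal)
  cfg <- list(nGenes = as.integer(nGenes), nSamples = as.integer(nSamples),
              nPathways = as.integer(nPathways),
              blockSize = as.integer(blockSize), nTfs = as.integer(nTfs),
              nTfGroups = as.integer(nTfGroups),
              targetsPerGroup = as.integer(targetsPerGroup),
              hkGenes = as.integer(hkGenes), dependence = dependence,
              noiseSd = noiseSd, outlierRate = outlierRate,
              marginal = marginal, seed = as.integer(seed))
  counts <- unlist(cfg[c("nGenes", "nSamples", "nPathways", "blockSize",
                         "nTfs", "nTfGroups", "targetsPerGroup")])
  if (any(counts <= 0))
    coexError("all counts must be positive", "configurationError")
  if (cfg$nSamples < 8L)
    coexError("nSamples must be at least 8", "configurationError")
  if (noiseSd < 0)
    coexError("noiseSd must be non-negative", "configurationError")
  if (outlierRate < 0 || outlierRate >= 1)
    coexError("outlierRate must lie in [0, 1)", "configurationError")
  if (cfg$nPathways * cfg$blockSize > cfg$nGenes)
    coexError("blockSize * nPathways exceeds nGenes", "configurationError")
  if (cfg$nTfs %% cfg$nTfGroups != 0L)
    coexError("nTfGroups must divide nTfs", "configurationError")
  if (cfg$nTfs + cfg$nTfGroups * cfg$targetsPerGroup + cfg$hkGenes >
      cfg$nGenes)
    coexError("TFs + targets + housekeeping genes exceed nGenes",
              "configurationError")
  class(cfg) <- "SimulationConfig"
  cfg
}

# strictly increasing link functions; output is standardised afterwards,
# so only the shape matters
linkFun <- function(kind) {
  pool <- switch(kind,
    linear = list(identity),
    monotone_nonlinear = list(function(z) z^3,
                              function(z) sinh(z),
                              function(z) exp(z),
                              function(z) sign(z) * sqrt(abs(z))),
    mixed = list(identity, function(z) z^3, function(z) sinh(z),
                 function(z) exp(z)))
  pool[[sample.int(length(pool), 1L)]]
}

standardise <- function(v) {
  s <- stats::sd(v)
  if (s == 0) v - mean(v) else (v - mean(v)) / s
}

injectOutliers <- function(m, rate) {
  if (rate <= 0) return(m)
  for (i in seq_len(nrow(m))) {
    hit <- stats::runif(ncol(m)) < rate
    if (any(hit)) {
      s <- stats::sd(m[i, ]); if (s == 0) s <- 1
      m[i, hit] <- mean(m[i, ]) +
        sample(c(-6, 6), sum(hit), replace = TRUE) * s
    }
  }
  m
}

applyMarginal <- function(m, marginal) {
  if (marginal == "normal") return(m)
  rows <- if (marginal == "lognormal") seq_len(nrow(m)) else
    sample.int(nrow(m), floor(nrow(m) / 2))
  m[rows, ] <- exp(m[rows, , drop = FALSE])
  m
}

# affine map of the whole matrix into the log2 intensity range [3, 14];
# a single global map leaves every pairwise association unchanged
toLog2Range <- function(m, lo = 3, hi = 14) {
  rng <- range(m)
  if (rng[2] == rng[1]) return(matrix(lo, nrow(m), ncol(m),
                                      dimnames = dimnames(m)))
  lo + (hi - lo) * (m - rng[1]) / (rng[2] - rng[1])
}

#' Simulate an expression matrix with planted pathway blocks
#'
#' Each pathway block shares one latent factor: gene values are strictly
#' monotone link functions of the factor plus independent noise, then
#' optional outlier spikes and marginal transforms, and finally a global
#' affine map into the 3-14 log2-intensity range.  Genes outside the
#' blocks are independent noise, so cross-block associations are
#' centered at zero by construction.
#'
#' @param config A [simConfig()] object.
#' @return List with `matrix` (genes x samples, dimnames set), `truth`
#'   (pathway map as named list gene -> pathway id, block index per
#'   gene) and `config`.
#' @export
simulateExpression <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  withSeed(config$seed, {
    nG <- config$nGenes; nS <- config$nSamples
    genes <- sprintf("G%04d", seq_len(nG))
    samples <- sprintf("S%03d", seq_len(nS))
    m <- matrix(stats::rnorm(nG * nS), nG, nS,
                dimnames = list(genes, samples))
    block <- rep(NA_integer_, nG)
    for (b in seq_len(config$nPathways)) {
      f <- stats::rnorm(nS)
      idx <- ((b - 1L) * config$blockSize + 1L):(b * config$blockSize)
      block[idx] <- b
      for (i in idx) {
        link <- linkFun(config$dependence)
        m[i, ] <- standardise(link(f)) + config$noiseSd * stats::rnorm(nS)
      }
    }
    m <- injectOutliers(m, config$outlierRate)
    m <- applyMarginal(m, config$marginal)
    m <- toLog2Range(m)
    pw <- sprintf("PWY%03d", block[!is.na(block)])
    pathwayMap <- split(rep(pw, 1L), genes[!is.na(block)])
    pathwayMap <- lapply(pathwayMap, unique)
    list(matrix = m,
         truth = list(pathwayMap = pathwayMap,
                      block = stats::setNames(block, genes)),
         config = config)
  })
}

#' Simulate coordinated TF groups with shared target programs
#'
#' Plants `nTfGroups` groups of TFs on mutually orthogonal latent
#' activity factors.  Every TF in a group is a strictly monotone link of
#' the group factor; the group's `targetsPerGroup` target genes follow
#' the same factor, so at low noise the top coexpression lists of
#' same-group TFs coincide and their overlaps exceed any practical
#' `kMin`, while between-group overlaps stay near zero.  TFs also load
#' on a global activity factor in proportion to the noise level, and a
#' block of housekeeping genes follows that global factor: at realistic
#' noise this reproduces the many weak TF-TF edges real coordination
#' networks contain (which is what keeps the Triple-Link significance
#' threshold well below the within-group overlaps).  The remaining genes
#' are independent noise.
#'
#' @param config A [simConfig()] object.
#' @return List with `matrix`, `truth` (named integer vector `tfGroup`,
#'   list `targets` per group, housekeeping ids) and `config`.
#' @export
simulateTFCoordination <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  withSeed(config$seed, {
    nS <- config$nSamples; nG <- config$nGenes
    g <- config$nTfGroups
    tfsPer <- config$nTfs %/% g
    if (nS < g + 3L)
      coexError("nSamples too small for the requested group count",
                "configurationError")
    # centered, mutually orthogonal unit-variance factors: columns of the
    # QR basis of [1 | raw factors], intercept dropped
    raw <- matrix(stats::rnorm(nS * (g + 1L)), nS)
    qb <- qr.Q(qr(cbind(1, raw)))[, -1, drop = FALSE]
    fac <- apply(qb, 2, standardise)
    fGroup <- fac[, seq_len(g), drop = FALSE]
    f0 <- fac[, g + 1L]

    tfIds <- sprintf("TF%03d", seq_len(config$nTfs))
    tgIds <- sprintf("TG%04d", seq_len(g * config$targetsPerGroup))
    hkIds <- sprintf("HK%03d", seq_len(config$hkGenes))
    nBg <- nG - length(tfIds) - length(tgIds) - length(hkIds)
    bgIds <- sprintf("BG%04d", seq_len(nBg))
    genes <- c(tfIds, tgIds, hkIds, bgIds)
    m <- matrix(stats::rnorm(nG * nS), nG, nS,
                dimnames = list(genes, sprintf("S%03d", seq_len(nS))))

    tfGroup <- rep(seq_len(g), each = tfsPer)
    for (t in seq_len(config$nTfs)) {
      a <- stats::runif(1, 1.2, 2)        # global-factor participation
      u <- fGroup[, tfGroup[t]] +
        config$noiseSd * (a * f0 + stats::rnorm(nS))
      m[tfIds[t], ] <- standardise(linkFun(config$dependence)(standardise(u)))
    }
    tgGroup <- rep(seq_len(g), each = config$targetsPerGroup)
    for (j in seq_along(tgIds)) {
      u <- fGroup[, tgGroup[j]] + config$noiseSd * stats::rnorm(nS)
      m[tgIds[j], ] <- standardise(linkFun(config$dependence)(standardise(u)))
    }
    for (j in seq_along(hkIds)) {
      u <- sqrt(0.9) * f0 + sqrt(0.1) * stats::rnorm(nS)
      m[hkIds[j], ] <- standardise(linkFun(config$dependence)(standardise(u)))
    }
    m <- injectOutliers(m, config$outlierRate)
    m <- applyMarginal(m, config$marginal)
    m <- toLog2Range(m)
    list(matrix = m,
         truth = list(tfGroup = stats::setNames(tfGroup, tfIds),
                      targets = split(tgIds, tgGroup),
                      housekeeping = hkIds),
         config = config)
  })
}
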