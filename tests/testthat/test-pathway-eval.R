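toyMap <- list(g1 = "P1", g2 = "P1", g3 = c("P1", "P2"), g4 = "P2",
               g5 = "P3")

test_that("pair labels are exhaustive and follow the S/D/N definitions", {
  expect_equal(labelPair("g1", "g2", toyMap), "S")   # share P1
  expect_equal(labelPair("g1", "g4", toyMap), "D")   # P1 vs P2 only
  expect_equal(labelPair("g1", "u1", toyMap), "N")   # unassigned partner
  expect_equal(labelPair("g3", "g4", toyMap), "S")   # multi-assignment
  expect_error(labelPair("g1", "g1", toyMap), class = "invalidPairError")
  set.seed(51)
  genes <- c(names(toyMap), paste0("u", 1:3))
  for (i in 1:30) {
    pr <- sample(genes, 2)
    expect_true(labelPair(pr[1], pr[2], toyMap) %in% c("S", "D", "N"))
  }
})

test_that("top counts conserve the cutoff and warn on short lists", {
  expect_equal(topCounts(rep("S", 100), 100), c(S = 100, D = 0, N = 0))
  expect_equal(topCounts(rep(c("S", "D"), 50), 100), c(S = 50, D = 50, N = 0))
  labels <- c("S", "S", "D", "N", "S", "D", "N", "N", "S", "D")
  expect_equal(topCounts(labels, 10), c(S = 4, D = 3, N = 3))
  expect_equal(sum(topCounts(labels, 10)), 10)
  expect_warning(cnt <- topCounts(labels, 20), "only 10")
  expect_equal(sum(cnt), 10)
})

test_that("slice confusion applies the divide-by-nine rule for the
           top-100 comparison", {
  # top 100 with 20 target pairs; 'next' slice (101-1000) with 90:
  # TP=20, FP=80, FN=10, TN=90 after /9; sensitivity 20/30
  labels <- c(rep("S", 20), rep("D", 80),
              rep("S", 90), rep("D", 810))
  cc <- sliceConfusion(labels, 100, "next", "S")
  expect_equal(cc$tp, 20); expect_equal(cc$fp, 80)
  expect_equal(cc$fn, 10); expect_equal(cc$tn, 90)
  expect_equal(cc$sensitivity, 20 / 30)
  expect_equal(cc$specificity, 90 / 170)
  expect_equal(cc$accuracy, 110 / 200)
  # perfect separation
  perfect <- c(rep("S", 100), rep("D", 900))
  pc <- sliceConfusion(perfect, 100, "next", "S")
  expect_equal(pc$sensitivity, 1)
  expect_equal(pc$specificity, 1)
})

test_that("top-500 slices hold 500 pairs and are used unrescaled", {
  labels <- c(rep("S", 150), rep("D", 350),    # top 500: 150 S
              rep("S", 50), rep("D", 450))     # next 500: 50 S
  cc <- sliceConfusion(labels, 500, "next", "S")
  expect_equal(cc$tp, 150); expect_equal(cc$fp, 350)
  expect_equal(cc$fn, 50); expect_equal(cc$tn, 450)
  expect_equal(cc$sensitivity, 150 / 200)
})

test_that("middle slice is centred on the list midpoint and bottom slice
           is the tail", {
  L <- 3000
  labels <- rep("D", L)
  midStart <- floor((L - 900) / 2) + 1
  labels[midStart:(midStart + 899)] <- "S"
  cc <- sliceConfusion(labels, 100, "middle", "S")
  expect_equal(cc$fn, 100)                     # all 900, rescaled by 9
  expect_equal(cc$tn, 0)
  bottom <- rep("D", L); bottom[(L - 899):L] <- "S"
  cb <- sliceConfusion(bottom, 100, "bottom", "S")
  expect_equal(cb$fn, 100)
  expect_error(sliceConfusion(rep("S", 500), 100, "next", "S"),
               class = "sliceError")
  expect_error(sliceConfusion(rep("S", 50), 100, "next", "S"),
               class = "sliceError")
})

test_that("undefined confusion ratios surface as NA, not zero", {
  labels <- c(rep("D", 100), rep("D", 900))    # no target pairs anywhere
  cc <- sliceConfusion(labels, 100, "next", "S")
  expect_true(is.na(cc$sensitivity))           # tp + fn == 0
  expect_equal(cc$specificity, 100 / 200)
})

test_that("p-value cutoff fractions count same-pathway pairs among the
           retained", {
  labels <- c(rep("S", 3), rep("D", 4), rep("N", 3))
  p <- seq(1e-8, 1e-2, length.out = 10)
  res <- pvalueCutoffFraction(labels, p, 0.5)
  expect_equal(res$fraction_same_pathway, 0.3)
  expect_equal(res$n_pairs, 10)
  none <- pvalueCutoffFraction(labels, p, 1e-12)
  expect_equal(none$fraction_same_pathway, 0)
  expect_equal(none$n_pairs, 0)
  straddle <- pvalueCutoffFraction(c("S", "S", "D", "N"),
                                   c(1e-7, 1e-6, 1e-6, 1e-3), 1e-5)
  expect_equal(straddle$n_pairs, 3)
  expect_equal(straddle$fraction_same_pathway, 2 / 3)
  expect_error(pvalueCutoffFraction(labels, p, 0),
               class = "configurationError")
})

test_that("unordered pairs deduplicate by sorted gene-id key", {
  df <- data.frame(gene1 = c("a", "b", "c", "a"),
                   gene2 = c("b", "a", "d", "c"),
                   p = c(1e-8, 1e-6, 1e-5, 1e-4))
  out <- dedupePairs(df)
  expect_equal(nrow(out), 3)
  expect_equal(out$p[1], 1e-8)       # first (most significant) kept
})

test_that("on planted pathway blocks the top pairs are dominated by
           same-pathway genes", {
  cfg <- simConfig(nGenes = 200, nSamples = 40, nPathways = 5,
                   blockSize = 10, nTfs = 2, nTfGroups = 1,
                   targetsPerGroup = 2, hkGenes = 2, seed = 77)
  sim <- simulateExpression(cfg)
  map <- sim$truth$pathwayMap
  queries <- names(map)                          # every pathway gene
  pooled <- do.call(rbind, lapply(queries, function(q) {
    ranked <- associateAll(sim$matrix, q, "spearman")
    data.frame(gene1 = q, gene2 = ranked$partner, p = ranked$p.value)
  }))
  pooled <- dedupePairs(pooled[order(pooled$p), ])
  labels <- labelPairs(pooled, map)$label
  counts <- topCounts(labels, 100)
  expect_gt(counts[["S"]], counts[["N"]])
  expect_equal(sum(counts), 100)
})

test_that("cluster positive-gene statistics count per set and pool for
           percentages", {
  res <- new("TripleLinkResult",
             clusters = list(sprintf("T%02d", 1:10), c("X1", "X2")),
             seedOverlaps = c(90, 50), singletons = character(),
             threshold = 40, multiplier = 1)
  pos <- list(rootHair = sprintf("T%02d", 1:4),
              rootCap = c("T04", "X9"))      # T04 shared by both sets
  st <- clusterPositiveStats(res, pos)
  expect_equal(st$n_positive[1], 4)
  expect_equal(st$percent_positive[1], 40)
  expect_equal(st$rootHair[1], 4)
  expect_equal(st$rootCap[1], 1)             # reported per set, overlap kept
  expect_equal(st$n_positive[2], 0)
  empty <- clusterPositiveStats(res, list(none = character()))
  expect_equal(empty$n_positive, c(0, 0))
})
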