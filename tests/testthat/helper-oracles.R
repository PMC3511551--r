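# brute-force enumeration oracles, written from the definitions with
# explicit loops; deliberately independent of the package's vectorised
# implementations

oraclePearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

oracleRank <- function(x) {
  # average-of-positions tie rule from first principles
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- sum(x < x[i]); eq <- sum(x == x[i])
    r[i] <- less + (eq + 1) / 2
  }
  r
}

oracleSpearman <- function(x, y) {
  oraclePearson(oracleRank(x), oracleRank(y))
}

oracleKendall <- function(x, y) {
  n <- length(x)
  C <- D <- tiesX <- tiesY <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    if (dx == 0 && dy == 0) { tiesX <- tiesX + 1; tiesY <- tiesY + 1 }
    else if (dx == 0) tiesX <- tiesX + 1
    else if (dy == 0) tiesY <- tiesY + 1
    else if (dx * dy > 0) C <- C + 1
    else D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tiesX) * (n0 - tiesY))
}

oracleWeightedRank <- function(x, y) {
  R <- oracleRank(x); S <- oracleRank(y)
  n <- length(x)
  acc <- 0
  for (i in seq_len(n))
    acc <- acc + (R[i] - S[i])^2 * ((n - R[i] + 1) + (n - S[i] + 1))
  1 - 6 * acc / (n^4 + n^3 - n^2 - n)
}

oracleHoeffding <- function(x, y) {
  n <- length(x)
  R <- oracleRank(x); S <- oracleRank(y)
  Q <- numeric(n)
  for (i in seq_len(n)) {
    q <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      cx <- if (x[j] < x[i]) 1 else if (x[j] == x[i]) 0.5 else 0
      cy <- if (y[j] < y[i]) 1 else if (y[j] == y[i]) 0.5 else 0
      q <- q + cx * cy
    }
    Q[i] <- q
  }
  D1 <- sum(Q * (Q - 1))
  D2 <- sum((R - 1) * (R - 2) * (S - 1) * (S - 2))
  D3 <- sum((R - 2) * (S - 2) * Q)
  30 * ((n - 2) * (n - 3) * D1 + D2 - 2 * (n - 2) * D3) /
    (n * (n - 1) * (n - 2) * (n - 3) * (n - 4))
}

oracleDcov2 <- function(x, y) {
  n <- length(x)
  a <- outer(x, x, function(u, v) abs(u - v))
  b <- outer(y, y, function(u, v) abs(u - v))
  A <- matrix(0, n, n); B <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    A[i, j] <- a[i, j] - mean(a[i, ]) - mean(a[, j]) + mean(a)
    B[i, j] <- b[i, j] - mean(b[i, ]) - mean(b[, j]) + mean(b)
  }
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + A[i, j] * B[i, j]
  s / n^2
}

oracleTheilSen <- function(x, y) {
  slopes <- c()
  n <- length(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (x[j] != x[i]) slopes <- c(slopes, (y[j] - y[i]) / (x[j] - x[i]))
  sorted <- sort(slopes)
  k <- length(sorted)
  if (k %% 2 == 1) sorted[(k + 1) / 2]
  else (sorted[k / 2] + sorted[k / 2 + 1]) / 2
}

oracleStat <- function(method, x, y) {
  switch(method,
    pearson = oraclePearson(x, y),
    spearman = oracleSpearman(x, y),
    kendall = oracleKendall(x, y),
    weighted_rank = oracleWeightedRank(x, y),
    hoeffding = oracleHoeffding(x, y),
    dcov = oracleDcov2(x, y),
    theil_sen = oracleTheilSen(x, y),
    rank_theil_sen = oracleTheilSen(oracleRank(x), oracleRank(y)))
}

# all permutations of 1..n (small n only)
allPerms <- function(n) {
  if (n == 1) return(matrix(1))
  p <- allPerms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) cbind(i, p + (p >= i))))
}

clusterLabels <- function(res, tfs) {
  lab <- rep(0L, length(tfs))
  names(lab) <- tfs
  for (i in seq_along(clusters(res))) lab[clusters(res)[[i]]] <- i
  lab
}
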