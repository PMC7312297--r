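# Independent brute-force oracles, deliberately naive: each re-derives an
# expected result by direct enumeration or elementwise loops, sharing no
# code with the implementation it checks.

## direct O(n^2 k^2) 2D convolution with symmetric padding
oracleConvolve2d <- function(m, g) {
  half <- (length(g) - 1L) %/% 2L
  k2 <- outer(g, g)
  n1 <- nrow(m); n2 <- ncol(m)
  reflect <- function(i, n) {
    while (i < 1L || i > n) {
      if (i < 1L) i <- 1L - i
      if (i > n) i <- 2L * n + 1L - i
    }
    i
  }
  out <- matrix(0, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    acc <- 0
    for (di in -half:half) for (dj in -half:half)
      acc <- acc + k2[di + half + 1L, dj + half + 1L] *
        m[reflect(i + di, n1), reflect(j + dj, n2)]
    out[i, j] <- acc
  }
  out
}

## per-column linear scan for the first value strictly above frac * max
oracleFirstCrossing <- function(column, frac) {
  thr <- frac * max(column)
  for (z in seq_along(column)) if (column[z] > thr) return(z)
  NA_integer_
}

## exhaustive minimum within-cluster sum of squares over all 2-partitions
## of a 1-D intensity set (optimal 1-D clusters are contiguous in sorted
## order, but enumerate every split anyway for independence)
oracleBestTwoPartition <- function(v) {
  n <- length(v)
  best <- Inf
  bestAssign <- NULL
  for (code in 1:(2^n - 2)) {
    a <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    w <- sum((v[a] - mean(v[a]))^2) + sum((v[!a] - mean(v[!a]))^2)
    if (w < best - 1e-12) {
      best <- w
      bestAssign <- a
    }
  }
  list(wcss = best, assign = bestAssign)
}

## one-way ANOVA F from hand-computed sums of squares
oracleAnovaF <- function(values, groups) {
  groups <- factor(groups)
  gm <- mean(values)
  ssb <- sum(tapply(values, groups, function(x) length(x) * (mean(x) - gm)^2))
  ssw <- sum(unlist(tapply(values, groups, function(x) (x - mean(x))^2)))
  dfb <- nlevels(groups) - 1
  dfw <- length(values) - nlevels(groups)
  (ssb / dfb) / (ssw / dfw)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)
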