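# Independent brute-force oracles used to validate the exact tests and the
# Ward agglomeration, plus small fixture builders.

# Brute-force Ward agglomeration: at every step recompute the delta-SSE of
# merging every pair of clusters directly from the raw points, pick the
# minimum (ties by lexicographic smallest-leaf pair), and record the merged
# leaf sets and heights.
bruteWard <- function(X) {
  n <- nrow(X)
  clusters <- lapply(seq_len(n), identity)  # leaf index sets
  merges <- list()
  heights <- numeric()
  deltaSSE <- function(a, b) {
    ca <- colMeans(X[a, , drop = FALSE])
    cb <- colMeans(X[b, , drop = FALSE])
    length(a) * length(b) / (length(a) + length(b)) * sum((ca - cb)^2)
  }
  while (length(clusters) > 1L) {
    best <- NULL; bestD <- Inf; bestKey <- c(Inf, Inf)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      d <- deltaSSE(clusters[[i]], clusters[[j]])
      key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
      tol <- 1e-12 * max(1, abs(bestD))
      if (d < bestD - tol ||
          (abs(d - bestD) <= tol &&
           (key[1] < bestKey[1] ||
            (key[1] == bestKey[1] && key[2] < bestKey[2])))) {
        best <- c(i, j); bestD <- d; bestKey <- key
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1L]] <- merged
    heights <- c(heights, bestD)
    clusters <- c(clusters[-best], list(merged))
  }
  list(merges = merges, heights = heights)
}

# Leaf sets per merge of a WardDendrogram, for oracle comparison.
dendroMergeSets <- function(dendro) {
  m <- dendro@merge
  sets <- vector("list", nrow(m))
  leavesOf <- function(k) if (k < 0) -k else sets[[k]]
  for (i in seq_len(nrow(m)))
    sets[[i]] <- sort(c(leavesOf(m[i, 1]), leavesOf(m[i, 2])))
  sets
}

# Exact two-sided Mann-Whitney p by direct enumeration of group splits,
# computing U by pair counting (not the rank-sum formula).
mwuOracle <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  uOf <- function(xi, yi) sum(outer(xi, yi, ">")) + 0.5 * sum(outer(xi, yi, "=="))
  uObs <- uOf(x, y)
  splits <- combn(length(pooled), nx)
  us <- apply(splits, 2, function(ix) uOf(pooled[ix], pooled[-ix]))
  pLo <- mean(us <= uObs + 1e-9)
  pHi <- mean(us >= uObs - 1e-9)
  min(1, 2 * min(pLo, pHi))
}

# Two-sided Fisher 2x2 p by explicit enumeration over the free cell with
# choose()-based probabilities.
fisher2x2Oracle <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  prob <- sapply(ks, function(k)
    choose(c1, k) * choose(n - c1, r1 - k) / choose(n, r1))
  pObs <- prob[ks == m[1, 1]]
  min(1, sum(prob[prob <= pObs * (1 + 1e-7)]))
}

# RxC exact p by enumeration over the free (R-1)x(C-1) cells (2-column
# tables only), with factorial-product probabilities.
fisherRxCOracle <- function(m) {
  stopifnot(ncol(m) == 2L)
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  lp <- function(tab) sum(lfactorial(rs)) + sum(lfactorial(cs)) -
    lfactorial(n) - sum(lfactorial(tab))
  lpObs <- lp(m)
  R <- nrow(m)
  grid <- do.call(expand.grid, lapply(seq_len(R), function(i) 0:rs[i]))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    col1 <- as.numeric(grid[g, ])
    if (sum(col1) != cs[1]) next
    tab <- cbind(col1, rs - col1)
    if (any(tab < 0)) next
    l <- lp(tab)
    if (l <= lpObs + 1e-7) total <- total + exp(l)
  }
  min(1, total)
}

# Rasterized disk mask (pixel centers within radius r of the center).
diskMask <- function(n, centerRow, centerCol, r) {
  outer((seq_len(n) - centerRow)^2, (seq_len(n) - centerCol)^2, "+") <= r^2
}

# Small deterministic cohort matrix for index tests: 10-gene default index
# panel x 8 subjects, constructed so subject ranks are explicit.
indexFixtureMatrix <- function() {
  panel <- defaultIndexPanel()
  genes <- panelEntries(panel)$symbol
  m <- matrix(0, length(genes), 8,
              dimnames = list(genes, paste0("s", 1:8)))
  for (g in seq_along(genes)) m[g, ] <- seq(1, 8)  # s8 highest everywhere
  m
}

adjustedRand <- function(a, b) mclust::adjustedRandIndex(a, b)
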