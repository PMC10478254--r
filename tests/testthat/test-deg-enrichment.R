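grpFixture <- function(n1, n2) {
  g <- c(rep("A", n1), rep("B", n2))
  names(g) <- paste0("s", seq_len(n1 + n2))
  g
}

test_that("differential expression computes pooled t on log2(CPM + 1)", {
  set.seed(601)
  n1 <- 40; n2 <- 40
  m <- rbind(
    hi = c(abs(rnorm(n1, 8, 0.01)), abs(rnorm(n2, 2, 0.01))),
    flat = abs(rnorm(n1 + n2, 5, 1)),
    const = rep(3, n1 + n2))
  colnames(m) <- paste0("s", seq_len(n1 + n2))
  g <- grpFixture(n1, n2)
  expect_message(deg <- differentialExpression(m, g), "zero variance")
  expect_equal(attr(deg, "nExcluded"), 1L)
  expect_false("const" %in% deg$gene)
  # group means 8 and 2 CPM -> log2fc ~ log2(9/3)
  expect_equal(deg$log2fc[deg$gene == "hi"], log2(9 / 3), tolerance = 0.01)
  # per-gene agreement with the scalar pooled t-test
  ref <- studentT(log2(m["flat", 1:n1] + 1), log2(m["flat", -(1:n1)] + 1))
  expect_equal(deg$t[deg$gene == "flat"], ref$statistic, tolerance = 1e-10)
  expect_equal(deg$p[deg$gene == "flat"], ref$p.value, tolerance = 1e-10)
  expect_error(differentialExpression(m, g[c(1, 41)]), "at least 2")
})

test_that("top-N selection is deterministic under ties and boundary sizes", {
  rec <- data.frame(gene = c("b", "a", "c", "d"),
                    t = c(2, -2, 1, 3),
                    p = c(0.01, 0.01, 0.5, 0.001),
                    log2fc = c(1, -1, 0.2, 2))
  expect_equal(topGenes(rec, 3), c("d", "a", "b"))  # tie at p=0.01: |t| equal, id order
  expect_equal(topGenes(rec, 10), c("d", "a", "b", "c"))
  shuffled <- rec[c(3, 1, 4, 2), ]
  expect_equal(topGenes(shuffled, 3), topGenes(rec, 3))
  expect_error(topGenes(rec[0, ], 3), "no DEG")
})

test_that("overrepresentation matches the direct hypergeometric sum", {
  universe <- paste0("g", 1:100)
  lst <- paste0("g", 1:10)
  sets <- GeneSetList(list(S = c(paste0("g", 6:10), paste0("g", 50:54))))
  res <- overrepresentation(lst, sets, universe)
  manual <- sum(sapply(5:10, function(k)
    choose(10, k) * choose(90, 10 - k) / choose(100, 10)))
  expect_equal(res$p, manual, tolerance = 1e-12)
  expect_equal(res$overlap, 5L)

  # overlap 0 with set = list = universe is impossible; a disjoint-set
  # degenerate case instead: overlap 0 over the whole universe -> p = 1
  all3 <- GeneSetList(list(S = universe))
  expect_equal(overrepresentation(universe, all3, universe)$p, 1)

  expect_error(overrepresentation(c(lst, "zzz"), sets, universe),
               "not contained")
})

test_that("overrepresentation is permutation invariant and monotone in overlap", {
  set.seed(602)
  universe <- paste0("g", 1:200)
  lst <- sample(universe, 30)
  sets <- GeneSetList(list(A = sample(universe, 15),
                           B = sample(universe, 25),
                           C = sample(universe, 10)))
  res <- overrepresentation(lst, sets, universe)
  resPerm <- overrepresentation(sample(lst),
                                GeneSetList(geneSets(sets)[c(2, 3, 1)]),
                                sample(universe))
  expect_equal(res[order(res$set), c("set", "p")],
               resPerm[order(resPerm$set), c("set", "p")])

  # decreasing overlap at fixed margins never decreases p
  p <- sapply(0:10, function(ov)
    phyper(ov - 1, 20, 180, 30, lower.tail = FALSE))
  expect_true(all(diff(p) <= 1e-15))
})

test_that("planted differentially expressed genes rank ahead of background", {
  wins <- 0L
  for (s in 1:5) {
    cs <- simulateCohort(nControlHigh = 0, nControlLow = 0,
                         nBackgroundGenes = 500, seed = 700 + s)
    grp <- cs$truth$group[cs$truth$group %in% c("HSR_SZ", "LSR_SZ")]
    deg <- differentialExpression(cs$experiment[, names(grp)], grp)
    planted <- cs$truth$plantedGenes
    rk <- rank(deg$p)[match(planted, deg$gene)]
    bg <- setdiff(cs$truth$backgroundGenes, planted)
    if (median(rk) < median(rank(deg$p)[match(bg, deg$gene)]))
      wins <- wins + 1L
  }
  expect_equal(wins, 5L)
})

test_that("the planted set is recovered end to end through ORA", {
  cs <- simulateCohort(seed = 606)
  grp <- cs$truth$group[cs$truth$group %in% c("HSR_SZ", "LSR_SZ")]
  deg <- differentialExpression(cs$experiment[, names(grp)], grp)
  top <- topGenes(deg, 200)
  gs <- simulateGeneSets(cs$truth, nDecoySets = 20, decoySize = 7, seed = 607)
  res <- overrepresentation(top, gs, deg$gene, deg)
  expect_equal(res$set[1], cs$truth$plantedSetName)
  expect_lt(res$p[1], 0.001)
  # direction annotation carries a sign per overlapping gene
  expect_match(res$overlapGenes[1], "[+-]")
})
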