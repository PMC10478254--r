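test_that("cohort generation is deterministic under a fixed seed", {
  a <- simulateCohort(nBackgroundGenes = 50, seed = 11)
  b <- simulateCohort(nBackgroundGenes = 50, seed = 11)
  expect_identical(cpmValues(a$experiment), cpmValues(b$experiment))
  expect_identical(a$truth, b$truth)
  expect_identical(sampleMetadata(a$experiment), sampleMetadata(b$experiment))
  c <- simulateCohort(nBackgroundGenes = 50, seed = 12)
  expect_false(identical(cpmValues(a$experiment), cpmValues(c$experiment)))
})

test_that("the dispersion -> 0 limit collapses to the Poisson floor", {
  pe <- data.frame(gene = "X", meanHSR = 10, meanLSR = 10,
                   meanContHigh = NA, meanContLow = NA)
  cs <- simulateCohort(nHSR = 20, nLSR = 20, nControlHigh = 0,
                       nControlLow = 0, nBackgroundGenes = 0,
                       panelEffects = pe, nbDispersion = 0,
                       librarySizeCV = 0, plantedSetSize = 0, seed = 5)
  v <- cpmValues(cs$experiment)["X", ]
  # counts ~ Poisson(466) at 46.6M reads -> CPM relative sd ~ 4.6%
  expect_equal(mean(v), 10, tolerance = 0.05)
  expect_lt(sd(v) / mean(v), 0.1)
})

test_that("panel-gene group means converge to their specified targets", {
  # Monte-Carlo check of the generator against its own targets: latent-HSR
  # mean of IL6 should approach 0.77 CPM (and LSR 0.38) over 200 seeds.
  hsrMeans <- numeric(200); lsrMeans <- numeric(200)
  for (s in seq_len(200)) {
    cs <- simulateCohort(nControlHigh = 0, nControlLow = 0,
                         nBackgroundGenes = 0, plantedSetSize = 0, seed = s)
    v <- cpmValues(cs$experiment)["IL6", ]
    g <- cs$truth$group
    hsrMeans[s] <- mean(v[g == "HSR_SZ"])
    lsrMeans[s] <- mean(v[g == "LSR_SZ"])
  }
  expect_lt(abs(mean(hsrMeans) - 0.77) / 0.77, 0.05)
  expect_lt(abs(mean(lsrMeans) - 0.38) / 0.38, 0.05)
})

test_that("cohort structure matches the requested design", {
  cs <- simulateCohort(nBackgroundGenes = 100, seed = 3)
  se <- cs$experiment
  md <- sampleMetadata(se)
  expect_equal(sum(md$diagnosis == "SZ"), 25L)
  expect_equal(sum(md$diagnosis == "CONTROL"), 21L)
  expect_equal(as.integer(table(cs$truth$group)[c("HSR_SZ", "LSR_SZ")]),
               c(7L, 18L))
  expect_equal(as.integer(table(cs$truth$group)[c("CONT_HIGH", "CONT_LOW")]),
               c(14L, 7L))
  expect_equal(nrow(se), 19L + 100L)
  expect_true(all(cs$truth$plantedGenes %in% rownames(se)))
  expect_true(all(md$rin > 0))
  expect_true(all(md$family_history %in% c("present", "absent", "unknown")))
})

test_that("generated gene sets are planted-first and decoys avoid the planted set", {
  cs <- simulateCohort(nBackgroundGenes = 200, seed = 9)
  gs <- simulateGeneSets(cs$truth, nDecoySets = 10, decoySize = 7, seed = 2)
  expect_equal(length(gs), 11L)
  expect_equal(names(gs)[1], cs$truth$plantedSetName)
  expect_equal(gs[[1]], cs$truth$plantedGenes)
  for (i in 2:11) {
    expect_length(gs[[i]], 7L)
    expect_length(intersect(gs[[i]], cs$truth$plantedGenes), 0L)
  }
  expect_equal(geneSets(simulateGeneSets(cs$truth, nDecoySets = 10,
                                         decoySize = 7, seed = 2)),
               geneSets(gs))
  none <- simulateGeneSets(cs$truth, nDecoySets = 0, seed = 1)
  expect_equal(length(none), 1L)
  expect_error(simulateGeneSets(cs$truth, nDecoySets = 1, decoySize = 1e5),
               "pool")
})

test_that("an empty noise-free field renders uniform white", {
  f <- renderField(nTunelPos = 0, nCounterstain = 0, width = 32, height = 32,
                   noiseSD = 0, seed = 1)
  expect_equal(dim(f$image), c(32L, 32L, 3L))
  expect_true(all(f$image == 255))
})

test_that("a pure-stain disk has OD parallel to its stain vector", {
  f <- renderField(nTunelPos = 1, nCounterstain = 0, width = 128,
                   height = 128, radiusRange = c(20, 20), noiseSD = 0,
                   seed = 4)
  ctr <- round(f$truth$centers[1, ])
  px <- f$image[ctr[1], ctr[2], ]
  od <- -log10(pmax(px, 1) / 255)
  dab <- stainVectors(defaultStainModel())[, "DAB"]
  # OD = amplitude * unit vector, up to 8-bit quantization
  expect_equal(od / sqrt(sum(od^2)), dab, tolerance = 2e-3)
  expect_equal(sqrt(sum(od^2)), 0.8, tolerance = 5e-3)
})

test_that("field rendering is deterministic and respects non-overlap", {
  a <- renderField(seed = 21)
  b <- renderField(seed = 21)
  expect_identical(a$image, b$image)
  ctr <- a$truth$centers; r <- a$truth$radii
  d <- as.matrix(dist(ctr))
  sep <- outer(r, r, "+")
  diag(d) <- Inf
  expect_true(all(d > sep))
  expect_error(renderField(nTunelPos = 500, nCounterstain = 0, width = 200,
                           height = 200, noiseSD = 0, seed = 1,
                           maxAttempts = 600),
               "non-overlapping")
})
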