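test_that("color deconvolution inverts the Beer-Lambert composition", {
  stains <- defaultStainModel()
  white <- array(255, c(2, 2, 3))
  conc <- colorDeconvolve(white, stains)
  expect_equal(max(abs(conc$DAB)), 0)
  expect_equal(max(abs(conc$MG)), 0)

  # synthesize a pure stain-1 pixel at amplitude a and recover it
  v <- stainVectors(stains)
  a <- 0.55
  img <- array(0, c(1, 1, 3))
  img[1, 1, ] <- 255 * 10^(-a * v[, 1])
  rec <- colorDeconvolve(img, stains)
  expect_equal(rec$DAB[1, 1], a, tolerance = 1e-6)
  expect_equal(rec$MG[1, 1], 0, tolerance = 1e-6)

  # mixed-stain noise-free field: per-pixel recovery within 1% after
  # 8-bit quantization
  f <- renderField(nTunelPos = 2, nCounterstain = 3, width = 256,
                   height = 256, noiseSD = 0, seed = 31)
  conc <- colorDeconvolve(f$image, stains)
  dabPix <- conc$DAB[conc$DAB > 0.4]
  mgPix <- conc$MG[conc$MG > 0.35]
  expect_equal(mean(dabPix), 0.8, tolerance = 0.01)
  expect_equal(mean(mgPix), 0.7, tolerance = 0.01)

  expect_error(StainModel(cbind(c(1, 1, 1), c(1, 1, 1) + 1e-12)),
               "collinear")
  expect_error(colorDeconvolve(matrix(0, 2, 2), stains), "RGB")
})

test_that("isodata threshold finds the intermeans fixed point", {
  ch <- matrix(c(rep(0.1, 50), rep(2, 50)), 10)
  mask <- isodataThreshold(ch)
  t <- attr(mask, "threshold")
  expect_gt(t, 0.1); expect_lt(t, 2)
  expect_equal(sum(mask), 50L)
  expect_true(all(mask[ch == 2]))
  # fixed point: t = (mean(<=t) + mean(>t))/2
  expect_equal(t, (mean(ch[ch <= t]) + mean(ch[ch > t])) / 2,
               tolerance = 1e-6)
  expect_error(isodataThreshold(matrix(1, 3, 3)), "constant")
})

test_that("particle filters apply the area and circularity rules", {
  # disk r=30 (area 2821 px^2) kept, disk r=20 (area 1257 px^2) rejected
  mask <- matrix(FALSE, 200, 200)
  mask[diskMask(200, 60, 60, 30)] <- TRUE
  mask[diskMask(200, 150, 150, 20)] <- TRUE
  expect_equal(sum(diskMask(200, 60, 60, 30)), 2821L)
  expect_equal(sum(diskMask(200, 150, 150, 20)), 1257L)
  kept <- particleAnalysis(mask)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$area, 2821L)
  allp <- attr(kept, "all")
  expect_equal(nrow(allp), 2L)

  # 50x50 square: boundary walk gives 4*49 = 196, circularity 0.818, kept
  sq <- matrix(FALSE, 60, 60); sq[6:55, 6:55] <- TRUE
  psq <- particleAnalysis(sq, minArea = 1000)
  expect_equal(psq$area, 2500L)
  expect_equal(psq$perimeter, 196)
  expect_equal(psq$circularity, 4 * pi * 2500 / 196^2, tolerance = 1e-9)

  # a 1-pixel-wide 3000 px line is far below the 0.1 circularity bound
  ln <- matrix(FALSE, 3, 3200); ln[2, 101:3100] <- TRUE
  pl <- particleAnalysis(ln, minArea = 2000)
  expect_equal(nrow(pl), 0L)
  expect_lt(attr(pl, "all")$circularity, 0.01)

  expect_equal(nrow(particleAnalysis(matrix(FALSE, 5, 5))), 0L)
})

test_that("rasterized disks with r >= 15 stay comfortably above circularity 0.85", {
  for (r in c(15, 20, 30, 36)) {
    n <- 2 * r + 11
    mask <- diskMask(n, r + 6, r + 6, r)
    p <- particleAnalysis(matrix(mask, n), minArea = 1)
    expect_gte(p$circularity, 0.85)
  }
})

test_that("8-connected labeling joins diagonal components", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE  # touch only diagonally
  p <- attr(particleAnalysis(m, minArea = 1, circularityRange = c(0, 1)),
            "all")
  expect_equal(nrow(p), 1L)
  expect_equal(p$area, 2L)
})

test_that("positivity rate follows the pooled-count definition", {
  expect_equal(tunelPositivity(5, 15), 0.25)
  expect_equal(tunelPositivity(0, 15), 0)
  expect_error(tunelPositivity(0, 0), "undefined")
  expect_error(tunelPositivity(-1, 3), "non-negative")
})

test_that("rendered fields are quantified back to their ground truth", {
  f <- renderField(nTunelPos = 5, nCounterstain = 15, noiseSD = 2, seed = 41)
  q <- quantifyField(f$image)
  expect_equal(q$nTunel, 5L)
  expect_equal(q$nCounterstain, 15L)
  expect_equal(q$rate, 0.25)

  f0 <- renderField(nTunelPos = 3, nCounterstain = 4, noiseSD = 0, seed = 42)
  q0 <- quantifyField(f0$image)
  expect_equal(c(q0$nTunel, q0$nCounterstain), c(3L, 4L))
})

test_that("case quantification pools counts across fields", {
  truth <- list(c(2, 18), c(3, 17), c(5, 15), c(0, 20), c(4, 16), c(1, 19))
  fields <- lapply(seq_along(truth), function(i)
    renderField(nTunelPos = truth[[i]][1], nCounterstain = truth[[i]][2],
                noiseSD = 2, seed = 500 + i)$image)
  res <- quantifyCase(fields)
  expect_equal(res@nTunel, 15L)
  expect_equal(res@nCounterstain, 105L)
  expect_equal(positivityRate(res), 15 / 120)
  expect_equal(positivityRate(res), 0.125)
  tab <- fieldCounts(res)
  expect_equal(tab$n_tunel, sapply(truth, `[`, 1))
  # pooling is order independent
  res2 <- quantifyCase(fields[c(4, 2, 6, 1, 3, 5)])
  expect_equal(positivityRate(res2), positivityRate(res))
  # six identical fields: case rate equals the field rate
  same <- quantifyCase(rep(fields[3], 6))
  expect_equal(positivityRate(same), 5 / 20)
})

test_that("fields that fail thresholding are skipped with a warning", {
  good <- renderField(nTunelPos = 2, nCounterstain = 3, noiseSD = 2,
                      seed = 51)$image
  flat <- array(255, c(64, 64, 3))  # constant channels cannot be thresholded
  expect_warning(res <- quantifyCase(list(good, flat)), "skipped")
  expect_equal(nrow(fieldCounts(res)), 1L)
  expect_error(suppressWarnings(quantifyCase(list(flat))), "all fields")
  expect_error(quantifyCase(list()), "at least one")
})

test_that("field images survive a PNG round trip", {
  f <- renderField(nTunelPos = 1, nCounterstain = 2, width = 256,
                   height = 256, noiseSD = 2, seed = 61)
  p <- tempfile(fileext = ".png")
  writeFieldImage(f$image, p)
  back <- readFieldImage(p)
  expect_equal(dim(back), dim(f$image))
  expect_equal(back, f$image)
  q <- quantifyField(back)
  expect_equal(c(q$nTunel, q$nCounterstain), c(1L, 2L))
})
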