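test_that("expression TSV and MTX round trips preserve values and ids", {
  set.seed(101)
  for (fmt in c("TSV", "MTX")) {
    for (rep in 1:3) {
      ng <- sample(2:20, 1); ns <- sample(2:8, 1)
      m <- matrix(round(abs(rnorm(ng * ns, 50, 30)), 3), ng,
                  dimnames = list(paste0("G", seq_len(ng)),
                                  paste0("S", seq_len(ns))))
      path <- tempfile(fileext = if (fmt == "TSV") ".tsv" else ".mtx")
      writeExpression(m, path, fmt)
      back <- readExpression(path, fmt)
      expect_equal(cpmValues(back), m, tolerance = 1e-8)
      expect_identical(rownames(back), rownames(m))
      expect_identical(colnames(back), colnames(m))
    }
  }
  m2 <- matrix(c(1, 3, 2, 4), 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  p <- tempfile(fileext = ".tsv")
  writeExpression(m2, p)
  expect_equal(unname(cpmValues(readExpression(p))), matrix(c(1, 3, 2, 4), 2))
})

test_that("malformed expression input is rejected with an informative error", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "IL6\t1\t2", "IL6\t3\t4"), p)
  expect_error(readExpression(p), "IL6")
  writeLines(c("gene_id\ts1\ts2", "IL6\t1\t-2"), p)
  expect_error(readExpression(p), "non-negative")
  expect_error(readExpression(tempfile()), "not found")
})

test_that("panel YAML round trip and the default panels have the expected shape", {
  panel <- defaultStressPanel()
  e <- panelEntries(panel)
  expect_equal(nrow(e), 19L)
  expect_equal(sum(e$direction == "UP"), 7L)
  expect_equal(sum(e$direction == "DOWN"), 7L)
  expect_equal(sum(e$direction == "VARIABLE"), 5L)
  expect_setequal(upGenes(panel),
                  c("IL1B", "IL6", "IFNG", "TNF", "SOD1", "SOD2", "SOD3"))
  expect_setequal(downGenes(panel),
                  c("BDNF", "IL10", "DLG4", "SYP", "SNCA", "SNCB", "SNCG"))

  p <- tempfile(fileext = ".yaml")
  writePanel(panel, p)
  back <- readPanel(p)
  expect_equal(panelEntries(back)$symbol, e$symbol)
  expect_equal(panelEntries(back)$direction, e$direction)

  ip <- defaultIndexPanel()
  ie <- panelEntries(ip)
  expect_equal(sum(ie$direction == "HIGH_IN_HSR"), 6L)
  expect_equal(sum(ie$direction == "HIGH_IN_LSR"), 4L)
  writePanel(ip, p)
  expect_equal(panelEntries(readPanel(p, type = "index"))$direction,
               ie$direction)
})

test_that("panel construction enforces the direction enum and uniqueness", {
  expect_s4_class(GenePanel("IL6", "UP"), "GenePanel")
  expect_error(GenePanel("IL6", "SIDEWAYS"), "SIDEWAYS")
  expect_error(GenePanel(c("IL6", "il6 "), c("UP", "DOWN")), "duplicate")
  expect_error(IndexPanel("IL6", "UP"), "invalid direction")
  p <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(panel = list(list(symbol = "IL6"))), p)
  expect_error(readPanel(p), "direction")
})

test_that("GMT reading handles the standard dialect and its edge cases", {
  p <- tempfile(fileext = ".gmt")
  writeLines("DSB_HR\tdesc\tMRE11\tBRCA2\tATRX\tRPA1\tPOLA1\tLIG1\tGEN1", p)
  gs <- readGMT(p)
  expect_equal(length(gs), 1L)
  expect_equal(length(gs[["DSB_HR"]]), 7L)
  expect_setequal(gs[["DSB_HR"]],
                  c("MRE11", "BRCA2", "ATRX", "RPA1", "POLA1", "LIG1", "GEN1"))

  writeLines(character(), p)
  expect_equal(length(readGMT(p)), 0L)

  writeLines(c("A\td\tX\tY", "A\td\tZ\tW"), p)
  expect_error(readGMT(p), "duplicate")
  writeLines("A\tonly_two_fields", p)
  expect_error(readGMT(p), "malformed")

  set.seed(7)
  sets <- lapply(1:5, function(i)
    paste0("G", sample(100, sample(2:10, 1))))
  names(sets) <- paste0("SET", 1:5)
  writeGMT(GeneSetList(sets), p)
  expect_equal(geneSets(readGMT(p)), sets)
})

test_that("sample metadata round trips with explicit missing markers", {
  md <- data.frame(diagnosis = c("SZ", "CONTROL"), age_years = c(70, 65),
                   sex = c("M", "F"), rin = c(7.1, 5.9),
                   pmi_hours = c(12, 8), cpz_eq_mg = c(500, NA),
                   family_history = c("present", NA),
                   death_category = c("inflammatory", "malignancy"),
                   row.names = c("s1", "s2"), stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".tsv")
  writeSampleMetadata(md, p)
  back <- readSampleMetadata(p)
  expect_equal(back$family_history, c("present", "unknown"))
  expect_true(is.na(back["s2", "cpz_eq_mg"]))
  expect_equal(back$rin, md$rin)
})

test_that("StressExperiment validity rejects inconsistent input", {
  m <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_s4_class(StressExperiment(m), "StressExperiment")
  bad <- m; bad[1] <- -1
  expect_error(StressExperiment(bad), "non-negative")
  dup <- m; rownames(dup) <- c("g1", "g1")
  expect_error(StressExperiment(dup), "duplicate")
  md <- data.frame(rin = c(0, 5), row.names = c("a", "b"))
  expect_error(StressExperiment(m, md), "rin")
})
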