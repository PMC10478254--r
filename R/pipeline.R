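#' Pipeline configuration
#'
#' Bundles the thresholds of the full analysis with their documented
#' defaults: the rescaled-distance cut at 20, the top-8000 DEG list, the
#' 2000 px^2 / 0.1-1 particle filters.
#'
#' @param rescaledCut rescaled dendrogram cut height in `(0, 25]`
#'   (default 20).
#' @param schedule `"incremental"` or `"cumulative"` height rescaling; see
#'   [cutRescaled()].
#' @param topN DEG list size (default 8000).
#' @param minArea,circularityRange particle filters.
#' @param seed integer seed recorded in the run manifest.
#' @return A named list of validated settings.
#' @export
pipelineConfig <- function(rescaledCut = 20, schedule = "incremental",
                           topN = 8000L, minArea = 2000L,
                           circularityRange = c(0.1, 1), seed = 1L) {
  if (rescaledCut <= 0 || rescaledCut > 25)
    stop("rescaledCut must lie in (0, 25]", call. = FALSE)
  if (topN < 1) stop("topN must be positive", call. = FALSE)
  if (minArea < 1) stop("minArea must be positive", call. = FALSE)
  if (circularityRange[1] < 0 || circularityRange[2] > 1 ||
      circularityRange[1] > circularityRange[2])
    stop("circularityRange must be within [0, 1]", call. = FALSE)
  list(rescaledCut = rescaledCut, schedule = schedule, topN = as.integer(topN),
       minArea = as.integer(minArea), circularityRange = circularityRange,
       seed = as.integer(seed))
}

#' Run the SZ stratification arm
#'
#' End-to-end chain on the SZ cases of a cohort: Z-score standardization of
#' panel genes, Ward clustering, rescaled-distance cut, HSR/LSR concordance
#' labeling, per-panel-gene Mann-Whitney contrasts between the strata,
#' Fisher exact tests on cause-of-death categories (RxC) and family history
#' (2x2, unknown excluded) when metadata provides them, differential
#' expression over all genes, top-N selection, and gene-set
#' overrepresentation. Stage names are prefixed to propagated errors. The
#' run is deterministic: identical inputs and config give byte-identical
#' output files.
#'
#' @param experiment a [StressExperiment-class] with `diagnosis` metadata.
#' @param panel a [GenePanel-class] (default [defaultStressPanel()]).
#' @param geneSets optional [GeneSetList-class] for overrepresentation.
#' @param config list from [pipelineConfig()].
#' @param outputDir optional directory; when given, all tables plus a JSON
#'   report and run manifest are written there.
#' @return A list report: `labeling`, `assignment`, `schedule`,
#'   `panelTests`, `fisherDeath`, `fisherFamily`, `deg`, `topGenes`,
#'   `enrichment`, `counts`.
#' @export
runSZArm <- function(experiment, panel = defaultStressPanel(),
                     geneSets = NULL, config = pipelineConfig(),
                     outputDir = NULL) {
  sz <- .stage("subset", subsetByDiagnosis(experiment, "SZ"))
  if (ncol(sz) < 4L)
    stop("stage subset: need at least 4 SZ samples", call. = FALSE)
  std <- .stage("standardize", zscoreStandardize(sz, panel))
  dendro <- .stage("cluster", wardCluster(std))
  part <- .stage("cut", cutRescaled(dendro, config$rescaledCut,
                                    config$schedule))
  labeling <- .stage("label", labelStrata(part, std, panel))
  assignment <- strataAssignment(labeling)
  panelTests <- .stage("panel-contrasts",
                       .panelContrasts(sz, panel, assignment))
  md <- sampleMetadata(sz)
  fisherDeath <- .deathCategoryTest(md, assignment)
  fisherFamily <- .familyHistoryTest(md, assignment)
  grp <- factor(assignment, levels = c("HSR", "LSR"))
  names(grp) <- names(assignment)
  deg <- .stage("deg", differentialExpression(sz, grp))
  top <- .stage("top-n", topGenes(deg, config$topN))
  enrichment <- if (!is.null(geneSets))
    .stage("enrich", overrepresentation(top, geneSets, deg$gene, deg))
  report <- list(arm = "SZ", labeling = labeling, assignment = assignment,
                 schedule = mergeSchedule(dendro, config$schedule),
                 panelTests = panelTests, fisherDeath = fisherDeath,
                 fisherFamily = fisherFamily, deg = deg, topGenes = top,
                 enrichment = enrichment,
                 counts = list(samples = ncol(sz), genesTested = nrow(deg),
                               genesExcluded = attr(deg, "nExcluded"),
                               listSize = length(top)))
  if (!is.null(outputDir))
    .writeArmOutputs(report, config, outputDir, prefix = "sz")
  report
}

#' Run the control classification arm
#'
#' Mirrors the SZ arm on the control subjects, replacing clustering with the
#' quartile stress-response index: index scores and HSR/LSR classes
#' (indeterminate subjects are excluded from contrasts with a warning),
#' per-panel-gene Mann-Whitney contrasts, Fisher exact test on death
#' categories, differential expression, top-N, and overrepresentation.
#' When an SZ-arm assignment is supplied, a four-group contrast table
#' (HSR/LSR x SZ/control, Mann-Whitney per gene) is produced for
#' `contrastGenes`.
#'
#' @param experiment a [StressExperiment-class] with `diagnosis` metadata.
#' @param indexPanel an [IndexPanel-class] (default [defaultIndexPanel()]).
#' @param panel a [GenePanel-class] for the per-gene contrasts.
#' @param geneSets optional [GeneSetList-class].
#' @param config list from [pipelineConfig()].
#' @param szAssignment optional named HSR/LSR vector from the SZ arm.
#' @param contrastGenes genes for the four-group contrast table (default:
#'   overlap genes of the SZ arm's top enriched set, when available via
#'   `szEnrichment`).
#' @param outputDir optional output directory.
#' @return A list report: `index`, `classes`, `panelTests`, `fisherDeath`,
#'   `deg`, `topGenes`, `enrichment`, `fourGroup`, `counts`.
#' @export
runControlArm <- function(experiment, indexPanel = defaultIndexPanel(),
                          panel = defaultStressPanel(), geneSets = NULL,
                          config = pipelineConfig(), szAssignment = NULL,
                          contrastGenes = NULL, outputDir = NULL) {
  if (!nrow(panelEntries(indexPanel)))
    stop("stage config: empty index panel", call. = FALSE)
  ctl <- .stage("subset", subsetByDiagnosis(experiment, "CONTROL"))
  if (ncol(ctl) < 4L)
    stop("stage subset: need at least 4 control samples", call. = FALSE)
  index <- .stage("index", stressResponseIndex(ctl, indexPanel))
  cls <- indexClasses(index)
  det <- cls[cls != "INDETERMINATE"]
  if (!length(det))
    stop("stage index: all controls indeterminate (index 0)", call. = FALSE)
  if (length(det) < length(cls))
    warning(length(cls) - length(det),
            " control(s) with index 0 excluded from contrasts")
  if (length(unique(det)) < 2L)
    stop("stage index: all controls fall in one class; no contrast possible",
         call. = FALSE)
  panelTests <- .stage("panel-contrasts", .panelContrasts(ctl, panel, det))
  fisherDeath <- .deathCategoryTest(sampleMetadata(ctl)[names(det), ,
                                                        drop = FALSE], det)
  grp <- factor(det, levels = c("HSR", "LSR"))
  names(grp) <- names(det)
  deg <- .stage("deg",
                differentialExpression(ctl[, names(det)], grp))
  top <- .stage("top-n", topGenes(deg, config$topN))
  enrichment <- if (!is.null(geneSets))
    .stage("enrich", overrepresentation(top, geneSets, deg$gene, deg))
  fourGroup <- NULL
  if (!is.null(szAssignment) && !is.null(contrastGenes))
    fourGroup <- .stage("four-group",
                        fourGroupContrasts(experiment, szAssignment, det,
                                           contrastGenes))
  report <- list(arm = "CONTROL", index = index, classes = det,
                 panelTests = panelTests, fisherDeath = fisherDeath,
                 deg = deg, topGenes = top, enrichment = enrichment,
                 fourGroup = fourGroup,
                 counts = list(samples = ncol(ctl),
                               classified = length(det),
                               genesTested = nrow(deg),
                               genesExcluded = attr(deg, "nExcluded"),
                               listSize = length(top)))
  if (!is.null(outputDir))
    .writeArmOutputs(report, config, outputDir, prefix = "control")
  report
}

#' Four-group expression contrasts
#'
#' Mann-Whitney contrasts of each gene across the four comparisons
#' HSR-SZ vs LSR-SZ, HSR-Cont vs LSR-Cont, HSR-SZ vs HSR-Cont and
#' LSR-SZ vs LSR-Cont, one row per gene per comparison.
#'
#' @param experiment a [StressExperiment-class].
#' @param szAssignment named HSR/LSR vector over SZ samples.
#' @param controlClasses named HSR/LSR vector over control samples.
#' @param genes gene ids to contrast.
#' @return `data.frame` with `gene`, `comparison`, `U`, `p`.
#' @export
fourGroupContrasts <- function(experiment, szAssignment, controlClasses,
                               genes) {
  m <- cpmValues(experiment)
  miss <- setdiff(genes, rownames(m))
  if (length(miss))
    stop("unknown gene(s): ", paste(miss, collapse = ", "), call. = FALSE)
  pools <- list(
    "HSR-SZ vs LSR-SZ" =
      list(names(szAssignment)[szAssignment == "HSR"],
           names(szAssignment)[szAssignment == "LSR"]),
    "HSR-Cont vs LSR-Cont" =
      list(names(controlClasses)[controlClasses == "HSR"],
           names(controlClasses)[controlClasses == "LSR"]),
    "HSR-SZ vs HSR-Cont" =
      list(names(szAssignment)[szAssignment == "HSR"],
           names(controlClasses)[controlClasses == "HSR"]),
    "LSR-SZ vs LSR-Cont" =
      list(names(szAssignment)[szAssignment == "LSR"],
           names(controlClasses)[controlClasses == "LSR"]))
  rows <- list()
  for (g in genes) for (cmp in names(pools)) {
    a <- m[g, pools[[cmp]][[1]]]; b <- m[g, pools[[cmp]][[2]]]
    tst <- mannWhitneyU(a, b)
    rows[[length(rows) + 1L]] <-
      data.frame(gene = g, comparison = cmp, U = tst$statistic,
                 p = tst$p.value, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
}

# Mann-Whitney contrast of every panel gene between the two strata, on the
# CPM scale; reports U, p and (approximate-path) effect size r.
.panelContrasts <- function(experiment, panel, assignment) {
  m <- cpmValues(experiment)
  e <- panelEntries(panel)
  idx <- .resolvePanelRows(e$symbol, e$alias, rownames(m))
  hi <- names(assignment)[assignment == "HSR"]
  lo <- names(assignment)[assignment == "LSR"]
  rows <- lapply(seq_along(idx), function(k) {
    tst <- mannWhitneyU(m[idx[k], hi], m[idx[k], lo])
    data.frame(gene = e$symbol[k], direction = e$direction[k],
               meanHSR = mean(m[idx[k], hi]), meanLSR = mean(m[idx[k], lo]),
               U = tst$statistic, p = tst$p.value, r = tst$effect.size.r,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.deathCategoryTest <- function(md, assignment) {
  if (!"death_category" %in% names(md)) return(NULL)
  dc <- md[names(assignment), "death_category"]
  keep <- !is.na(dc)
  if (!any(keep)) return(NULL)
  tab <- table(factor(dc[keep], c("inflammatory", "non_inflammatory",
                                  "malignancy")),
               factor(assignment[keep], c("HSR", "LSR")))
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2L || any(colSums(tab) == 0)) return(NULL)
  fisherExactRxC(tab)
}

.familyHistoryTest <- function(md, assignment) {
  if (!"family_history" %in% names(md)) return(NULL)
  fh <- md[names(assignment), "family_history"]
  keep <- !is.na(fh) & fh %in% c("present", "absent")
  if (sum(keep) < 2L) return(NULL)
  tab <- table(factor(fh[keep], c("present", "absent")),
               factor(assignment[keep], c("HSR", "LSR")))
  if (any(colSums(tab) == 0)) return(NULL)
  fisherExact2x2(tab)
}

# Deterministic serialization of an arm report: fixed column orders, fixed
# numeric formatting, no timestamps.
.writeArmOutputs <- function(report, config, outputDir, prefix) {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(outputDir, paste0(prefix, "_", name)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$assignment))
    wt(data.frame(sample = names(report$assignment),
                  stratum = unname(report$assignment)), "assignment.tsv")
  if (!is.null(report$classes))
    wt(data.frame(sample = names(report$classes),
                  score = unname(indexScores(report$index)[names(report$classes)]),
                  class = unname(report$classes)), "classes.tsv")
  if (!is.null(report$schedule)) wt(report$schedule, "merge_schedule.tsv")
  wt(report$panelTests, "panel_tests.tsv")
  wt(report$deg, "deg.tsv")
  writeLines(report$topGenes, file.path(outputDir,
                                        paste0(prefix, "_top_genes.txt")))
  if (!is.null(report$enrichment)) wt(report$enrichment, "enrichment.tsv")
  if (!is.null(report$fourGroup)) wt(report$fourGroup, "four_group.tsv")
  manifest <- list(
    arm = report$arm,
    config = config[c("rescaledCut", "schedule", "topN", "minArea",
                      "circularityRange", "seed")],
    counts = report$counts,
    concordance = if (!is.null(report$labeling))
      as.list(strataConcordance(report$labeling)),
    fisherDeath_p = if (!is.null(report$fisherDeath))
      report$fisherDeath$p.value,
    fisherFamily_p = if (!is.null(report$fisherFamily))
      report$fisherFamily$p.value,
    package = as.character(utils::packageVersion("stressStrat")))
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  writeLines(json, file.path(outputDir, paste0(prefix, "_manifest.json")))
  invisible(outputDir)
}
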