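#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats pt phyper dhyper pnorm quantile rnorm rnbinom rpois runif
#'   rbinom sd setNames p.adjust complete.cases
#' @importFrom utils combn read.table write.table head
NULL

.DIRECTIONS <- c("UP", "DOWN", "VARIABLE")
.INDEX_DIRECTIONS <- c("HIGH_IN_HSR", "HIGH_IN_LSR")

#' Panel of stress-responsive genes
#'
#' A `GenePanel` holds the membership of the stress-responsive gene panel used
#' for patient stratification, together with each gene's expected direction of
#' change under stress: `"UP"` (expression increases under stress), `"DOWN"`
#' (decreases), or `"VARIABLE"` (reported direction inconsistent across
#' studies). `VARIABLE` genes take part in clustering but are excluded from
#' the directional concordance used to name the clusters.
#'
#' @slot entries `data.frame` with columns `symbol` (character, unique after
#'   whitespace trimming and case folding), `direction` (one of `"UP"`,
#'   `"DOWN"`, `"VARIABLE"`), and `alias` (character or `NA`; an alternative
#'   symbol under which the gene may appear in an expression matrix, e.g. a
#'   protein name).
#'
#' @seealso [GenePanel()], [defaultStressPanel()], [labelStrata()]
#' @export
setClass("GenePanel", representation(entries = "data.frame"))

setValidity("GenePanel", function(object) {
  e <- object@entries
  msgs <- character()
  need <- c("symbol", "direction", "alias")
  if (!all(need %in% names(e)))
    return(sprintf("entries must have columns %s", paste(need, collapse = ", ")))
  if (nrow(e) == 0L) msgs <- c(msgs, "panel must contain at least one gene")
  key <- toupper(trimws(e$symbol))
  if (anyDuplicated(key))
    msgs <- c(msgs, sprintf("duplicate gene symbol(s): %s",
                            paste(unique(key[duplicated(key)]), collapse = ", ")))
  bad <- setdiff(unique(e$direction), .DIRECTIONS)
  if (length(bad))
    msgs <- c(msgs, sprintf("invalid direction value(s): %s (allowed: %s)",
                            paste(bad, collapse = ", "),
                            paste(.DIRECTIONS, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Index panel for the stress-response index
#'
#' An `IndexPanel` lists the genes entering the quartile-weighted
#' stress-response index, each tagged with the subgroup in which it is more
#' highly expressed: `"HIGH_IN_HSR"` genes score (-3, -1, 1, 3) across
#' quartiles 1..4 and `"HIGH_IN_LSR"` genes score (3, 1, -1, -3).
#'
#' @slot entries `data.frame` with columns `symbol`, `direction`
#'   (`"HIGH_IN_HSR"` or `"HIGH_IN_LSR"`), and `alias`.
#'
#' @seealso [IndexPanel()], [defaultIndexPanel()], [stressResponseIndex()]
#' @export
setClass("IndexPanel", representation(entries = "data.frame"))

setValidity("IndexPanel", function(object) {
  e <- object@entries
  msgs <- character()
  need <- c("symbol", "direction", "alias")
  if (!all(need %in% names(e)))
    return(sprintf("entries must have columns %s", paste(need, collapse = ", ")))
  if (nrow(e) == 0L) msgs <- c(msgs, "index panel must contain at least one gene")
  key <- toupper(trimws(e$symbol))
  if (anyDuplicated(key))
    msgs <- c(msgs, sprintf("duplicate gene symbol(s): %s",
                            paste(unique(key[duplicated(key)]), collapse = ", ")))
  bad <- setdiff(unique(e$direction), .INDEX_DIRECTIONS)
  if (length(bad))
    msgs <- c(msgs, sprintf("invalid direction value(s): %s (allowed: %s)",
                            paste(bad, collapse = ", "),
                            paste(.INDEX_DIRECTIONS, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Expression matrix with sample metadata
#'
#' A `StressExperiment` is a [SummarizedExperiment::SummarizedExperiment]
#' whose single assay `"cpm"` holds a gene x sample matrix of counts per
#' million (non-negative reals) and whose `colData` carries the clinical
#' covariates the pipeline consumes: `diagnosis` (`"SZ"`/`"CONTROL"`),
#' `age_years`, `sex` (`"F"`/`"M"`), `rin`, `pmi_hours`, `cpz_eq_mg`
#' (`NA` allowed), `family_history` (`"present"`/`"absent"`/`"unknown"`),
#' `death_category` (`"inflammatory"`/`"non_inflammatory"`/`"malignancy"`).
#'
#' @seealso [StressExperiment()], [readExpression()], [simulateCohort()]
#' @export
setClass("StressExperiment", contains = "SummarizedExperiment")

setValidity("StressExperiment", function(object) {
  msgs <- character()
  if (!"cpm" %in% SummarizedExperiment::assayNames(object))
    return("assay 'cpm' is required")
  m <- SummarizedExperiment::assay(object, "cpm")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msgs <- c(msgs, "gene (row) and sample (column) names are required")
  if (!is.null(rownames(m)) && anyDuplicated(rownames(m)))
    msgs <- c(msgs, sprintf("duplicate gene id(s): %s",
                            paste(unique(rownames(m)[duplicated(rownames(m))]),
                                  collapse = ", ")))
  if (!is.null(colnames(m)) && anyDuplicated(colnames(m)))
    msgs <- c(msgs, sprintf("duplicate sample id(s): %s",
                            paste(unique(colnames(m)[duplicated(colnames(m))]),
                                  collapse = ", ")))
  if (anyNA(m) || any(m < 0))
    msgs <- c(msgs, "CPM values must be non-negative and non-missing")
  cd <- SummarizedExperiment::colData(object)
  if ("rin" %in% names(cd)) {
    r <- cd$rin
    if (any(!is.na(r) & r <= 0)) msgs <- c(msgs, "rin must be > 0 when present")
  }
  if ("diagnosis" %in% names(cd)) {
    bad <- setdiff(unique(as.character(cd$diagnosis)), c("SZ", "CONTROL", NA))
    if (length(bad))
      msgs <- c(msgs, sprintf("invalid diagnosis value(s): %s",
                              paste(bad, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Named collection of gene sets
#'
#' Plain container for gene-set collections read from GMT files or generated
#' synthetically; names are unique and every set is non-empty.
#'
#' @slot sets named `list` of character vectors of gene symbols.
#' @seealso [GeneSetList()], [readGMT()], [overrepresentation()]
#' @export
setClass("GeneSetList", representation(sets = "list"))

setValidity("GeneSetList", function(object) {
  s <- object@sets
  msgs <- character()
  if (length(s)) {
    if (is.null(names(s)) || any(!nzchar(names(s))))
      msgs <- c(msgs, "all gene sets must be named")
    if (anyDuplicated(names(s)))
      msgs <- c(msgs, sprintf("duplicate set name(s): %s",
                              paste(unique(names(s)[duplicated(names(s))]),
                                    collapse = ", ")))
    if (any(lengths(s) == 0L))
      msgs <- c(msgs, "gene sets must be non-empty")
    if (!all(vapply(s, is.character, logical(1))))
      msgs <- c(msgs, "gene sets must be character vectors")
  }
  if (length(msgs)) msgs else TRUE
})

#' Ward merge history with incremental sum-of-squares heights
#'
#' Agglomeration schedule of Ward clustering. `merge` follows the
#' [stats::hclust] convention (negative entries are leaves, positive entries
#' reference earlier merges); `height[i]` is the increase in total
#' within-cluster sum of squares (delta-SSE) caused by merge `i`. Ward
#' linkage guarantees the heights are non-decreasing.
#'
#' @slot merge integer matrix, (n-1) x 2.
#' @slot height numeric vector of delta-SSE merge costs, non-decreasing.
#' @slot labels character vector of the n leaf (sample) ids.
#' @seealso [wardCluster()], [cutRescaled()], [as.hclust.WardDendrogram]
#' @export
setClass("WardDendrogram",
         representation(merge = "matrix", height = "numeric",
                        labels = "character"))

setValidity("WardDendrogram", function(object) {
  n <- length(object@labels)
  msgs <- character()
  if (nrow(object@merge) != n - 1L || length(object@height) != n - 1L)
    msgs <- c(msgs, "a dendrogram over n leaves must contain n-1 merges")
  h <- object@height
  if (length(h) > 1L && any(diff(h) < -1e-8 * max(abs(h), 1)))
    msgs <- c(msgs, "Ward merge heights must be non-decreasing")
  if (length(msgs)) msgs else TRUE
})

#' High/low stress-response cluster labeling
#'
#' Assignment of samples to the HSR (high stress-response) and LSR (low
#' stress-response) strata, with each cluster's directional concordance
#' (mean z-score over UP panel genes minus mean z-score over DOWN panel
#' genes); the higher-concordance cluster is HSR by definition.
#'
#' @slot assignment named character vector, one of `"HSR"`/`"LSR"` per sample.
#' @slot concordance named numeric vector of length 2 (names `"HSR"`, `"LSR"`).
#' @seealso [labelStrata()]
#' @export
setClass("StrataLabeling",
         representation(assignment = "character", concordance = "numeric"))

setValidity("StrataLabeling", function(object) {
  msgs <- character()
  if (!setequal(unique(object@assignment), c("HSR", "LSR")))
    msgs <- c(msgs, "exactly the two strata HSR and LSR must be assigned")
  if (!setequal(names(object@concordance), c("HSR", "LSR")))
    msgs <- c(msgs, "concordance must be named HSR and LSR")
  else if (!isTRUE(object@concordance[["HSR"]] > object@concordance[["LSR"]]))
    msgs <- c(msgs, "HSR concordance must exceed LSR concordance")
  if (length(msgs)) msgs else TRUE
})

#' Quartile-weighted stress-response index
#'
#' Per-subject integer index scores, the per-gene quartile memberships behind
#' them, and the resulting class (`"HSR"` for score > 0, `"LSR"` for
#' score < 0, `"INDETERMINATE"` for the score-0 boundary the scoring rule
#' leaves undefined).
#'
#' @slot score named integer vector of index scores.
#' @slot quartiles integer matrix (panel gene x subject) of quartile
#'   memberships 1..4.
#' @slot classification named character vector of `"HSR"`/`"LSR"`/`"INDETERMINATE"`.
#' @seealso [stressResponseIndex()]
#' @export
setClass("StressIndexResult",
         representation(score = "integer", quartiles = "matrix",
                        classification = "character"))

setValidity("StressIndexResult", function(object) {
  msgs <- character()
  g <- nrow(object@quartiles)
  if (any(abs(object@score) > 3L * g))
    msgs <- c(msgs, "|score| cannot exceed 3 x (number of panel genes)")
  if (!all(object@classification %in% c("HSR", "LSR", "INDETERMINATE")))
    msgs <- c(msgs, "class must be HSR, LSR or INDETERMINATE")
  q <- object@quartiles
  if (length(q) && (any(q < 1L) || any(q > 4L)))
    msgs <- c(msgs, "quartile memberships must lie in 1..4")
  if (length(msgs)) msgs else TRUE
})

#' Optical-density stain basis for color deconvolution
#'
#' Two or three unit-length, non-negative optical-density triplets, one per
#' stain (Beer-Lambert model). When only two stains are supplied a residual
#' third vector (normalized cross product) completes the basis.
#'
#' @slot vectors 3 x k numeric matrix (k = 2 or 3), columns are stains,
#'   rows are the R, G, B optical-density components.
#' @seealso [StainModel()], [defaultStainModel()], [colorDeconvolve()]
#' @export
setClass("StainModel", representation(vectors = "matrix"))

setValidity("StainModel", function(object) {
  v <- object@vectors
  msgs <- character()
  if (nrow(v) != 3L || !ncol(v) %in% c(2L, 3L))
    return("stain vectors must form a 3 x 2 or 3 x 3 matrix")
  if (any(v < -1e-12)) msgs <- c(msgs, "OD components must be non-negative")
  nrm <- sqrt(colSums(v^2))
  if (any(abs(nrm - 1) > 1e-6))
    msgs <- c(msgs, "each stain vector must have unit L2 norm")
  cr <- .crossProduct(v[, 1], v[, 2])
  if (sqrt(sum(cr^2)) < 1e-8)
    msgs <- c(msgs, "the first two stain vectors must not be collinear")
  if (length(msgs)) msgs else TRUE
})

#' Per-case TUNEL quantification result
#'
#' Particle counts per stain channel for each image field of a case, together
#' with the case-level TUNEL positivity rate obtained by pooling counts
#' across fields: rate = n_tunel / (n_tunel + n_counterstain).
#'
#' @slot fields `data.frame` with one row per analyzed field: `field`,
#'   `n_tunel`, `n_counterstain`, `rate` (`NA` when a field holds no
#'   particles at all).
#' @slot nTunel,nCounterstain pooled particle counts.
#' @slot rate pooled positivity rate in `[0, 1]`.
#' @seealso [quantifyCase()]
#' @export
setClass("QuantResult",
         representation(fields = "data.frame", nTunel = "integer",
                        nCounterstain = "integer", rate = "numeric"))

setValidity("QuantResult", function(object) {
  msgs <- character()
  if (object@nTunel < 0L || object@nCounterstain < 0L)
    msgs <- c(msgs, "counts must be non-negative")
  if (!is.na(object@rate) && (object@rate < 0 || object@rate > 1))
    msgs <- c(msgs, "positivity rate must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

.crossProduct <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
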