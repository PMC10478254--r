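#' Z-score standardize panel genes
#'
#' Restricts the expression matrix to the panel genes (matched
#' case-insensitively after trimming, with alias fallback) and standardizes
#' each gene row to mean 0 and unit sample standard deviation (n-1
#' denominator). Rows of the result are named by the panel symbol.
#'
#' @param object a [StressExperiment-class] or a numeric gene x sample matrix.
#' @param panel a [GenePanel-class]; all its genes must be present.
#' @return Numeric panel-gene x sample matrix of z-scores.
#' @export
zscoreStandardize <- function(object, panel) {
  m <- if (methods::is(object, "StressExperiment")) cpmValues(object)
       else as.matrix(object)
  if (ncol(m) < 2L)
    stop("at least 2 samples are required for standardization", call. = FALSE)
  e <- panelEntries(panel)
  idx <- .resolvePanelRows(e$symbol, e$alias, rownames(m))
  sub <- m[idx, , drop = FALSE]
  rownames(sub) <- e$symbol
  mu <- rowMeans(sub)
  sdv <- apply(sub, 1L, stats::sd)
  zero <- sdv == 0
  if (any(zero))
    stop("cannot standardize zero-variance gene(s): ",
         paste(e$symbol[zero], collapse = ", "), call. = FALSE)
  (sub - mu) / sdv
}

#' Ward agglomerative clustering of samples
#'
#' Clusters the samples (columns) of a standardized panel matrix by Ward's
#' minimum-variance method: at every step the pair of clusters whose merge
#' least increases the total within-cluster sum of squares is joined. The
#' merge cost (delta-SSE, `n_i n_j / (n_i + n_j) * ||c_i - c_j||^2` for
#' centroids `c`) is maintained by the Lance-Williams recurrence and stored
#' as the merge height. Ties in the minimal cost are broken by the lowest
#' (smallest-leaf-index, smallest-leaf-index) pair, lexicographically, so
#' results are deterministic across platforms.
#'
#' @param std numeric gene x sample matrix (typically from
#'   [zscoreStandardize()]); samples are the clustered units.
#' @return A [WardDendrogram-class].
#' @export
wardCluster <- function(std) {
  std <- as.matrix(std)
  n <- ncol(std)
  if (n < 2L) stop("at least 2 samples are required", call. = FALSE)
  labels <- colnames(std)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  X <- t(std)                       # samples x features
  # delta[i, j] = SSE increase if clusters i and j merge
  sq <- rowSums(X^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  d2[d2 < 0] <- 0
  delta <- d2 / 2
  diag(delta) <- Inf
  active <- rep(TRUE, n)
  sizes <- rep(1L, n)
  code <- -seq_len(n)               # hclust convention
  rep_ <- seq_len(n)                # smallest original leaf index per cluster
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- delta[idx, idx, drop = FALSE]
    mn <- min(sub)
    tol <- 1e-12 * max(1, abs(mn))
    cand <- which(sub <= mn + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pr <- cbind(rep_[idx[cand[, 1]]], rep_[idx[cand[, 2]]])
    pr <- cbind(pmin(pr[, 1], pr[, 2]), pmax(pr[, 1], pr[, 2]))
    best <- order(pr[, 1], pr[, 2])[1L]
    i <- idx[cand[best, 1]]; j <- idx[cand[best, 2]]
    if (rep_[i] > rep_[j]) { tmp <- i; i <- j; j <- tmp }
    height[step] <- delta[i, j]
    merge[step, ] <- .orderMergeCodes(code[i], code[j])
    ni <- sizes[i]; nj <- sizes[j]
    # Lance-Williams update of delta-SSE against every other active cluster
    others <- setdiff(which(active), c(i, j))
    if (length(others)) {
      nk <- sizes[others]
      delta[i, others] <- ((ni + nk) * delta[i, others] +
                           (nj + nk) * delta[j, others] -
                           nk * delta[i, j]) / (ni + nj + nk)
      delta[others, i] <- delta[i, others]
    }
    active[j] <- FALSE
    sizes[i] <- ni + nj
    code[i] <- step
    rep_[i] <- min(rep_[i], rep_[j])
    delta[j, ] <- Inf; delta[, j] <- Inf
    delta[i, i] <- Inf
  }
  methods::new("WardDendrogram", merge = merge, height = height,
               labels = labels)
}

# hclust puts singletons (negative codes) before merged clusters and orders
# within kind; keep that convention for interoperability.
.orderMergeCodes <- function(a, b) {
  if ((a < 0 && b < 0 && a > b) || (a > 0 && b > 0 && a > b) ||
      (a > 0 && b < 0)) c(b, a) else c(a, b)
}

#' Convert a WardDendrogram to hclust
#'
#' Heights are the delta-SSE merge costs; see [wardCluster()].
#'
#' @param x a [WardDendrogram-class].
#' @param ... ignored.
#' @return A [stats::hclust] object.
#' @export
as.hclust.WardDendrogram <- function(x, ...) {
  structure(list(merge = x@merge, height = x@height,
                 order = .dendroLeafOrder(x@merge),
                 labels = x@labels, method = "ward (delta-SSE)",
                 call = match.call(), dist.method = "squared euclidean"),
            class = "hclust")
}

.dendroLeafOrder <- function(merge) {
  getLeaves <- function(k) {
    if (k < 0) return(-k)
    c(getLeaves(merge[k, 1]), getLeaves(merge[k, 2]))
  }
  getLeaves(nrow(merge))
}

setMethod("show", "WardDendrogram", function(object) {
  cat(sprintf("WardDendrogram over %d samples (%d merges)\n",
              length(object@labels), length(object@height)))
  cat(sprintf("  delta-SSE heights: %.4g .. %.4g\n",
              min(object@height), max(object@height)))
})

#' Agglomeration schedule with rescaled heights
#'
#' @param dendro a [WardDendrogram-class].
#' @param schedule `"incremental"` (heights are per-merge delta-SSE) or
#'   `"cumulative"` (running total of delta-SSE, the SPSS agglomeration
#'   coefficient).
#' @return `data.frame` with `step`, `height`, `rescaled` (heights linearly
#'   mapped to 0..25 by `25 * h / max(h)`).
#' @export
mergeSchedule <- function(dendro, schedule = c("incremental", "cumulative")) {
  schedule <- match.arg(schedule)
  h <- dendro@height
  if (schedule == "cumulative") h <- cumsum(h)
  hmax <- max(h)
  resc <- if (hmax > 0) 25 * h / hmax else rep(0, length(h))
  data.frame(step = seq_along(h), height = h, rescaled = resc)
}

#' Cut a dendrogram at a rescaled distance
#'
#' Merge heights are linearly rescaled to the 0-25 dendrogram axis used by
#' SPSS (`h' = 25 * h / max(h)`); all merges with rescaled height at or
#' below `threshold` are applied and the resulting connected components form
#' the partition (so a cut at the top of the axis, 25, always yields a
#' single cluster). The conventional subgroup cut is at 20.
#'
#' @param dendro a [WardDendrogram-class].
#' @param threshold rescaled cut height in `(0, 25]` (default 20).
#' @param schedule rescale the incremental delta-SSE heights (default) or
#'   the cumulative agglomeration coefficients; see [mergeSchedule()].
#' @return Named integer vector mapping each sample to a cluster id (ids are
#'   1..k in order of first appearance).
#' @export
cutRescaled <- function(dendro, threshold = 20,
                        schedule = c("incremental", "cumulative")) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 25)
    stop("threshold must lie in (0, 25]", call. = FALSE)
  sched <- mergeSchedule(dendro, schedule)
  n <- length(dendro@labels)
  if (max(dendro@height) == 0) {
    warning("degenerate dendrogram (all merge heights 0); single cluster")
    return(stats::setNames(rep(1L, n), dendro@labels))
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  clusterOf <- integer(nrow(dendro@merge))  # leaf index representing merge k
  for (k in seq_len(nrow(dendro@merge))) {
    a <- dendro@merge[k, 1]; b <- dendro@merge[k, 2]
    ia <- if (a < 0) -a else clusterOf[a]
    ib <- if (b < 0) -b else clusterOf[b]
    if (sched$rescaled[k] <= threshold) {
      ra <- find(ia); rb <- find(ib)
      parent[max(ra, rb)] <- min(ra, rb)
    }
    clusterOf[k] <- ia
  }
  roots <- vapply(seq_len(n), find, integer(1))
  ids <- match(roots, unique(roots))
  stats::setNames(as.integer(ids), dendro@labels)
}

#' Label two clusters as HSR and LSR by directional concordance
#'
#' For each cluster the concordance score is the mean z-score over the
#' panel's UP genes minus the mean z-score over its DOWN genes
#' (VARIABLE genes are excluded from labeling). The cluster with the higher
#' concordance — higher expression of stress-elevated genes and lower
#' expression of stress-suppressed genes — is the high stress-response (HSR)
#' stratum; the other is LSR. An exact tie is an error rather than a silent
#' choice.
#'
#' @param partition named cluster assignment from [cutRescaled()]; must
#'   contain exactly 2 clusters.
#' @param std z-score matrix from [zscoreStandardize()] (panel genes x
#'   samples).
#' @param panel the [GenePanel-class] used for standardization; needs at
#'   least one UP and one DOWN gene.
#' @return A [StrataLabeling-class].
#' @export
labelStrata <- function(partition, std, panel) {
  ids <- sort(unique(partition))
  if (length(ids) != 2L)
    stop("labeling requires exactly 2 clusters (found ", length(ids),
         "); adjust the cut threshold", call. = FALSE)
  up <- upGenes(panel); down <- downGenes(panel)
  if (!length(up) || !length(down))
    stop("panel must contain at least one UP and one DOWN gene",
         call. = FALSE)
  miss <- setdiff(c(up, down), rownames(std))
  if (length(miss))
    stop("standardized matrix lacks panel gene(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  samples <- names(partition)
  if (is.null(samples) || !all(samples %in% colnames(std)))
    stop("partition names must match standardized matrix samples",
         call. = FALSE)
  conc <- vapply(ids, function(k) {
    cols <- samples[partition == k]
    mean(std[up, cols, drop = FALSE]) - mean(std[down, cols, drop = FALSE])
  }, numeric(1))
  if (abs(conc[1] - conc[2]) < 1e-12)
    stop("exact concordance tie between clusters; cannot label HSR/LSR",
         call. = FALSE)
  hsr <- ids[which.max(conc)]
  assignment <- ifelse(partition == hsr, "HSR", "LSR")
  names(assignment) <- samples
  methods::new("StrataLabeling", assignment = assignment,
               concordance = c(HSR = max(conc), LSR = min(conc)))
}

#' @describeIn StrataLabeling-class named HSR/LSR assignment per sample.
#' @param object a `StrataLabeling`.
#' @export
setGeneric("strataAssignment",
           function(object) standardGeneric("strataAssignment"))

#' @export
setMethod("strataAssignment", "StrataLabeling",
          function(object) object@assignment)

#' @describeIn StrataLabeling-class concordance scores of the two strata.
#' @export
setGeneric("strataConcordance",
           function(object) standardGeneric("strataConcordance"))

#' @export
setMethod("strataConcordance", "StrataLabeling",
          function(object) object@concordance)

setMethod("show", "StrataLabeling", function(object) {
  tab <- table(object@assignment)
  cat(sprintf("StrataLabeling: HSR n=%d (concordance %.3f), LSR n=%d (concordance %.3f)\n",
              tab[["HSR"]], object@concordance[["HSR"]],
              tab[["LSR"]], object@concordance[["LSR"]]))
})
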