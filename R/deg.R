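#' Two-group differential expression on log2(CPM + 1)
#'
#' Per gene, the two-sided pooled-variance Student t statistic between the
#' two groups is computed on `log2(CPM + 1)` (the pseudocount stabilizes the
#' variance of low-expression genes), and the log2 fold change is the
#' difference of group means on the same transformed scale
#' (group 1 - group 2). Genes with zero variance in both groups cannot be
#' tested and are excluded; their count is reported via a message and the
#' `"nExcluded"` attribute.
#'
#' @param object a [StressExperiment-class] or gene x sample CPM matrix.
#' @param groups named vector (sample -> group) with exactly two distinct
#'   values; a factor's level order, or sorted order otherwise, defines
#'   group 1 vs group 2. Each group needs >= 2 samples.
#' @return `data.frame` with columns `gene`, `t`, `p`, `log2fc`, ordered as
#'   the input genes (tested genes only).
#' @seealso [topGenes()], [overrepresentation()]
#' @export
differentialExpression <- function(object, groups) {
  m <- if (methods::is(object, "StressExperiment")) cpmValues(object)
       else as.matrix(object)
  if (is.null(names(groups)))
    stop("groups must be named by sample id", call. = FALSE)
  miss <- setdiff(names(groups), colnames(m))
  if (length(miss))
    stop("unknown sample(s) in groups: ", paste(miss, collapse = ", "),
         call. = FALSE)
  lv <- if (is.factor(groups)) levels(droplevels(groups))
        else sort(unique(as.character(groups)))
  if (length(lv) != 2L)
    stop("exactly two groups are required", call. = FALSE)
  g1 <- names(groups)[as.character(groups) == lv[1]]
  g2 <- names(groups)[as.character(groups) == lv[2]]
  if (length(g1) < 2L || length(g2) < 2L)
    stop("each group needs at least 2 samples", call. = FALSE)
  x <- log2(m[, g1, drop = FALSE] + 1)
  y <- log2(m[, g2, drop = FALSE] + 1)
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  df <- n1 + n2 - 2
  pooled <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  keep <- pooled > 0
  nExcluded <- sum(!keep)
  if (nExcluded > 0)
    message(nExcluded, " gene(s) with zero variance in both groups excluded")
  tstat <- (m1[keep] - m2[keep]) /
    sqrt(pooled[keep] * (1 / n1 + 1 / n2))
  res <- data.frame(gene = rownames(m)[keep], t = as.numeric(tstat),
                    p = 2 * stats::pt(-abs(tstat), df),
                    log2fc = as.numeric(m1[keep] - m2[keep]),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "nExcluded") <- nExcluded
  attr(res, "groups") <- lv
  res
}

#' Select the top-N genes by significance
#'
#' Sorts by ascending p-value, breaking ties by descending `|t|` and then
#' by gene id, so the selection is deterministic regardless of input order.
#' The conventional list size for downstream pathway analysis is 8000.
#'
#' @param records `data.frame` from [differentialExpression()].
#' @param n list size (default 8000); capped at the number of records.
#' @return Character vector of gene ids.
#' @export
topGenes <- function(records, n = 8000L) {
  if (!nrow(records)) stop("no DEG records", call. = FALSE)
  ord <- order(records$p, -abs(records$t), records$gene)
  records$gene[ord][seq_len(min(n, nrow(records)))]
}

#' Gene-set overrepresentation by the hypergeometric test
#'
#' For each set, members are intersected with the universe and the
#' right-tailed hypergeometric p-value
#' `P[X >= overlap | universe, set, list]` is computed, i.e. the chance of
#' at least the observed overlap if the list were drawn at random from the
#' universe. Benjamini-Hochberg q-values are computed across sets and the
#' result is sorted by ascending p (ties by set name).
#'
#' @param list character vector of selected genes (must be contained in
#'   `universe`), e.g. from [topGenes()].
#' @param sets a [GeneSetList-class].
#' @param universe character vector of all testable genes.
#' @param deg optional [differentialExpression()] table used to annotate
#'   each overlapping gene with its fold-change direction.
#' @return `data.frame` with `set`, `overlap`, `setSize` (within universe),
#'   `listSize`, `universeSize`, `p`, `q`, `overlapGenes` (";"-separated,
#'   with `+`/`-` direction suffixes when `deg` is given).
#' @export
overrepresentation <- function(list, sets, universe, deg = NULL) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  list <- unique(list)
  if (length(setdiff(list, universe)))
    stop("gene list is not contained in the universe", call. = FALSE)
  s <- geneSets(sets)
  if (!length(s))
    return(data.frame(set = character(), overlap = integer(),
                      setSize = integer(), listSize = integer(),
                      universeSize = integer(), p = numeric(), q = numeric(),
                      overlapGenes = character(), stringsAsFactors = FALSE))
  N <- length(universe); k <- length(list)
  rows <- lapply(names(s), function(nm) {
    members <- intersect(unique(s[[nm]]), universe)
    ov <- intersect(members, list)
    mSize <- length(members)
    p <- if (mSize == 0) 1 else
      stats::phyper(length(ov) - 1, mSize, N - mSize, k, lower.tail = FALSE)
    ovLab <- sort(ov)
    if (!is.null(deg) && length(ovLab)) {
      sgn <- ifelse(deg$log2fc[match(ovLab, deg$gene)] >= 0, "+", "-")
      ovLab <- paste0(ovLab, sgn)
    }
    data.frame(set = nm, overlap = length(ov), setSize = mSize,
               listSize = k, universeSize = N, p = p,
               overlapGenes = paste(ovLab, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- bhAdjust(res$p)
  res <- res[order(res$p, res$set), c("set", "overlap", "setSize",
                                      "listSize", "universeSize", "p", "q",
                                      "overlapGenes")]
  rownames(res) <- NULL
  res
}
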