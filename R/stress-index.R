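#' Assign quartile memberships
#'
#' Cut points Q1, Q2, Q3 are computed by [stats::quantile()] type 8
#' (linear interpolation between order statistics, median-unbiased), and
#' membership uses closed-right intervals: a value `v` falls in quartile 1
#' if `v <= Q1`, quartile 2 if `Q1 < v <= Q2`, quartile 3 if
#' `Q2 < v <= Q3`, and quartile 4 otherwise. A value exactly equal to a cut
#' point therefore lands deterministically in the lower quartile.
#'
#' @param values numeric vector with at least 4 values, not all identical.
#' @return Integer vector of quartiles 1..4, same length/order as `values`.
#' @examples
#' assignQuartiles(1:8)  # 1 1 2 2 3 3 4 4
#' @export
assignQuartiles <- function(values) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("missing values not allowed", call. = FALSE)
  if (length(values) < 4L)
    stop("at least 4 values are required for quartiles", call. = FALSE)
  if (max(values) == min(values))
    stop("all values identical; quartiles undefined", call. = FALSE)
  q <- stats::quantile(values, probs = c(0.25, 0.5, 0.75), type = 8,
                       names = FALSE)
  as.integer(1L + (values > q[1]) + (values > q[2]) + (values > q[3]))
}

.HSR_WEIGHTS <- c(-3L, -1L, 1L, 3L)   # quartiles 1..4, gene high in HSR
.LSR_WEIGHTS <- c(3L, 1L, -1L, -3L)   # quartiles 1..4, gene high in LSR

#' Quartile-weighted stress-response index
#'
#' For every subject in `subjects`, each index-panel gene contributes a
#' weight determined by the subject's within-subset quartile of that gene's
#' expression: quartiles 1..4 score (-3, -1, 1, 3) for genes higher in the
#' high stress-response group and (3, 1, -1, -3) for genes higher in the
#' low stress-response group. The stress-response index is the sum of the
#' weights; subjects with index > 0 are classed HSR, < 0 LSR, and exactly 0
#' INDETERMINATE (the scoring rule defines only the strict inequalities).
#' Quartiles are computed within `subjects` only — classifying controls uses
#' control-only quartiles.
#'
#' @param object a [StressExperiment-class] or gene x sample CPM matrix.
#' @param indexPanel an [IndexPanel-class]; all its genes must be present.
#' @param subjects character vector of sample ids to score (default: all
#'   samples of `object`).
#' @return A [StressIndexResult-class].
#' @export
stressResponseIndex <- function(object, indexPanel, subjects = NULL) {
  m <- if (methods::is(object, "StressExperiment")) cpmValues(object)
       else as.matrix(object)
  if (is.null(subjects)) subjects <- colnames(m)
  miss <- setdiff(subjects, colnames(m))
  if (length(miss))
    stop("unknown sample(s): ", paste(miss, collapse = ", "), call. = FALSE)
  e <- panelEntries(indexPanel)
  idx <- .resolvePanelRows(e$symbol, e$alias, rownames(m))
  sub <- m[idx, subjects, drop = FALSE]
  rownames(sub) <- e$symbol
  quart <- matrix(NA_integer_, nrow(sub), ncol(sub),
                  dimnames = dimnames(sub))
  for (g in seq_len(nrow(sub))) {
    quart[g, ] <- tryCatch(assignQuartiles(sub[g, ]),
                           error = function(err)
                             stop("gene ", e$symbol[g], ": ",
                                  conditionMessage(err), call. = FALSE))
  }
  wts <- matrix(0L, nrow(sub), ncol(sub))
  for (g in seq_len(nrow(sub))) {
    w <- if (e$direction[g] == "HIGH_IN_HSR") .HSR_WEIGHTS else .LSR_WEIGHTS
    wts[g, ] <- w[quart[g, ]]
  }
  score <- stats::setNames(as.integer(colSums(wts)), colnames(sub))
  cls <- vapply(score, classifyByIndex, character(1))
  methods::new("StressIndexResult", score = score, quartiles = quart,
               classification = cls)
}

#' Classify a stress-response index score
#'
#' @param score integer index score.
#' @return `"HSR"` if score > 0, `"LSR"` if score < 0, else
#'   `"INDETERMINATE"` (with a warning: the boundary is undefined by the
#'   scoring rule).
#' @export
classifyByIndex <- function(score) {
  if (score > 0) "HSR"
  else if (score < 0) "LSR"
  else {
    warning("stress-response index of 0 is indeterminate", call. = FALSE)
    "INDETERMINATE"
  }
}

#' @describeIn StressIndexResult-class named integer scores.
#' @param object a `StressIndexResult`.
#' @export
setGeneric("indexScores", function(object) standardGeneric("indexScores"))

#' @export
setMethod("indexScores", "StressIndexResult", function(object) object@score)

#' @describeIn StressIndexResult-class named HSR/LSR/INDETERMINATE classes.
#' @export
setGeneric("indexClasses", function(object) standardGeneric("indexClasses"))

#' @export
setMethod("indexClasses", "StressIndexResult", function(object) object@classification)

#' @describeIn StressIndexResult-class gene x subject quartile memberships.
#' @export
setGeneric("quartileDetail", function(object) standardGeneric("quartileDetail"))

#' @export
setMethod("quartileDetail", "StressIndexResult",
          function(object) object@quartiles)

setMethod("show", "StressIndexResult", function(object) {
  tab <- table(factor(object@classification, c("HSR", "LSR", "INDETERMINATE")))
  cat(sprintf("StressIndexResult for %d subject(s) over %d gene(s)\n",
              length(object@score), nrow(object@quartiles)))
  cat(sprintf("  classes: HSR=%d, LSR=%d, INDETERMINATE=%d\n",
              tab[["HSR"]], tab[["LSR"]], tab[["INDETERMINATE"]]))
  cat(sprintf("  scores: %d .. %d\n", min(object@score), max(object@score)))
})
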