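#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of gene symbols; names must be
#'   unique and every set non-empty.
#' @return A [GeneSetList-class].
#' @examples
#' GeneSetList(list(DSB_HR = c("MRE11", "BRCA2", "ATRX")))
#' @export
GeneSetList <- function(sets = list()) {
  sets <- lapply(sets, as.character)
  methods::new("GeneSetList", sets = sets)
}

#' @describeIn GeneSetList-class the underlying named list of member vectors.
#' @param object a `GeneSetList`.
#' @export
setGeneric("geneSets", function(object) standardGeneric("geneSets"))

#' @export
setMethod("geneSets", "GeneSetList", function(object) object@sets)

#' @export
setMethod("length", "GeneSetList", function(x) length(x@sets))

#' @export
setMethod("names", "GeneSetList", function(x) names(x@sets))

#' @export
setMethod("[[", "GeneSetList", function(x, i) x@sets[[i]])

setMethod("show", "GeneSetList", function(object) {
  cat(sprintf("GeneSetList with %d set(s)\n", length(object@sets)))
  if (length(object@sets)) {
    sz <- lengths(object@sets)
    n <- min(5L, length(sz))
    for (i in seq_len(n))
      cat(sprintf("  %s (%d genes)\n", names(object@sets)[i], sz[i]))
    if (length(sz) > n) cat(sprintf("  ... and %d more\n", length(sz) - n))
  }
})
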