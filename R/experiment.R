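#' Construct a StressExperiment
#'
#' Bundles a CPM expression matrix (genes x samples) with per-sample clinical
#' metadata into a validated [StressExperiment-class].
#'
#' @param cpm numeric matrix of non-negative CPM values with gene row names
#'   and sample column names.
#' @param metadata `data.frame` or `DataFrame` of per-sample covariates, one
#'   row per column of `cpm` (matched by row names when present, otherwise by
#'   position). May be omitted for purely expression-level work.
#' @return A [StressExperiment-class].
#' @examples
#' m <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' StressExperiment(m)
#' @export
StressExperiment <- function(cpm, metadata = NULL) {
  cpm <- as.matrix(cpm)
  storage.mode(cpm) <- "double"
  if (is.null(metadata)) {
    metadata <- S4Vectors::DataFrame(row.names = colnames(cpm))
  } else {
    metadata <- S4Vectors::DataFrame(metadata)
    if (!is.null(rownames(metadata)) &&
        !identical(rownames(metadata), as.character(seq_len(nrow(metadata))))) {
      miss <- setdiff(colnames(cpm), rownames(metadata))
      if (length(miss))
        stop("metadata missing sample(s): ", paste(miss, collapse = ", "),
             call. = FALSE)
      metadata <- metadata[colnames(cpm), , drop = FALSE]
    } else if (nrow(metadata) != ncol(cpm)) {
      stop("metadata must have one row per sample", call. = FALSE)
    }
    rownames(metadata) <- colnames(cpm)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(cpm = cpm), colData = metadata)
  methods::new("StressExperiment", se)
}

#' Extract the CPM matrix
#'
#' @param object a [StressExperiment-class].
#' @return The gene x sample CPM matrix.
#' @export
setGeneric("cpmValues", function(object) standardGeneric("cpmValues"))

#' @rdname cpmValues
#' @export
setMethod("cpmValues", "StressExperiment", function(object)
  SummarizedExperiment::assay(object, "cpm"))

#' Extract sample metadata as a data.frame
#'
#' @param object a [StressExperiment-class].
#' @return `data.frame` of per-sample covariates.
#' @export
setGeneric("sampleMetadata", function(object) standardGeneric("sampleMetadata"))

#' @rdname sampleMetadata
#' @export
setMethod("sampleMetadata", "StressExperiment", function(object)
  as.data.frame(SummarizedExperiment::colData(object)))

#' Subset to samples of one diagnosis
#'
#' @param object a [StressExperiment-class] whose metadata carries `diagnosis`.
#' @param diagnosis `"SZ"` or `"CONTROL"`.
#' @return A [StressExperiment-class] restricted to the requested samples.
#' @export
subsetByDiagnosis <- function(object, diagnosis = c("SZ", "CONTROL")) {
  diagnosis <- match.arg(diagnosis)
  cd <- SummarizedExperiment::colData(object)
  if (!"diagnosis" %in% names(cd))
    stop("metadata does not carry a 'diagnosis' column", call. = FALSE)
  object[, !is.na(cd$diagnosis) & as.character(cd$diagnosis) == diagnosis]
}

setMethod("show", "StressExperiment", function(object) {
  cat(sprintf("StressExperiment: %d gene(s) x %d sample(s) [assay: cpm]\n",
              nrow(object), ncol(object)))
  cd <- SummarizedExperiment::colData(object)
  if ("diagnosis" %in% names(cd)) {
    tab <- table(as.character(cd$diagnosis))
    cat("  diagnosis:", paste(sprintf("%s=%d", names(tab), tab),
                              collapse = ", "), "\n")
  }
  if (length(names(cd)))
    cat("  covariates:", paste(names(cd), collapse = ", "), "\n")
})
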