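#' Read an expression matrix from TSV or MatrixMarket files
#'
#' The TSV dialect stores genes in rows with the gene id in the first column
#' (header `gene_id`) and one column per sample. The MTX dialect stores the
#' dense or sparse matrix in MatrixMarket format with sidecar plain-text
#' files listing the row (gene) and column (sample) names, one per line.
#' Parsing uses the C locale decimal point regardless of the session locale.
#'
#' @param path path to the TSV or MTX file.
#' @param format `"TSV"` (default) or `"MTX"`.
#' @param metadata optional path to a sample-metadata TSV
#'   (see [readSampleMetadata()]).
#' @param rowNamesPath,colNamesPath sidecar name files for `format = "MTX"`;
#'   default `<path>.rownames` / `<path>.colnames`.
#' @return A [StressExperiment-class] with genes in file order.
#' @seealso [writeExpression()]
#' @export
readExpression <- function(path, format = c("TSV", "MTX"), metadata = NULL,
                           rowNamesPath = paste0(path, ".rownames"),
                           colNamesPath = paste0(path, ".colnames")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "TSV") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = NA,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2L)
      stop("expression TSV needs a gene_id column plus at least one sample",
           call. = FALSE)
    ids <- as.character(tab[[1L]])
    if (anyDuplicated(ids))
      stop("duplicate gene id(s) in ", path, ": ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "),
           call. = FALSE)
    m <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric expression values in ", path,
                             call. = FALSE)
    rownames(m) <- ids
  } else {
    mm <- as.matrix(Matrix::readMM(path))
    if (!file.exists(rowNamesPath) || !file.exists(colNamesPath))
      stop("MTX sidecar name files not found: ", rowNamesPath, " / ",
           colNamesPath, call. = FALSE)
    rn <- readLines(rowNamesPath)
    cn <- readLines(colNamesPath)
    if (length(rn) != nrow(mm) || length(cn) != ncol(mm))
      stop("sidecar name files do not match MTX dimensions", call. = FALSE)
    if (anyDuplicated(rn))
      stop("duplicate gene id(s) in ", rowNamesPath, ": ",
           paste(unique(rn[duplicated(rn)]), collapse = ", "), call. = FALSE)
    dimnames(mm) <- list(rn, cn)
    m <- mm
  }
  if (anyNA(m) || any(m < 0))
    stop("expression values must be non-negative and non-missing",
         call. = FALSE)
  md <- if (!is.null(metadata)) readSampleMetadata(metadata) else NULL
  StressExperiment(m, md)
}

#' Write an expression matrix
#'
#' @param object a [StressExperiment-class] or plain matrix.
#' @param path destination file.
#' @param format `"TSV"` or `"MTX"` (writes sidecar `.rownames`/`.colnames`).
#' @return `path`, invisibly.
#' @export
writeExpression <- function(object, path, format = c("TSV", "MTX")) {
  format <- match.arg(format)
  m <- if (methods::is(object, "StressExperiment")) cpmValues(object)
       else as.matrix(object)
  if (format == "TSV") {
    tab <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    writeLines(rownames(m), paste0(path, ".rownames"))
    writeLines(colnames(m), paste0(path, ".colnames"))
  }
  invisible(path)
}

.META_COLS <- c("diagnosis", "age_years", "sex", "rin", "pmi_hours",
                "cpz_eq_mg", "family_history", "death_category")

#' Read or write a sample-metadata table
#'
#' Tab-separated with a `sample_id` column; recognized covariates are
#' `diagnosis` (SZ/CONTROL), `age_years`, `sex` (F/M), `rin`, `pmi_hours`,
#' `cpz_eq_mg`, `family_history` (present/absent/unknown) and
#' `death_category` (inflammatory/non_inflammatory/malignancy). Missing
#' values are kept as explicit `NA`/`"unknown"`, never dropped.
#'
#' @param path file path.
#' @return `data.frame` with `sample_id` row names.
#' @export
readSampleMetadata <- function(path) {
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!"sample_id" %in% names(md))
    stop("metadata requires a sample_id column", call. = FALSE)
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample id(s) in metadata", call. = FALSE)
  rownames(md) <- md$sample_id
  md$sample_id <- NULL
  if ("family_history" %in% names(md))
    md$family_history[is.na(md$family_history)] <- "unknown"
  md
}

#' @rdname readSampleMetadata
#' @param metadata `data.frame` of covariates with sample row names.
#' @export
writeSampleMetadata <- function(metadata, path) {
  out <- data.frame(sample_id = rownames(metadata), metadata,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene panel from YAML
#'
#' Expects a top-level `panel:` sequence of `symbol` / `direction` (and
#' optional `alias`) mappings. Directions must be `UP`/`DOWN`/`VARIABLE` for
#' `type = "stress"` and `HIGH_IN_HSR`/`HIGH_IN_LSR` for `type = "index"`;
#' anything else is rejected.
#'
#' @param path YAML file.
#' @param type `"stress"` (clustering panel) or `"index"` (index panel).
#' @return A [GenePanel-class] or [IndexPanel-class].
#' @seealso [writePanel()], [defaultStressPanel()], [defaultIndexPanel()]
#' @export
readPanel <- function(path, type = c("stress", "index")) {
  type <- match.arg(type)
  y <- yaml::read_yaml(path)
  entries <- y[["panel"]]
  if (is.null(entries)) stop("no 'panel' key in ", path, call. = FALSE)
  sym <- vapply(entries, function(e) {
    if (is.null(e$symbol)) stop("panel entry without a symbol in ", path,
                                call. = FALSE)
    as.character(e$symbol)
  }, character(1))
  dir <- vapply(entries, function(e) {
    if (is.null(e$direction)) stop("panel entry without a direction in ",
                                   path, call. = FALSE)
    as.character(e$direction)
  }, character(1))
  ali <- vapply(entries, function(e)
    if (is.null(e$alias)) NA_character_ else as.character(e$alias),
    character(1))
  if (type == "stress") GenePanel(sym, dir, ali) else IndexPanel(sym, dir, ali)
}

#' Write a gene panel to YAML
#'
#' @param panel a [GenePanel-class] or [IndexPanel-class].
#' @param path destination YAML file.
#' @export
writePanel <- function(panel, path) {
  e <- panelEntries(panel)
  lst <- lapply(seq_len(nrow(e)), function(i) {
    entry <- list(symbol = e$symbol[i], direction = e$direction[i])
    if (!is.na(e$alias[i]) && nzchar(e$alias[i])) entry$alias <- e$alias[i]
    entry
  })
  yaml::write_yaml(list(panel = lst), path)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then one or more member symbols. The description is kept
#' out of computation.
#'
#' @param path GMT file.
#' @return A [GeneSetList-class]; an empty file yields an empty collection.
#' @seealso [writeGMT()]
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(GeneSetList())
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("malformed GMT line (need name, description, >=1 member): ",
           substr(ln, 1, 60), call. = FALSE)
    nm <- trimws(f[1L])
    if (nm %in% names(sets))
      stop("duplicate set name in ", path, ": ", nm, call. = FALSE)
    members <- trimws(f[-(1:2)])
    sets[[nm]] <- members[nzchar(members)]
  }
  GeneSetList(sets)
}

#' Write gene sets in GMT format
#'
#' @param object a [GeneSetList-class].
#' @param path destination file.
#' @param description description field written for every set.
#' @export
writeGMT <- function(object, path, description = "na") {
  s <- geneSets(object)
  lines <- vapply(seq_along(s), function(i)
    paste(c(names(s)[i], description, s[[i]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
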