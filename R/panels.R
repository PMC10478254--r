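#' Construct a stress-responsive gene panel
#'
#' @param symbol character vector of gene symbols.
#' @param direction character vector of expected directions under stress:
#'   `"UP"`, `"DOWN"` or `"VARIABLE"`.
#' @param alias optional character vector of alternative symbols (protein
#'   names, legacy symbols) matched against expression matrices when the
#'   primary symbol is absent; `NA` where not needed.
#' @return A [GenePanel-class] object.
#' @examples
#' GenePanel(c("IL6", "BDNF"), c("UP", "DOWN"))
#' @export
GenePanel <- function(symbol, direction, alias = NA_character_) {
  e <- data.frame(symbol = trimws(as.character(symbol)),
                  direction = as.character(direction),
                  alias = trimws(as.character(rep_len(alias, length(symbol)))),
                  stringsAsFactors = FALSE)
  methods::new("GenePanel", entries = e)
}

#' Construct a stress-response index panel
#'
#' @param symbol character vector of gene symbols.
#' @param direction `"HIGH_IN_HSR"` (quartiles 1..4 score -3, -1, 1, 3) or
#'   `"HIGH_IN_LSR"` (quartiles 1..4 score 3, 1, -1, -3) per gene.
#' @param alias optional alternative symbols, as in [GenePanel()].
#' @return An [IndexPanel-class] object.
#' @export
IndexPanel <- function(symbol, direction, alias = NA_character_) {
  e <- data.frame(symbol = trimws(as.character(symbol)),
                  direction = as.character(direction),
                  alias = trimws(as.character(rep_len(alias, length(symbol)))),
                  stringsAsFactors = FALSE)
  methods::new("IndexPanel", entries = e)
}

#' @describeIn GenePanel-class the entries `data.frame`.
#' @param object a `GenePanel` or `IndexPanel`.
#' @export
setGeneric("panelEntries", function(object) standardGeneric("panelEntries"))

#' @export
setMethod("panelEntries", "GenePanel", function(object) object@entries)

#' @export
setMethod("panelEntries", "IndexPanel", function(object) object@entries)

#' Panel genes by direction class
#'
#' @param panel a [GenePanel-class].
#' @return Character vector of gene symbols.
#' @export
upGenes <- function(panel) {
  e <- panelEntries(panel)
  e$symbol[e$direction == "UP"]
}

#' @rdname upGenes
#' @export
downGenes <- function(panel) {
  e <- panelEntries(panel)
  e$symbol[e$direction == "DOWN"]
}

#' @rdname upGenes
#' @export
variableGenes <- function(panel) {
  e <- panelEntries(panel)
  e$symbol[e$direction == "VARIABLE"]
}

setMethod("show", "GenePanel", function(object) {
  e <- object@entries
  cat(sprintf("GenePanel with %d gene(s): %d UP, %d DOWN, %d VARIABLE\n",
              nrow(e), sum(e$direction == "UP"), sum(e$direction == "DOWN"),
              sum(e$direction == "VARIABLE")))
  cat(" ", paste(e$symbol, collapse = ", "), "\n")
})

setMethod("show", "IndexPanel", function(object) {
  e <- object@entries
  cat(sprintf("IndexPanel with %d gene(s): %d HIGH_IN_HSR, %d HIGH_IN_LSR\n",
              nrow(e), sum(e$direction == "HIGH_IN_HSR"),
              sum(e$direction == "HIGH_IN_LSR")))
  cat(" ", paste(e$symbol, collapse = ", "), "\n")
})

#' Default 19-gene stress-responsive panel
#'
#' The stress-responsive molecules used for stratification: seven genes
#' reported to increase under stress (IL1B, IL6, IFNG, TNF, SOD1-3), seven
#' reported to decrease (BDNF, IL10, DLG4, SYP, SNCA, SNCB, SNCG), and five
#' with inconsistent reported direction (APOA1, APOA2, NR3C1, S100B, SLC6A4).
#' Protein-name aliases (e.g. PSD95 for DLG4, GR for NR3C1) are carried so
#' matrices keyed by either symbol resolve.
#'
#' @return A [GenePanel-class] of 19 entries.
#' @export
defaultStressPanel <- function() {
  GenePanel(
    symbol = c("IL1B", "IL6", "IFNG", "TNF", "SOD1", "SOD2", "SOD3",
               "BDNF", "IL10", "DLG4", "SYP", "SNCA", "SNCB", "SNCG",
               "APOA1", "APOA2", "NR3C1", "S100B", "SLC6A4"),
    direction = c(rep("UP", 7), rep("DOWN", 7), rep("VARIABLE", 5)),
    alias = c(NA, NA, NA, "TNFA", NA, NA, NA,
              NA, NA, "PSD95", NA, NA, NA, NA,
              NA, NA, "GR", NA, "5HTT")
  )
}

#' Default ten-gene stress-response index panel
#'
#' Genes entering the quartile-weighted stress-response index for control
#' subjects: IL6, IFNG, SOD2, NR3C1 (GR), APOA1 and SLC6A4 are scored as
#' higher-in-HSR; BDNF, SYP, DLG4 (PSD95) and SNCA as higher-in-LSR.
#'
#' @return An [IndexPanel-class] of 10 entries.
#' @export
defaultIndexPanel <- function() {
  IndexPanel(
    symbol = c("IL6", "IFNG", "SOD2", "NR3C1", "APOA1", "SLC6A4",
               "BDNF", "SYP", "DLG4", "SNCA"),
    direction = c(rep("HIGH_IN_HSR", 6), rep("HIGH_IN_LSR", 4)),
    alias = c(NA, NA, NA, "GR", NA, NA, NA, NA, "PSD95", NA)
  )
}

# Resolve panel symbols against matrix row names: case-insensitive after
# trimming, falling back to the alias column. Errors name the missing gene.
.resolvePanelRows <- function(symbols, aliases, geneIds) {
  key <- toupper(trimws(geneIds))
  idx <- match(toupper(trimws(symbols)), key)
  useAlias <- is.na(idx) & !is.na(aliases) & nzchar(aliases)
  idx[useAlias] <- match(toupper(trimws(aliases[useAlias])), key)[seq_len(sum(useAlias))]
  if (anyNA(idx))
    stop("panel gene(s) not found in expression matrix: ",
         paste(symbols[is.na(idx)], collapse = ", "), call. = FALSE)
  if (anyDuplicated(idx))
    stop("panel genes resolve to duplicated matrix rows", call. = FALSE)
  idx
}
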