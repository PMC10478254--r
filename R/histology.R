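#' Construct a stain model
#'
#' @param vectors 3 x 2 or 3 x 3 numeric matrix of non-negative
#'   optical-density triplets, one column per stain; columns are normalized
#'   to unit L2 norm. With two stains a residual third basis vector
#'   (normalized cross product) is used internally for deconvolution.
#' @param names optional stain names.
#' @return A [StainModel-class].
#' @export
StainModel <- function(vectors, names = NULL) {
  v <- as.matrix(vectors)
  nrm <- sqrt(colSums(v^2))
  if (any(nrm == 0)) stop("zero stain vector", call. = FALSE)
  v <- sweep(v, 2L, nrm, "/")
  if (!is.null(names)) colnames(v) <- names
  methods::new("StainModel", vectors = v)
}

#' @describeIn StainModel-class the 3 x k matrix of unit OD vectors.
#' @param object a `StainModel`.
#' @export
setGeneric("stainVectors", function(object) standardGeneric("stainVectors"))

#' @export
setMethod("stainVectors", "StainModel", function(object) object@vectors)

setMethod("show", "StainModel", function(object) {
  v <- object@vectors
  cat(sprintf("StainModel with %d stain(s)\n", ncol(v)))
  nm <- colnames(v)
  for (i in seq_len(ncol(v)))
    cat(sprintf("  %s: (%.3f, %.3f, %.3f)\n",
                if (is.null(nm)) paste0("stain", i) else nm[i],
                v[1, i], v[2, i], v[3, i]))
})

#' Default DAB + methyl green stain model
#'
#' The DAB column is the widely published brightfield DAB optical-density
#' triplet (0.268, 0.570, 0.776). Methyl green has no canonical published
#' vector; the shipped value (0.620, 0.200, 0.760) was estimated once from
#' a pure-stain synthetic fixture (a green-transmitting nuclear stain
#' absorbs mostly in red and blue) and can be overridden via [StainModel()].
#'
#' @return A [StainModel-class] with stains `DAB` and `MG`.
#' @export
defaultStainModel <- function() {
  StainModel(cbind(c(0.268, 0.570, 0.776), c(0.620, 0.200, 0.760)),
             names = c("DAB", "MG"))
}

# Complete a 2-stain basis with the normalized cross product and invert.
.stainInverse <- function(stains) {
  v <- stainVectors(stains)
  if (ncol(v) == 2L) {
    res <- .crossProduct(v[, 1], v[, 2])
    res <- res / sqrt(sum(res^2))
    v <- cbind(v, residual = res)
  }
  if (abs(det(v)) < 1e-8)
    stop("stain vectors are collinear; deconvolution basis is singular",
         call. = FALSE)
  solve(v)
}

#' Color deconvolution of an RGB brightfield image
#'
#' Converts each pixel to optical densities
#' `OD_c = -log10(max(I_c, 1) / 255)` per RGB channel (Beer-Lambert), then
#' projects the OD vector through the inverse of the stain matrix to obtain
#' per-stain concentration (amplitude) images. Negative concentrations are
#' clipped to 0.
#'
#' @param image height x width x 3 numeric array with values in 0..255.
#' @param stains a [StainModel-class].
#' @return Named list of height x width concentration matrices, one per
#'   stain (plus `residual` for a 2-stain model).
#' @export
colorDeconvolve <- function(image, stains = defaultStainModel()) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("an RGB (height x width x 3) image is required", call. = FALSE)
  inv <- .stainInverse(stains)
  h <- dim(image)[1]; w <- dim(image)[2]
  od <- -log10(pmax(image, 1) / 255)
  odm <- matrix(od, h * w, 3L)
  conc <- odm %*% t(inv)
  conc[conc < 0] <- 0
  nm <- colnames(stainVectors(stains))
  if (is.null(nm)) nm <- paste0("stain", seq_len(ncol(stainVectors(stains))))
  if (ncol(conc) == 3L && length(nm) == 2L) nm <- c(nm, "residual")
  out <- lapply(seq_len(ncol(conc)), function(k) matrix(conc[, k], h, w))
  names(out) <- nm
  out
}

#' Isodata (iterative intermeans) threshold
#'
#' Finds the fixed point of `t = (mean(values <= t) + mean(values > t)) / 2`
#' starting from the mid-range, and returns the mask of pixels strictly
#' above the threshold.
#'
#' @param channel numeric matrix (e.g. a concentration image) with at least
#'   two distinct values.
#' @return Logical matrix mask with attribute `"threshold"`.
#' @export
isodataThreshold <- function(channel) {
  v <- sort(as.numeric(channel))
  n <- length(v)
  if (v[1] == v[n])
    stop("constant channel; nothing to separate", call. = FALSE)
  cums <- cumsum(v)
  t <- (v[1] + v[n]) / 2
  for (i in seq_len(200L)) {
    k <- findInterval(t, v)           # values <= t
    if (k >= n) { t <- v[n - 1L]; next }
    if (k < 1L) { t <- v[1L]; next }
    tNew <- (cums[k] / k + (cums[n] - cums[k]) / (n - k)) / 2
    if (abs(tNew - t) < 1e-9) { t <- tNew; break }
    t <- tNew
  }
  mask <- channel > t
  attr(mask, "threshold") <- t
  mask
}

#' Particle analysis with area and circularity filters
#'
#' Labels 8-connected components of a binary mask, measures each
#' component's area (pixel count), boundary-walk perimeter (outer contour
#' traced with unit steps for axial moves and sqrt(2) for diagonal moves),
#' and circularity `min(1, 4 pi area / perimeter^2)`, and keeps particles
#' with `area >= minArea` and circularity within `circularityRange`. The
#' conventional filters for TUNEL counting are a 2000 px^2 minimum and
#' circularity 0.1-1.
#'
#' @param mask logical matrix.
#' @param minArea minimum particle area in px^2 (default 2000).
#' @param circularityRange inclusive circularity bounds (default
#'   `c(0.1, 1)`).
#' @return `data.frame` with one row per kept particle: `label`, `area`,
#'   `perimeter`, `circularity`, `centroidRow`, `centroidCol`. The full
#'   unfiltered table is attached as attribute `"all"`.
#' @export
particleAnalysis <- function(mask, minArea = 2000L,
                             circularityRange = c(0.1, 1)) {
  mask <- mask != 0
  lab <- .label8(mask)
  nlab <- max(lab)
  empty <- data.frame(label = integer(), area = integer(),
                      perimeter = numeric(), circularity = numeric(),
                      centroidRow = numeric(), centroidCol = numeric())
  if (nlab == 0L) { attr(empty, "all") <- empty; return(empty) }
  areas <- tabulate(lab[lab > 0], nbins = nlab)
  idx <- which(lab > 0)
  rows <- ((idx - 1L) %% nrow(lab)) + 1L
  cols <- ((idx - 1L) %/% nrow(lab)) + 1L
  labs <- lab[idx]
  cr <- vapply(split(rows, labs), mean, numeric(1))
  cc <- vapply(split(cols, labs), mean, numeric(1))
  per <- vapply(seq_len(nlab), function(k) .tracePerimeter(lab, k), numeric(1))
  circ <- ifelse(per > 0, pmin(1, 4 * pi * areas / per^2), 1)
  all <- data.frame(label = seq_len(nlab), area = areas, perimeter = per,
                    circularity = circ, centroidRow = as.numeric(cr),
                    centroidCol = as.numeric(cc))
  keep <- all[all$area >= minArea &
              all$circularity >= circularityRange[1] &
              all$circularity <= circularityRange[2], , drop = FALSE]
  rownames(keep) <- NULL
  attr(keep, "all") <- all
  keep
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels touching
# diagonally are merged afterwards with a union-find pass.
.label8 <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask)))
  lab <- matrix(as.integer(round(lab)), nrow(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  pairUp <- function(a, b) {
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) {
      pr <- unique(cbind(a[sel], b[sel]))
      for (k in seq_len(nrow(pr))) union(pr[k, 1], pr[k, 2])
    }
  }
  # diagonal neighbours: down-right and down-left
  pairUp(lab[-nr, -nc], lab[-1, -1])
  pairUp(lab[-nr, -1], lab[-1, -nc])
  roots <- vapply(seq_len(n), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- remap[lab[lab > 0L]]
  out
}

# Outer-boundary perimeter by Moore-neighbour tracing; axial steps count 1,
# diagonal steps sqrt(2). Single-pixel components have perimeter 0 (their
# circularity is defined as 1).
.tracePerimeter <- function(lab, k) {
  nr <- nrow(lab); nc <- ncol(lab)
  inside <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc &&
    lab[r, c] == k
  idx <- which(lab == k)
  if (length(idx) == 1L) return(0)
  # start: smallest column, then smallest row (uppermost-leftmost)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  o <- order(cols, rows)
  r0 <- rows[o[1]]; c0 <- cols[o[1]]
  # Moore neighbourhood, clockwise starting from W
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  stepLen <- ifelse(dr != 0L & dc != 0L, sqrt(2), 1)
  per <- 0
  r <- r0; c <- c0
  dir <- 1L  # came from the W (backtrack direction index)
  firstState <- NULL
  maxSteps <- 4L * (nr + nc) + 4L * length(idx)
  for (step in seq_len(maxSteps)) {
    d <- NA_integer_
    for (s in 0:7) {
      cand <- ((dir - 1L + s) %% 8L) + 1L
      if (inside(r + dr[cand], c + dc[cand])) { d <- cand; break }
    }
    if (is.na(d)) return(per)  # no traversable neighbour
    state <- c(r, c, d)
    if (!is.null(firstState) && all(state == firstState)) return(per)
    if (is.null(firstState)) firstState <- state
    per <- per + stepLen[d]
    r <- r + dr[d]; c <- c + dc[d]
    # next search starts one step clockwise from the backtrack direction
    dir <- ((d + 4L) %% 8L) + 1L
  }
  per
}

#' TUNEL positivity rate
#'
#' @param tunelParticles,counterstainParticles non-negative particle counts
#'   for the TUNEL (DAB) and counterstain (methyl green) channels.
#' @return `tunel / (tunel + counterstain)`; both counts zero is an error
#'   (the rate is undefined for an empty field).
#' @export
tunelPositivity <- function(tunelParticles, counterstainParticles) {
  if (tunelParticles < 0 || counterstainParticles < 0)
    stop("counts must be non-negative", call. = FALSE)
  tot <- tunelParticles + counterstainParticles
  if (tot == 0)
    stop("no particles in either channel; positivity rate undefined",
         call. = FALSE)
  tunelParticles / tot
}

#' Quantify a single histology field
#'
#' Runs the per-field chain: color deconvolution into DAB and counterstain
#' concentration channels, isodata thresholding of each channel, and
#' particle analysis under the area/circularity filters.
#'
#' @param image height x width x 3 array in 0..255.
#' @param stains a [StainModel-class].
#' @param minArea,circularityRange particle filters (see
#'   [particleAnalysis()]).
#' @return List with `nTunel`, `nCounterstain`, `rate` (`NA` if no
#'   particles at all), and the kept particle tables `tunelParticles`,
#'   `counterstainParticles`.
#' @export
quantifyField <- function(image, stains = defaultStainModel(),
                          minArea = 2000L, circularityRange = c(0.1, 1)) {
  conc <- colorDeconvolve(image, stains)
  pT <- particleAnalysis(isodataThreshold(conc[[1L]]), minArea,
                         circularityRange)
  pC <- particleAnalysis(isodataThreshold(conc[[2L]]), minArea,
                         circularityRange)
  nT <- nrow(pT); nC <- nrow(pC)
  rate <- if (nT + nC > 0) nT / (nT + nC) else NA_real_
  list(nTunel = nT, nCounterstain = nC, rate = rate,
       tunelParticles = pT, counterstainParticles = pC)
}

#' Quantify a case from multiple fields
#'
#' Applies [quantifyField()] to each field image (six fields per case is
#' the convention) and pools particle counts across fields before forming
#' the case-level TUNEL positivity rate — pooling counts rather than
#' averaging per-field rates keeps fields with few cells from dominating.
#' A field whose thresholding fails (e.g. a constant channel) is skipped
#' with a warning; if every field fails, an error is raised.
#'
#' @param fields list of height x width x 3 arrays.
#' @param stains a [StainModel-class].
#' @param minArea,circularityRange particle filters.
#' @return A [QuantResult-class].
#' @export
quantifyCase <- function(fields, stains = defaultStainModel(),
                         minArea = 2000L, circularityRange = c(0.1, 1)) {
  if (!length(fields)) stop("at least one field is required", call. = FALSE)
  rows <- list()
  for (i in seq_along(fields)) {
    q <- tryCatch(quantifyField(fields[[i]], stains, minArea,
                                circularityRange),
                  error = function(e) {
                    warning("field ", i, " skipped: ", conditionMessage(e),
                            call. = FALSE)
                    NULL
                  })
    if (!is.null(q))
      rows[[length(rows) + 1L]] <-
        data.frame(field = i, n_tunel = q$nTunel,
                   n_counterstain = q$nCounterstain, rate = q$rate)
  }
  if (!length(rows))
    stop("all fields failed quantification", call. = FALSE)
  tab <- do.call(rbind, rows)
  nT <- sum(tab$n_tunel); nC <- sum(tab$n_counterstain)
  rate <- tunelPositivity(nT, nC)
  methods::new("QuantResult", fields = tab, nTunel = as.integer(nT),
               nCounterstain = as.integer(nC), rate = rate)
}

#' @describeIn QuantResult-class the pooled case-level positivity rate.
#' @param object a `QuantResult`.
#' @export
setGeneric("positivityRate", function(object) standardGeneric("positivityRate"))

#' @export
setMethod("positivityRate", "QuantResult", function(object) object@rate)

#' @describeIn QuantResult-class the per-field count table.
#' @export
setGeneric("fieldCounts", function(object) standardGeneric("fieldCounts"))

#' @export
setMethod("fieldCounts", "QuantResult", function(object) object@fields)

setMethod("show", "QuantResult", function(object) {
  cat(sprintf("QuantResult: %d field(s); TUNEL+ %d, counterstain %d; rate %.4f\n",
              nrow(object@fields), object@nTunel, object@nCounterstain,
              object@rate))
})

#' Read or write a field image
#'
#' PNG via the png package; TIFF via the tiff package when installed.
#' Images are scaled to the 0..255 convention used throughout.
#'
#' @param path image path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @return `readFieldImage`: height x width x 3 array in 0..255.
#' @export
readFieldImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the tiff package is required for TIFF input", call. = FALSE)
    tiff::readTIFF(path)
  } else stop("unsupported image format: ", ext, call. = FALSE)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

#' @rdname readFieldImage
#' @param image height x width x 3 array in 0..255.
#' @export
writeFieldImage <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  scaled <- pmin(pmax(image / 255, 0), 1)
  if (ext == "png") png::writePNG(scaled, path)
  else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the tiff package is required for TIFF output", call. = FALSE)
    tiff::writeTIFF(scaled, path)
  } else stop("unsupported image format: ", ext, call. = FALSE)
  invisible(path)
}
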