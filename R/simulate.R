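#' Default panel-gene subgroup means (CPM)
#'
#' Per-gene mean CPM of the latent high (HSR) and low (LSR) stress-response
#' subgroups used by [simulateCohort()], plus control-subgroup means where
#' a value is fixed; control means left `NA` are derived at simulation time
#' as midpoint +/- `controlEffect` x half-difference of the SZ means.
#' Genes whose reported direction of change is inconsistent across studies,
#' or that do not enter the stress-response index, carry equal means.
#'
#' @return `data.frame` with columns `gene`, `meanHSR`, `meanLSR`,
#'   `meanContHigh`, `meanContLow`.
#' @export
defaultPanelEffects <- function() {
  df <- data.frame(
    gene = c("IL6", "IFNG", "SOD2", "DLG4", "SYP", "SNCA", "BDNF",
             "SOD3", "NR3C1", "APOA1", "SLC6A4",
             "IL1B", "TNF", "SOD1", "IL10", "SNCB", "SNCG", "APOA2",
             "S100B"),
    meanHSR = c(0.77, 0.14, 84.7, 14.5, 350.1, 6.74, 0.30,
                7.3, 45, 4.0, 1.1,
                2.0, 3.0, 180, 1.0, 80, 15, 0.8, 600),
    meanLSR = c(0.38, 0.06, 46.1, 21.5, 556.3, 11.26, 0.51,
                3.4, 35, 2.5, 0.6,
                2.0, 3.0, 180, 1.0, 80, 15, 0.8, 600),
    meanContHigh = c(0.59, NA, 79.6, 15.2, 366.3, 7.68, NA,
                     6.95, NA, NA, NA,
                     NA, NA, NA, NA, NA, NA, NA, NA),
    meanContLow = c(0.33, NA, 50.6, 20.6, 558.5, 12.12, NA,
                    3.81, NA, NA, NA,
                    NA, NA, NA, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
  df
}

#' Simulate a cohort with latent stress-response subgroups
#'
#' Generates a negative-binomial bulk RNA-seq cohort in CPM units with the
#' structure the stratification pipeline assumes: panel genes whose means
#' differ between the latent high and low stress-response subgroups of the
#' SZ cases (and, attenuated, of the controls), negative-binomial background
#' genes with a shared mean across groups, and a planted gene set whose
#' members are shifted by `plantedLog2FC` in the latent HSR-SZ subgroup.
#' Counts are drawn per sample as NB(mean = CPM x L/1e6, dispersion) for a
#' simulated library size L and rescaled to CPM. All randomness flows from
#' `seed`; identical seeds give identical cohorts.
#'
#' @param nHSR,nLSR latent SZ subgroup sizes (defaults 7 and 18).
#' @param nControlHigh,nControlLow latent control subgroup sizes (defaults
#'   14 and 7).
#' @param nBackgroundGenes number of background genes (default 2000).
#' @param panelEffects `data.frame` as from [defaultPanelEffects()].
#' @param controlEffect attenuation in `[0, 1]` of the SZ subgroup
#'   difference applied to control subgroups where no fixed control mean is
#'   given (default 0.8).
#' @param nbDispersion negative-binomial dispersion phi (variance =
#'   mu + phi mu^2); `0` gives Poisson sampling. Default 0.1.
#' @param librarySize mean library size in reads (default 46.6e6).
#' @param librarySizeCV coefficient of variation of the per-sample library
#'   size (default 0.15).
#' @param plantedSetName,plantedSetSize,plantedLog2FC name, size and log2
#'   fold change (latent HSR-SZ vs everyone) of the planted set (defaults
#'   `"SYNTHETIC_DSB_REPAIR_HR"`, 7, 1).
#' @param backgroundMeanlog,backgroundSdlog log-normal parameters of the
#'   background-gene CPM means (defaults `log(20)`, 1.5).
#' @param seed integer seed.
#' @return A list with `experiment` (a [StressExperiment-class]), and
#'   `truth`: `group` (named latent group per sample, one of `"HSR_SZ"`,
#'   `"LSR_SZ"`, `"CONT_HIGH"`, `"CONT_LOW"`), `plantedGenes`,
#'   `plantedSetName`, and `backgroundGenes`.
#' @export
simulateCohort <- function(nHSR = 7L, nLSR = 18L,
                           nControlHigh = 14L, nControlLow = 7L,
                           nBackgroundGenes = 2000L,
                           panelEffects = defaultPanelEffects(),
                           controlEffect = 0.8,
                           nbDispersion = 0.1,
                           librarySize = 46.6e6, librarySizeCV = 0.15,
                           plantedSetName = "SYNTHETIC_DSB_REPAIR_HR",
                           plantedSetSize = 7L, plantedLog2FC = 1,
                           backgroundMeanlog = log(20),
                           backgroundSdlog = 1.5,
                           seed = 1L) {
  stopifnot(nHSR >= 0, nLSR >= 0, nControlHigh >= 0, nControlLow >= 0,
            nBackgroundGenes >= 0, nbDispersion >= 0, controlEffect >= 0,
            plantedSetSize >= 0, plantedSetSize <= nBackgroundGenes)
  .withSeed(seed, {
    nSZ <- nHSR + nLSR; nCont <- nControlHigh + nControlLow
    n <- nSZ + nCont
    if (n == 0) stop("cohort must contain at least one sample", call. = FALSE)
    samples <- c(sprintf("SZ%02d", seq_len(nSZ)),
                 sprintf("C%02d", seq_len(nCont)))
    group <- c(rep("HSR_SZ", nHSR), rep("LSR_SZ", nLSR),
               rep("CONT_HIGH", nControlHigh), rep("CONT_LOW", nControlLow))
    names(group) <- samples

    pe <- panelEffects
    mid <- (pe$meanHSR + pe$meanLSR) / 2
    half <- (pe$meanHSR - pe$meanLSR) / 2
    contHigh <- ifelse(is.na(pe$meanContHigh), mid + controlEffect * half,
                       pe$meanContHigh)
    contLow <- ifelse(is.na(pe$meanContLow), mid - controlEffect * half,
                      pe$meanContLow)
    panelMeans <- cbind(HSR_SZ = pe$meanHSR, LSR_SZ = pe$meanLSR,
                        CONT_HIGH = contHigh, CONT_LOW = contLow)
    rownames(panelMeans) <- pe$gene

    bgGenes <- if (nBackgroundGenes > 0)
      sprintf("BG%04d", seq_len(nBackgroundGenes)) else character()
    bgMeans <- if (nBackgroundGenes > 0)
      exp(stats::rnorm(nBackgroundGenes, backgroundMeanlog, backgroundSdlog))
      else numeric()
    names(bgMeans) <- bgGenes
    # planted genes: background genes with enough expression to be testable
    planted <- character()
    if (plantedSetSize > 0) {
      pool <- bgGenes[bgMeans >= 5]
      if (length(pool) < plantedSetSize)
        pool <- bgGenes[order(bgMeans, decreasing = TRUE)]
      planted <- sort(sample(pool, plantedSetSize))
    }

    genes <- c(pe$gene, bgGenes)
    meanMat <- matrix(0, length(genes), n, dimnames = list(genes, samples))
    meanMat[pe$gene, ] <- panelMeans[, group]
    if (nBackgroundGenes > 0) {
      meanMat[bgGenes, ] <- matrix(bgMeans, nBackgroundGenes, n)
      if (length(planted) && nHSR > 0)
        meanMat[planted, group == "HSR_SZ"] <-
          meanMat[planted, group == "HSR_SZ", drop = FALSE] * 2^plantedLog2FC
    }

    libs <- librarySize * exp(stats::rnorm(n, 0, librarySizeCV) -
                              librarySizeCV^2 / 2)
    muCounts <- sweep(meanMat, 2L, libs / 1e6, "*")
    counts <- if (nbDispersion <= 1e-12)
      matrix(stats::rpois(length(muCounts), muCounts), nrow(muCounts))
    else
      matrix(stats::rnbinom(length(muCounts), mu = muCounts,
                            size = 1 / nbDispersion), nrow(muCounts))
    cpm <- sweep(counts, 2L, 1e6 / libs, "*")
    dimnames(cpm) <- dimnames(meanMat)

    md <- .simulateMetadata(group)
    exp <- StressExperiment(cpm, md)
    list(experiment = exp,
         truth = list(group = group, plantedGenes = planted,
                      plantedSetName = plantedSetName,
                      backgroundGenes = bgGenes))
  })
}

# Clinical covariates with the cohort structure the analysis expects;
# values echo the demographic tables (means/SDs per subgroup) but only the
# Fisher/MWU plumbing consumes them downstream.
.simulateMetadata <- function(group) {
  n <- length(group)
  rnormTrunc <- function(n, mean, sd, lo, hi = Inf)
    pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
  age <- numeric(n); rin <- numeric(n); pmi <- numeric(n)
  cpz <- rep(NA_real_, n); sexP <- numeric(n)
  isSZ <- group %in% c("HSR_SZ", "LSR_SZ")
  age[isSZ] <- rnormTrunc(sum(isSZ), 68.4, 11.3, 30, 100)
  age[!isSZ] <- rnormTrunc(sum(!isSZ), 66.4, 17.7, 30, 100)
  rin[group == "HSR_SZ"] <- rnormTrunc(sum(group == "HSR_SZ"), 6.6, 0.7, 1, 10)
  rin[group == "LSR_SZ"] <- rnormTrunc(sum(group == "LSR_SZ"), 7.8, 0.9, 1, 10)
  rin[!isSZ] <- rnormTrunc(sum(!isSZ), 5.8, 1.2, 1, 10)
  pmi[isSZ] <- rnormTrunc(sum(isSZ), 16.8, 11.8, 0.5)
  pmi[!isSZ] <- rnormTrunc(sum(!isSZ), 11.4, 12.9, 0.5)
  cpz[group == "HSR_SZ"] <- rnormTrunc(sum(group == "HSR_SZ"), 347, 345, 0)
  cpz[group == "LSR_SZ"] <- rnormTrunc(sum(group == "LSR_SZ"), 652, 664, 0)
  sexP[isSZ] <- 8 / 25; sexP[!isSZ] <- 8 / 21
  sex <- ifelse(stats::runif(n) < sexP, "F", "M")
  famAvail <- ifelse(group == "HSR_SZ", 3 / 7,
                     ifelse(group == "LSR_SZ", 4 / 18, 0.3))
  famPres <- ifelse(group == "HSR_SZ", 0.05,
                    ifelse(group == "LSR_SZ", 0.75, 0.1))
  fam <- ifelse(stats::runif(n) < famAvail,
                ifelse(stats::runif(n) < famPres, "present", "absent"),
                "unknown")
  deathP <- list(HSR_SZ = c(4, 2, 1) / 7, LSR_SZ = c(7, 8, 3) / 18,
                 CONT_HIGH = c(0.35, 0.5, 0.15), CONT_LOW = c(0.35, 0.5, 0.15))
  death <- vapply(group, function(g)
    sample(c("inflammatory", "non_inflammatory", "malignancy"), 1L,
           prob = deathP[[g]]), character(1))
  data.frame(diagnosis = ifelse(isSZ, "SZ", "CONTROL"),
             age_years = round(age, 1), sex = sex, rin = round(rin, 1),
             pmi_hours = round(pmi, 1), cpz_eq_mg = round(cpz),
             family_history = fam, death_category = unname(death),
             row.names = names(group), stringsAsFactors = FALSE)
}

#' Generate a planted-plus-decoy gene-set collection
#'
#' Builds a [GeneSetList-class] holding the cohort's planted set followed by
#' `nDecoySets` decoy sets sampled (without replacement within each set)
#' from the non-shifted background genes, disjoint from the planted set.
#'
#' @param truth the `truth` element returned by [simulateCohort()].
#' @param nDecoySets number of decoy sets (default 20).
#' @param decoySize genes per decoy set (default 7).
#' @param seed integer seed.
#' @return A [GeneSetList-class]; the planted set is first.
#' @export
simulateGeneSets <- function(truth, nDecoySets = 20L, decoySize = 7L,
                             seed = 1L) {
  pool <- setdiff(truth$backgroundGenes, truth$plantedGenes)
  if (decoySize > length(pool))
    stop("decoySize exceeds the background-gene pool", call. = FALSE)
  .withSeed(seed, {
    sets <- list()
    if (length(truth$plantedGenes))
      sets[[truth$plantedSetName]] <- truth$plantedGenes
    for (i in seq_len(nDecoySets))
      sets[[sprintf("DECOY_%02d", i)]] <- sort(sample(pool, decoySize))
    GeneSetList(sets)
  })
}

#' Render a synthetic two-stain histology field
#'
#' Draws non-overlapping filled disks (cells) on a white background: the
#' first `nTunelPos` disks carry the first stain of the model (DAB, the
#' TUNEL chromogen) at `dabAmplitude`, the remaining `nCounterstain` disks
#' the second stain (methyl green) at `mgAmplitude`. Pixels are composed by
#' the Beer-Lambert law — transmitted intensity
#' `I_c = 255 * 10^(-amplitude * stainVector_c)` per RGB channel — then
#' Gaussian noise of `noiseSD` gray levels is added, and values are clipped
#' to `[0, 255]` and rounded to the 8-bit grid.
#'
#' @param nTunelPos,nCounterstain numbers of DAB and methyl-green disks.
#' @param width,height field size in pixels (defaults 512).
#' @param radiusRange disk radius range in pixels, sampled uniformly
#'   (default `c(30, 36)`).
#' @param dabAmplitude,mgAmplitude stain optical-density amplitudes
#'   (defaults 0.8 and 0.7).
#' @param noiseSD Gaussian noise standard deviation in gray levels
#'   (default 2).
#' @param stains a [StainModel-class] (default [defaultStainModel()]).
#' @param seed integer seed.
#' @param maxAttempts rejection-sampling budget for non-overlapping
#'   placement; exceeded placement is an error.
#' @return A list with `image` (height x width x 3 array, 0..255) and
#'   `truth` (`nTunelPos`, `nCounterstain`, `centers` (row, col), `radii`,
#'   `stain` per cell).
#' @export
renderField <- function(nTunelPos = 5L, nCounterstain = 15L,
                        width = 512L, height = 512L,
                        radiusRange = c(30, 36),
                        dabAmplitude = 0.8, mgAmplitude = 0.7,
                        noiseSD = 2, stains = defaultStainModel(),
                        seed = 1L, maxAttempts = 20000L) {
  stopifnot(nTunelPos >= 0, nCounterstain >= 0, width >= 8, height >= 8,
            radiusRange[1] >= 1, radiusRange[2] >= radiusRange[1])
  .withSeed(seed, {
    nCells <- nTunelPos + nCounterstain
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    attempts <- 0L
    while (nrow(centers) < nCells) {
      attempts <- attempts + 1L
      if (attempts > maxAttempts)
        stop("could not place ", nCells,
             " non-overlapping cells within the attempt budget",
             call. = FALSE)
      r <- stats::runif(1, radiusRange[1], radiusRange[2])
      if (2 * r + 4 > min(width, height))
        stop("cell radius too large for the field", call. = FALSE)
      row <- stats::runif(1, r + 2, height - r - 1)
      col <- stats::runif(1, r + 2, width - r - 1)
      if (nrow(centers)) {
        d <- sqrt((centers[, 1] - row)^2 + (centers[, 2] - col)^2)
        if (any(d < radii + r + 2)) next
      }
      centers <- rbind(centers, c(row, col))
      radii <- c(radii, r)
    }
    v <- stainVectors(stains)
    conc <- array(0, c(height, width, 2L))
    stainOf <- rep(c("DAB", "MG"), c(nTunelPos, nCounterstain))
    amp <- c(DAB = dabAmplitude, MG = mgAmplitude)
    for (i in seq_len(nCells)) {
      r <- radii[i]; cy <- centers[i, 1]; cx <- centers[i, 2]
      rows <- max(1, floor(cy - r)):min(height, ceiling(cy + r))
      cols <- max(1, floor(cx - r)):min(width, ceiling(cx + r))
      dd <- outer((rows - cy)^2, (cols - cx)^2, "+")
      inside <- dd <= r^2
      ch <- if (stainOf[i] == "DAB") 1L else 2L
      patch <- conc[rows, cols, ch]
      patch[inside] <- amp[[stainOf[i]]]
      conc[rows, cols, ch] <- patch
    }
    img <- array(0, c(height, width, 3L))
    for (c3 in 1:3) {
      od <- conc[, , 1L] * v[c3, 1L] + conc[, , 2L] * v[c3, 2L]
      img[, , c3] <- 255 * 10^(-od)
    }
    if (noiseSD > 0)
      img <- img + array(stats::rnorm(length(img), 0, noiseSD), dim(img))
    img <- round(pmin(pmax(img, 0), 255))
    list(image = img,
         truth = list(nTunelPos = nTunelPos, nCounterstain = nCounterstain,
                      centers = centers, radii = radii, stain = stainOf))
  })
}
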