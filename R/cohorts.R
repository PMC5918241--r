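# Study-level cohort analyses: each function simulates a cohort with a
# named fixture configuration, runs the full image pipeline on it, and
# returns the headline statistic. These are the computations behind the
# package's reported numbers; the vignette discusses the study designs.

fieldSeeds <- function(seed, n) (as.integer(seed) - 1L) * 1000L + seq_len(n)

#' Split-centriole census over a simulated cohort
#'
#' Simulates tiled fields under a fixture population until \code{nCells}
#' cells are placed, runs nucleus/cytoplasm segmentation, PCM focus
#' detection without declumping (so cohered centrosomes group into one
#' focus), pairs the two brightest foci per cell, classifies split at the
#' distance threshold, and reports the percentage of non-excluded cells
#' classified split.
#'
#' @param fixture fixture name, e.g. \code{"rpe_like"} or
#'   \code{"hela_like"}.
#' @param nCells total cells to simulate (rounded up to whole fields).
#' @param seed cohort seed; field f uses seed \code{(seed-1)*1000 + f}.
#' @param thresholdUm split threshold, micrometres.
#' @param cellsPerField field tiling density.
#' @return list: \code{percentSplit}, \code{nAnalyzed}, \code{nExcluded},
#'   \code{census} (per-cell records).
#' @export
censusCohort <- function(fixture, nCells = 1000, seed = 1,
                         thresholdUm = 1.5, cellsPerField = 32L) {
  nFields <- ceiling(nCells / cellsPerField)
  cfg <- fixtureConfig(fixture, nCells = as.integer(cellsPerField))
  seeds <- fieldSeeds(seed, nFields)
  census <- NULL
  for (f in seq_len(nFields)) {
    sc <- simulateField(cfg, seed = seeds[f])
    res <- censusField(sceneImages(sc), cfg@pixelSizeUm,
                       thresholdUm = thresholdUm, withRoots = FALSE)
    res$census$field <- f
    census <- rbind(census, res$census)
  }
  ok <- !census$excluded
  list(percentSplit = 100 * mean(census$splitFlag[ok]),
       nAnalyzed = sum(ok), nExcluded = sum(!ok), census = census)
}

#' Root-to-centriole area ratio over a simulated cohort
#'
#' Simulates fields, segments roots by propagation from detected PCM
#' seeds and centriole foci by declumped detection, and reports the mean
#' per-cell ratio of total root area to total centriole-focus area.
#'
#' @param fixture fixture name.
#' @param nCells total cells to simulate.
#' @param seed cohort seed.
#' @param cellsPerField field tiling density.
#' @return list: \code{meanRatio}, \code{nCellsUsed}, \code{ratios}.
#' @export
rootAreaRatioCohort <- function(fixture = "rpe_like", nCells = 100,
                                seed = 2, cellsPerField = 25L) {
  nFields <- ceiling(nCells / cellsPerField)
  cfg <- fixtureConfig(fixture, nCells = as.integer(cellsPerField))
  seeds <- fieldSeeds(seed, nFields)
  ratios <- numeric(0)
  for (f in seq_len(nFields)) {
    sc <- simulateField(cfg, seed = seeds[f])
    img <- sceneImages(sc)
    ps <- cfg@pixelSizeUm
    nuclei <- segmentNuclei(img[, , "dna"], ps)
    cells <- assignCytoplasm(nuclei)
    mit <- excludeMitotic(img[, , "dna"], nuclei)
    pcm <- detectFoci(img[, , "pcm"], cells, declump = FALSE)
    cent <- detectFoci(img[, , "centriole"], cells, declump = TRUE,
                       channelName = "centriole")
    roots <- segmentRoots(img[, , "rootletin"], pcm, ps)
    ri <- rootInfo(roots)
    for (cc in seq_len(nObjects(nuclei))) {
      if (cc %in% mit$cell[mit$mitotic]) next
      rootArea <- sum(ri$areaPx[!is.na(ri$cell) & ri$cell == cc])
      centArea <- sum(cent$areaPx[!is.na(cent$cell) & cent$cell == cc])
      if (rootArea > 0 && centArea > 0)
        ratios <- c(ratios, rootArea / centArea)
    }
  }
  list(meanRatio = mean(ratios), nCellsUsed = length(ratios),
       ratios = ratios)
}

#' Empirical split threshold from a linkage-versus-distance cohort
#'
#' Simulates a cohort whose pair distances span the configured uniform
#' range, classifies root linkage per cell through the image pipeline,
#' bins the linked fraction by distance and derives the distance above
#' which roots rarely link.
#'
#' @param nCells total cells to simulate.
#' @param seed cohort seed.
#' @param binWidthUm linkage-curve bin width.
#' @param rareFraction operational definition of "rarely linked".
#' @param cellsPerField field tiling density.
#' @return list: \code{thresholdUm}, \code{curve}, \code{nUsed}.
#' @export
linkageThresholdCohort <- function(nCells = 2000, seed = 3,
                                   binWidthUm = 0.25, rareFraction = 0.1,
                                   cellsPerField = 32L) {
  nFields <- ceiling(nCells / cellsPerField)
  cfg <- fixtureConfig("linkage_sweep", nCells = as.integer(cellsPerField))
  seeds <- fieldSeeds(seed, nFields)
  census <- NULL
  for (f in seq_len(nFields)) {
    sc <- simulateField(cfg, seed = seeds[f])
    res <- censusField(sceneImages(sc), cfg@pixelSizeUm, withRoots = TRUE)
    census <- rbind(census, res$census)
  }
  ok <- !census$excluded & !is.na(census$linked) &
    !is.na(census$distanceUm) & census$nFoci == 2
  curve <- linkageVsDistance(census$distanceUm[ok], census$linked[ok],
                             binWidthUm, maxUm = 4)
  list(thresholdUm = deriveSplitThreshold(curve, rareFraction),
       curve = curve, nUsed = sum(ok))
}

#' FRAP recovery over a cohort of simulated bleach movies
#'
#' Simulates whole-centrosome bleach time-lapses, tracks the centrosome in
#' the PCM channel, extracts and normalizes the rootletin trace, fits the
#' single-exponential recovery model per cell and reports the mean plateau
#' recovery percentage.
#'
#' @param nMovies number of cells.
#' @param seed cohort seed; movie m uses seed \code{(seed-1)*1000 + m}.
#' @param fixture fixture name (default \code{"frap"}).
#' @return list: \code{meanPlateauRecoveryPct}, \code{fits},
#'   \code{perCell}.
#' @export
frapCohort <- function(nMovies = 11, seed = 1, fixture = "frap") {
  cfg <- fixtureConfig(fixture)
  seeds <- fieldSeeds(seed, nMovies)
  fits <- vector("list", nMovies)
  for (m in seq_len(nMovies)) {
    tl <- simulateTimelapse(cfg, seed = seeds[m])
    tr <- analyzeMovie(tl)
    fits[[m]] <- fitRecovery(normalizeFrap(tr))
  }
  pct <- vapply(fits, function(f) f@plateauRecoveryPct, numeric(1))
  list(meanPlateauRecoveryPct = mean(pct), fits = fits, perCell = pct)
}

#' Anaphase-aligned assembly kinetics over a simulated cohort
#'
#' Simulates single-cell division time-lapses, tracks centrosomes,
#' extracts rootletin traces, aligns them to the true anaphase frames,
#' fits the saturating-exponential assembly model to the post-anaphase
#' mean trace and the plateau-then-decline model to the pre-anaphase
#' mean trace.
#'
#' @param nMovies number of cells.
#' @param seed cohort seed.
#' @param fixture fixture name (default \code{"timelapse"}).
#' @return list: \code{t90H}, \code{releaseOnsetH}, \code{assembly}
#'   (an \linkS4class{AssemblyFit}), \code{onset}, \code{aligned}.
#' @export
assemblyCohort <- function(nMovies = 17, seed = 1, fixture = "timelapse") {
  cfg <- fixtureConfig(fixture)
  seeds <- fieldSeeds(seed, nMovies)
  traces <- vector("list", nMovies)
  ana <- integer(nMovies)
  for (m in seq_len(nMovies)) {
    tl <- simulateTimelapse(cfg, seed = seeds[m])
    traces[[m]] <- analyzeMovie(tl)
    ana[m] <- tl@truth$anaphaseFrame
  }
  aligned <- alignTraces(traces, ana)
  post <- aligned$relTimeH >= 0
  fit <- estimateAssembly(aligned$relTimeH[post], aligned$mean[post])
  pre <- aligned$relTimeH <= 0
  onset <- estimateReleaseOnset(aligned$relTimeH[pre], aligned$mean[pre])
  list(t90H = t90(fit), releaseOnsetH = onset$onsetH, assembly = fit,
       onset = onset, aligned = aligned)
}
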