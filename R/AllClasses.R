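#' @import methods
NULL

# ---------------------------------------------------------------------------
# Configuration classes
# ---------------------------------------------------------------------------

#' Configuration of a synthetic multi-cell field
#'
#' A \code{SceneConfig} describes one fixed, multi-cell fluorescence field:
#' geometry (pixel size, field size, nucleus radius), the cohesion state of
#' the centriole pairs (split probability, cohered and split distance
#' regimes), root-fibre size and linkage behaviour, per-channel intensities,
#' and the optical model (PSF width, Poisson--Gaussian noise).
#'
#' Distances are in micrometres throughout. The cohered and split distance
#' regimes must be separable: the lower edge of the split range has to exceed
#' the 99th percentile of the cohered distribution, so that the configured
#' split probability is recoverable by a distance threshold placed between
#' the two regimes. Setting \code{distanceRangeUm} replaces the two-regime
#' mixture by a single uniform draw over the given range, which is what a
#' linkage-versus-distance sweep uses.
#'
#' @slot pixelSizeUm length of one pixel side, micrometres.
#' @slot fieldPx image side length in pixels.
#' @slot nCells number of cells to place in the field.
#' @slot pSplit probability that a cell's centriole pair is split.
#' @slot coheredDistUm mean and SD of the cohered inter-centriole distance.
#' @slot splitDistUm min and max of the uniform split-distance range.
#' @slot nCentrioles centrioles per cell, 2 or 4.
#' @slot rootAreaScale expected root-mask area as a multiple of one
#'   centriole-focus area.
#' @slot linkMidpointUm distance at which root-linkage probability is 0.5.
#' @slot linkSteepness logistic slope (micrometres) of linkage vs distance.
#' @slot intensity named per-channel signal levels
#'   (\code{dna}, \code{centriole}, \code{pcm}, \code{rootletin}).
#' @slot psfSigmaUm Gaussian PSF sigma, micrometres; 0 disables blur.
#' @slot noiseGaussianSd additive read-noise SD; 0 disables.
#' @slot noisePoissonGain photons per intensity unit for shot noise; 0 disables.
#' @slot pMitotic fraction of cells rendered with condensed (bright, compact)
#'   chromatin.
#' @slot nucleusRadiusUm nucleus radius.
#' @slot minSeparationUm minimum nucleus centre-to-centre distance.
#' @slot centrioleOffsetUm distance of the centrosome site beyond the nucleus
#'   edge.
#' @slot distanceRangeUm optional; when length 2, pair distances are drawn
#'   uniformly from this range instead of the cohered/split mixture.
#'
#' @seealso [sceneConfig()], [simulateField()]
#' @exportClass SceneConfig
setClass("SceneConfig", representation(
  pixelSizeUm = "numeric", fieldPx = "integer", nCells = "integer",
  pSplit = "numeric", coheredDistUm = "numeric", splitDistUm = "numeric",
  nCentrioles = "integer", rootAreaScale = "numeric",
  linkMidpointUm = "numeric", linkSteepness = "numeric",
  intensity = "numeric", psfSigmaUm = "numeric",
  noiseGaussianSd = "numeric", noisePoissonGain = "numeric",
  pMitotic = "numeric", nucleusRadiusUm = "numeric",
  minSeparationUm = "numeric", centrioleOffsetUm = "numeric",
  distanceRangeUm = "numeric"))

setValidity("SceneConfig", function(object) {
  msg <- character()
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be > 0")
  if (object@pSplit < 0 || object@pSplit > 1)
    msg <- c(msg, "pSplit must lie in [0, 1]")
  if (object@pMitotic < 0 || object@pMitotic > 1)
    msg <- c(msg, "pMitotic must lie in [0, 1]")
  if (object@linkMidpointUm <= 0) msg <- c(msg, "linkMidpointUm must be > 0")
  if (object@fieldPx < 8) msg <- c(msg, "fieldPx must be at least 8")
  if (object@nCells < 0) msg <- c(msg, "nCells must be non-negative")
  if (!object@nCentrioles %in% c(2L, 4L))
    msg <- c(msg, "nCentrioles must be 2 or 4")
  if (length(object@coheredDistUm) != 2 || any(object@coheredDistUm < 0))
    msg <- c(msg, "coheredDistUm must be (mean, sd), both non-negative")
  if (length(object@splitDistUm) != 2 ||
      object@splitDistUm[1] > object@splitDistUm[2])
    msg <- c(msg, "splitDistUm must be (min, max) with min <= max")
  if (!length(object@distanceRangeUm) %in% c(0L, 2L))
    msg <- c(msg, "distanceRangeUm must be empty or length 2")
  if (length(object@distanceRangeUm) == 0) {
    cohered99 <- object@coheredDistUm[1] +
      stats::qnorm(0.99) * object@coheredDistUm[2]
    if (object@splitDistUm[1] <= cohered99)
      msg <- c(msg, sprintf(
        "split range must start above the cohered 99th percentile (%.2f um)",
        cohered99))
  }
  need <- c("dna", "centriole", "pcm", "rootletin")
  if (!all(need %in% names(object@intensity)))
    msg <- c(msg, "intensity must name dna, centriole, pcm and rootletin")
  if (length(msg)) msg else TRUE
})

#' Create a synthetic-field configuration
#'
#' Defaults encode an untransformed epithelial-like population: ~10% of
#' interphase cells split, cohered pairs at 0.6 +/- 0.15 um, split pairs
#' between 1.8 and 4 um, roots ten-fold the area of a centriole focus, and
#' root linkage falling off logistically so that pairs beyond ~1.5 um are
#' rarely linked. See the fixture configurations shipped under
#' \code{inst/extdata} for the named populations used in the vignette.
#'
#' @param pixelSizeUm,fieldPx,nCells,pSplit,coheredDistUm,splitDistUm
#'   geometry and cohesion parameters; see \linkS4class{SceneConfig}.
#' @param nCentrioles,rootAreaScale,linkMidpointUm,linkSteepness root and
#'   linkage parameters.
#' @param intensity named per-channel signal levels.
#' @param psfSigmaUm,noiseGaussianSd,noisePoissonGain optical model.
#' @param pMitotic,nucleusRadiusUm,minSeparationUm,centrioleOffsetUm cell
#'   placement parameters.
#' @param distanceRangeUm optional uniform pair-distance override.
#' @return a validated \linkS4class{SceneConfig}.
#' @examples
#' cfg <- sceneConfig(nCells = 4L, fieldPx = 256L)
#' cfg
#' @export
sceneConfig <- function(pixelSizeUm = 0.1, fieldPx = 800L, nCells = 24L,
                        pSplit = 0.10, coheredDistUm = c(0.6, 0.15),
                        splitDistUm = c(1.8, 4.0), nCentrioles = 2L,
                        rootAreaScale = 10, linkMidpointUm = 1.4,
                        linkSteepness = 0.05,
                        intensity = c(dna = 400, centriole = 600,
                                      pcm = 500, rootletin = 300),
                        psfSigmaUm = 0.1, noiseGaussianSd = 5,
                        noisePoissonGain = 0.25, pMitotic = 0,
                        nucleusRadiusUm = 2.5, minSeparationUm = 9,
                        centrioleOffsetUm = 1.2,
                        distanceRangeUm = numeric(0)) {
  new("SceneConfig", pixelSizeUm = pixelSizeUm,
      fieldPx = as.integer(fieldPx), nCells = as.integer(nCells),
      pSplit = pSplit, coheredDistUm = coheredDistUm,
      splitDistUm = splitDistUm, nCentrioles = as.integer(nCentrioles),
      rootAreaScale = rootAreaScale, linkMidpointUm = linkMidpointUm,
      linkSteepness = linkSteepness, intensity = intensity,
      psfSigmaUm = psfSigmaUm, noiseGaussianSd = noiseGaussianSd,
      noisePoissonGain = noisePoissonGain, pMitotic = pMitotic,
      nucleusRadiusUm = nucleusRadiusUm, minSeparationUm = minSeparationUm,
      centrioleOffsetUm = centrioleOffsetUm,
      distanceRangeUm = distanceRangeUm)
}

#' Configuration of a synthetic single-cell time-lapse
#'
#' Describes the kinetic model of a single-cell movie: centrosomal rootletin
#' holds a plateau, declines linearly to zero over \code{releaseLeadH} hours
#' before anaphase, and reassembles after anaphase as a saturating
#' exponential with time constant \code{assemblyTauH}. The centriole pair
#' follows a two-state (cohered/split) Markov process with the given rates.
#' An optional FRAP event multiplies the rootletin signal by
#' \code{1 - frapBleachDepth} at \code{frapBleachTimeH} and lets it recover
#' towards \code{(1 - depth) + depth * mobileFraction} with time constant
#' \code{frapRecoveryTauH}.
#'
#' @slot pixelSizeUm,fieldPx image geometry.
#' @slot frameIntervalMin acquisition interval, minutes.
#' @slot durationH movie length, hours.
#' @slot anaphaseTimeH anaphase onset, hours from movie start; \code{NA}
#'   for a movie without mitosis.
#' @slot releaseLeadH hours before anaphase at which release begins.
#' @slot assemblyTauH time constant of post-anaphase assembly, hours.
#' @slot assemblyPlateau plateau intensity (arbitrary units).
#' @slot splitRatePerH,rejoinRatePerH two-state transition rates, per hour.
#' @slot coheredDistUm,splitDistUm distance regimes as in
#'   \linkS4class{SceneConfig}.
#' @slot frapBleachTimeH bleach time, hours; \code{NA} disables FRAP.
#' @slot frapBleachDepth fraction of fluorescence removed by the bleach.
#' @slot frapMobileFraction fraction of the bleached signal that recovers.
#' @slot frapRecoveryTauH recovery time constant, hours.
#' @slot intensityPcm constant PCM-channel signal per centrosome.
#' @slot psfSigmaUm,noiseGaussianSd,noisePoissonGain optical model.
#' @seealso [timelapseConfig()], [simulateTimelapse()]
#' @exportClass TimelapseConfig
setClass("TimelapseConfig", representation(
  pixelSizeUm = "numeric", fieldPx = "integer",
  frameIntervalMin = "numeric", durationH = "numeric",
  anaphaseTimeH = "numeric", releaseLeadH = "numeric",
  assemblyTauH = "numeric", assemblyPlateau = "numeric",
  splitRatePerH = "numeric", rejoinRatePerH = "numeric",
  coheredDistUm = "numeric", splitDistUm = "numeric",
  frapBleachTimeH = "numeric", frapBleachDepth = "numeric",
  frapMobileFraction = "numeric", frapRecoveryTauH = "numeric",
  intensityPcm = "numeric", psfSigmaUm = "numeric",
  noiseGaussianSd = "numeric", noisePoissonGain = "numeric"))

setValidity("TimelapseConfig", function(object) {
  msg <- character()
  if (object@frameIntervalMin <= 0) msg <- c(msg, "frameIntervalMin must be > 0")
  if (object@durationH <= 0) msg <- c(msg, "durationH must be > 0")
  if (object@splitRatePerH < 0 || object@rejoinRatePerH < 0)
    msg <- c(msg, "transition rates must be non-negative")
  if (!is.na(object@anaphaseTimeH) &&
      object@anaphaseTimeH > object@durationH)
    msg <- c(msg, "durationH must cover anaphaseTimeH")
  if (!is.na(object@frapBleachTimeH)) {
    if (object@frapBleachDepth <= 0 || object@frapBleachDepth > 1)
      msg <- c(msg, "frapBleachDepth must lie in (0, 1]")
    if (object@frapMobileFraction < 0 || object@frapMobileFraction > 1)
      msg <- c(msg, "frapMobileFraction must lie in [0, 1]")
    if (object@frapRecoveryTauH < 0)
      msg <- c(msg, "frapRecoveryTauH must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Create a time-lapse configuration
#'
#' Defaults follow the live-imaging design the package emulates: 12-minute
#' frames, anaphase part-way through the movie, release starting 2.5 h
#' before anaphase, and an assembly time constant of 9/ln(10) h so that 90%
#' of the plateau is reached 9 h after anaphase.
#'
#' @param frameIntervalMin,durationH,anaphaseTimeH,releaseLeadH,assemblyTauH,
#'   assemblyPlateau kinetic model; see \linkS4class{TimelapseConfig}.
#' @param splitRatePerH,rejoinRatePerH,coheredDistUm,splitDistUm pair motion.
#' @param frapBleachTimeH,frapBleachDepth,frapMobileFraction,frapRecoveryTauH
#'   optional FRAP event (\code{frapBleachTimeH = NA} disables it).
#' @param intensityPcm,pixelSizeUm,fieldPx,psfSigmaUm,noiseGaussianSd,
#'   noisePoissonGain rendering and optics.
#' @return a validated \linkS4class{TimelapseConfig}.
#' @export
timelapseConfig <- function(frameIntervalMin = 12, durationH = 16,
                            anaphaseTimeH = 4, releaseLeadH = 2.5,
                            assemblyTauH = 9 / log(10),
                            assemblyPlateau = 300,
                            splitRatePerH = 0, rejoinRatePerH = 1,
                            coheredDistUm = c(0.6, 0.1),
                            splitDistUm = c(1.8, 3.0),
                            frapBleachTimeH = NA_real_,
                            frapBleachDepth = 0.5,
                            frapMobileFraction = 0.3,
                            frapRecoveryTauH = 3,
                            intensityPcm = 400, pixelSizeUm = 0.1,
                            fieldPx = 128L, psfSigmaUm = 0.1,
                            noiseGaussianSd = 2, noisePoissonGain = 0.5) {
  new("TimelapseConfig", pixelSizeUm = pixelSizeUm,
      fieldPx = as.integer(fieldPx), frameIntervalMin = frameIntervalMin,
      durationH = durationH, anaphaseTimeH = as.numeric(anaphaseTimeH),
      releaseLeadH = releaseLeadH, assemblyTauH = assemblyTauH,
      assemblyPlateau = assemblyPlateau, splitRatePerH = splitRatePerH,
      rejoinRatePerH = rejoinRatePerH, coheredDistUm = coheredDistUm,
      splitDistUm = splitDistUm,
      frapBleachTimeH = as.numeric(frapBleachTimeH),
      frapBleachDepth = frapBleachDepth,
      frapMobileFraction = frapMobileFraction,
      frapRecoveryTauH = frapRecoveryTauH, intensityPcm = intensityPcm,
      psfSigmaUm = psfSigmaUm, noiseGaussianSd = noiseGaussianSd,
      noisePoissonGain = noisePoissonGain)
}

# ---------------------------------------------------------------------------
# Scene containers
# ---------------------------------------------------------------------------

#' A rendered synthetic field with ground truth
#'
#' Holds the four-channel image array (x, y, channel; channels
#' \code{dna}, \code{centriole}, \code{pcm}, \code{rootletin}) together with
#' the ground truth used to render it: per-cell nucleus geometry and mitotic
#' flags, per-centriole positions, pair distances and split flags, per-root
#' areas and linkage flags, and the true nucleus and root label images.
#'
#' @slot images numeric array, \code{fieldPx x fieldPx x 4}.
#' @slot truth list with elements \code{cells}, \code{centrioles},
#'   \code{roots} (data frames), \code{nucleusLabels} and \code{rootLabels}
#'   (integer label matrices).
#' @slot config the \linkS4class{SceneConfig} that produced the scene.
#' @slot seed integer seed used for every random draw.
#' @exportClass Scene
setClass("Scene", representation(
  images = "array", truth = "list", config = "SceneConfig",
  seed = "integer"))

#' @describeIn Scene channel images as a named array
#' @param scene a \code{Scene}
#' @export
sceneImages <- function(scene) scene@images

#' @describeIn Scene ground-truth list
#' @export
sceneTruth <- function(scene) scene@truth

setMethod("show", "Scene", function(object) {
  tr <- object@truth
  cat(sprintf("Scene: %d x %d px (%.1f um/px), %d cells, seed %d\n",
              dim(object@images)[1], dim(object@images)[2],
              object@config@pixelSizeUm, nrow(tr$cells), object@seed))
  if (nrow(tr$cells) > 0)
    cat(sprintf("  %d centrioles, %d roots, %d/%d cells split\n",
                nrow(tr$centrioles), nrow(tr$roots),
                sum(tr$cells$splitFlag), nrow(tr$cells)))
})

#' A rendered synthetic time-lapse with ground truth
#'
#' @slot frames numeric array, \code{fieldPx x fieldPx x channel x frame};
#'   channels \code{pcm} and \code{rootletin}.
#' @slot truth list: \code{trace} data frame (frame, time, noiseless
#'   per-centrosome intensity, split state, pair distance, centriole
#'   positions), \code{anaphaseFrame}, \code{bleachFrame}.
#' @slot config the \linkS4class{TimelapseConfig}.
#' @slot seed integer seed.
#' @exportClass Timelapse
setClass("Timelapse", representation(
  frames = "array", truth = "list", config = "TimelapseConfig",
  seed = "integer"))

setMethod("show", "Timelapse", function(object) {
  d <- dim(object@frames)
  cat(sprintf("Timelapse: %d frames of %d x %d px, %.0f-min interval\n",
              d[4], d[1], d[2], object@config@frameIntervalMin))
  cat(sprintf("  anaphase frame: %s, bleach frame: %s\n",
              ifelse(is.na(object@truth$anaphaseFrame), "none",
                     object@truth$anaphaseFrame),
              ifelse(is.na(object@truth$bleachFrame), "none",
                     object@truth$bleachFrame)))
})

# ---------------------------------------------------------------------------
# Segmentation containers
# ---------------------------------------------------------------------------

#' An integer label image with physical scale
#'
#' Background is 0 and object labels are consecutive positive integers.
#'
#' @slot data integer matrix of labels.
#' @slot pixelSizeUm pixel size, micrometres.
#' @slot channel name of the source channel.
#' @exportClass LabelMap
setClass("LabelMap", representation(
  data = "matrix", pixelSizeUm = "numeric", channel = "character"))

setValidity("LabelMap", function(object) {
  lab <- object@data
  u <- sort(unique(as.integer(lab[lab > 0])))
  if (length(u) && !identical(u, seq_along(u)))
    return("labels must be consecutive positive integers")
  if (object@pixelSizeUm <= 0) return("pixelSizeUm must be > 0")
  TRUE
})

#' Construct a LabelMap, relabelling to consecutive integers
#' @param data integer matrix (0 = background).
#' @param pixelSizeUm pixel size in micrometres.
#' @param channel source channel name.
#' @export
labelMap <- function(data, pixelSizeUm, channel = "unknown") {
  data <- matrix(as.integer(round(data)), nrow(data), ncol(data))
  u <- sort(unique(data[data > 0]))
  if (length(u) && !identical(u, seq_along(u))) {
    remap <- integer(max(u)); remap[u] <- seq_along(u)
    pos <- data > 0
    data[pos] <- remap[data[pos]]
  }
  new("LabelMap", data = data, pixelSizeUm = pixelSizeUm, channel = channel)
}

#' @describeIn LabelMap the label matrix
#' @param x a \code{LabelMap}
#' @export
labelData <- function(x) x@data

#' @describeIn LabelMap number of labelled objects
#' @export
nObjects <- function(x) max(0L, max(x@data))

#' @describeIn LabelMap pixel size in micrometres
#' @export
pixelSize <- function(x) x@pixelSizeUm

setMethod("show", "LabelMap", function(object) {
  cat(sprintf("LabelMap (%s): %d x %d px, %d objects\n", object@channel,
              nrow(object@data), ncol(object@data), nObjects(object)))
})

#' A set of segmented root fibres
#'
#' Root pixels carry the label of the PCM seed they were propagated from,
#' so the labels partition the thresholded rootletin mask.
#'
#' @slot labels a \linkS4class{LabelMap} of root pixels.
#' @slot info data frame: \code{rootId}, \code{seedFocusId}, \code{cell},
#'   \code{areaPx}, \code{areaUm2}.
#' @exportClass RootSet
setClass("RootSet", representation(labels = "LabelMap", info = "data.frame"))

#' @describeIn RootSet per-root summary table
#' @param x a \code{RootSet}
#' @export
rootInfo <- function(x) x@info

#' @describeIn RootSet root label map
#' @export
rootLabels <- function(x) x@labels

setMethod("show", "RootSet", function(object) {
  cat(sprintf("RootSet: %d roots, total area %.1f um^2\n",
              nrow(object@info), sum(object@info$areaUm2)))
})

# ---------------------------------------------------------------------------
# Traces and kinetic fits
# ---------------------------------------------------------------------------

#' A time-indexed centrosomal intensity trace
#'
#' Background-corrected integrated intensity of one tracked centrosome,
#' one value per tracked frame. Gap frames (closed tracking gaps) are
#' linearly interpolated and flagged.
#'
#' @slot timeH time of each frame, hours from movie start.
#' @slot intensity background-corrected integrated intensity.
#' @slot frames frame indices (1-based).
#' @slot anaphaseFrame anaphase frame index or \code{NA}.
#' @slot bleachFrame bleach frame index or \code{NA}.
#' @slot gapFrames frame indices whose values were interpolated.
#' @slot trackId id of the source track.
#' @exportClass IntensityTrace
setClass("IntensityTrace", representation(
  timeH = "numeric", intensity = "numeric", frames = "integer",
  anaphaseFrame = "integer", bleachFrame = "integer",
  gapFrames = "integer", trackId = "integer"))

setValidity("IntensityTrace", function(object) {
  if (length(object@timeH) != length(object@intensity))
    return("timeH and intensity must have equal length")
  if (is.unsorted(object@frames, strictly = TRUE))
    return("frames must be strictly increasing")
  TRUE
})

#' Construct an IntensityTrace
#' @param timeH,intensity,frames,anaphaseFrame,bleachFrame,gapFrames,trackId
#'   see \linkS4class{IntensityTrace}.
#' @export
intensityTrace <- function(timeH, intensity, frames = seq_along(timeH),
                           anaphaseFrame = NA_integer_,
                           bleachFrame = NA_integer_,
                           gapFrames = integer(0), trackId = 1L) {
  new("IntensityTrace", timeH = as.numeric(timeH),
      intensity = as.numeric(intensity), frames = as.integer(frames),
      anaphaseFrame = as.integer(anaphaseFrame),
      bleachFrame = as.integer(bleachFrame),
      gapFrames = as.integer(gapFrames), trackId = as.integer(trackId))
}

#' @describeIn IntensityTrace trace as a data frame
#' @param x an \code{IntensityTrace}
#' @export
traceData <- function(x) data.frame(frame = x@frames, timeH = x@timeH,
                                    intensity = x@intensity,
                                    gap = x@frames %in% x@gapFrames)

setMethod("show", "IntensityTrace", function(object) {
  cat(sprintf(
    "IntensityTrace (track %d): %d frames over %.1f h, %d gap frame(s)\n",
    object@trackId, length(object@timeH), diff(range(object@timeH)),
    length(object@gapFrames)))
})

#' A fitted FRAP recovery model
#'
#' Single-exponential recovery with an immobile fraction:
#' \eqn{R(t) = f_m (1 - e^{-t/\tau})}. The plateau recovery percentage is
#' \eqn{100 f_m} by construction.
#'
#' @slot mobileFraction fitted mobile fraction, clipped to [0, 1].
#' @slot tauH fitted recovery time constant, hours.
#' @slot plateauRecoveryPct \code{100 * mobileFraction}.
#' @slot iPre,iPost pre- and post-bleach intensity levels of the raw trace.
#' @slot residSS residual sum of squares of the fit.
#' @slot nPoints number of post-bleach points fitted.
#' @exportClass FrapFit
setClass("FrapFit", representation(
  mobileFraction = "numeric", tauH = "numeric",
  plateauRecoveryPct = "numeric", iPre = "numeric", iPost = "numeric",
  residSS = "numeric", nPoints = "integer"))

#' @describeIn FrapFit fitted mobile fraction
#' @param x a \code{FrapFit}
#' @export
mobileFraction <- function(x) x@mobileFraction

setMethod("show", "FrapFit", function(object) {
  cat(sprintf(
    "FrapFit: mobile fraction %.3f (plateau recovery %.1f%%), tau %.2f h\n",
    object@mobileFraction, object@plateauRecoveryPct, object@tauH))
})

#' A fitted post-anaphase assembly model
#'
#' Saturating exponential \eqn{I(t) = I_0 + A (1 - e^{-t/\tau_a})} fitted to
#' an anaphase-aligned trace; the operational assembly duration is
#' \eqn{t_{90} = \tau_a \ln 10}, the time to reach 90% of the plateau.
#'
#' @slot i0 fitted baseline at anaphase.
#' @slot amplitude fitted amplitude \eqn{A}.
#' @slot tauH fitted time constant, hours.
#' @slot t90H \eqn{\tau_a \ln 10}, hours.
#' @slot residSS residual sum of squares.
#' @slot nPoints number of points fitted.
#' @exportClass AssemblyFit
setClass("AssemblyFit", representation(
  i0 = "numeric", amplitude = "numeric", tauH = "numeric", t90H = "numeric",
  residSS = "numeric", nPoints = "integer"))

#' @describeIn AssemblyFit assembly duration t90 in hours
#' @param x an \code{AssemblyFit}
#' @export
t90 <- function(x) x@t90H

setMethod("show", "AssemblyFit", function(object) {
  cat(sprintf("AssemblyFit: A %.1f, tau %.2f h, t90 %.2f h\n",
              object@amplitude, object@tauH, object@t90H))
})
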