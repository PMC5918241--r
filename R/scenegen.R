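# Synthetic scene generation: fixed multi-cell fields and single-cell
# time-lapses with full ground truth. All randomness is drawn from one
# generator stream seeded once per call.

# --- internal rendering helpers -------------------------------------------

# Set a labelled disc into an integer label matrix (no overwrite of
# existing labels). Returns the modified matrix.
setDiscLabel <- function(labels, cx, cy, radiusPx, id) {
  nx <- nrow(labels); ny <- ncol(labels)
  x0 <- max(1L, floor(cx - radiusPx)); x1 <- min(nx, ceiling(cx + radiusPx))
  y0 <- max(1L, floor(cy - radiusPx)); y1 <- min(ny, ceiling(cy + radiusPx))
  if (x0 > x1 || y0 > y1) return(labels)
  xs <- x0:x1; ys <- y0:y1
  sub <- labels[xs, ys]
  inside <- outer((xs - cx)^2, (ys - cy)^2, "+") <= radiusPx^2 & sub == 0L
  sub[inside] <- id
  labels[xs, ys] <- sub
  labels
}

# Number of pixels a rendered disc covers at a sub-pixel centre.
discPixelCount <- function(cx, cy, radiusPx) {
  xs <- floor(cx - radiusPx):ceiling(cx + radiusPx)
  ys <- floor(cy - radiusPx):ceiling(cy + radiusPx)
  sum(outer((xs - cx)^2, (ys - cy)^2, "+") <= radiusPx^2)
}

# Linear pixel indices of a polyline dilated to a tube, plus the indices of
# its 1-px dilation; computed on a local crop for speed.
tubeIndices <- function(segments, nx, ny, widthPx) {
  pts <- do.call(rbind, lapply(segments, function(s) {
    len <- sqrt(sum((s[2, ] - s[1, ])^2))
    n <- max(2L, ceiling(len * 4))
    tt <- seq(0, 1, length.out = n)
    cbind(s[1, 1] + tt * (s[2, 1] - s[1, 1]),
          s[1, 2] + tt * (s[2, 2] - s[1, 2]))
  }))
  pts <- unique(round(pts))
  pad <- widthPx + 2L
  x0 <- max(1L, min(pts[, 1]) - pad); x1 <- min(nx, max(pts[, 1]) + pad)
  y0 <- max(1L, min(pts[, 2]) - pad); y1 <- min(ny, max(pts[, 2]) + pad)
  lm <- matrix(0L, x1 - x0 + 1L, y1 - y0 + 1L)
  keep <- pts[, 1] >= 1 & pts[, 1] <= nx & pts[, 2] >= 1 & pts[, 2] <= ny
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) == 0) return(list(idx = integer(0), idxDil = integer(0)))
  lm[cbind(pts[, 1] - x0 + 1L, pts[, 2] - y0 + 1L)] <- 1L
  bsize <- max(3L, widthPx + (widthPx + 1L) %% 2L)
  tube <- as.matrix(EBImage::dilate(EBImage::Image(lm),
                                    EBImage::makeBrush(bsize, "disc"))) > 0
  dil <- as.matrix(EBImage::dilate(EBImage::Image(tube * 1L),
                                   EBImage::makeBrush(3, "box"))) > 0
  toGlobal <- function(mask) {
    w <- which(mask)
    lx <- (w - 1L) %% nrow(mask) + 1L
    ly <- (w - 1L) %/% nrow(mask) + 1L
    (ly + y0 - 2L) * nx + (lx + x0 - 1L)
  }
  list(idx = toGlobal(tube), idxDil = toGlobal(dil))
}

rotate2 <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                            sin(a) * v[1] + cos(a) * v[2])

# Branched root polyline: one trunk, one bifurcation into two branches.
# origin/partner in px; geometry (angles) is drawn once and reused across
# the area-calibration passes.
rootGeometry <- function(origin, partner, linked, distPx) {
  dirTo <- partner - origin
  nrm <- sqrt(sum(dirTo^2))
  dirTo <- if (nrm > 0) dirTo / nrm else c(1, 0)
  if (linked) {
    trunkDir <- rotate2(dirTo, stats::rnorm(1, 0, 0.12))
    minTrunk <- distPx / 2 + 2
  } else {
    trunkDir <- rotate2(-dirTo, stats::runif(1, -0.7, 0.7))
    minTrunk <- 0
  }
  list(trunkDir = trunkDir, minTrunk = minTrunk,
       branchAngles = stats::runif(2, 0.4, 0.9) * c(1, -1),
       branchSplit = stats::runif(1, 0.45, 0.55))
}

rootSegmentsFromGeometry <- function(origin, geom, totalLenPx) {
  trunkLen <- max(geom$minTrunk, 0.5 * totalLenPx)
  branchLen <- max(2, (totalLenPx - trunkLen) / 2)
  elbow <- origin + trunkLen * geom$trunkDir
  b1 <- elbow + branchLen * rotate2(geom$trunkDir, geom$branchAngles[1])
  b2 <- elbow + branchLen * rotate2(geom$trunkDir, geom$branchAngles[2])
  list(rbind(origin, elbow), rbind(elbow, b1), rbind(elbow, b2))
}

# Render one root to the target pixel area (two-pass length calibration).
renderRoot <- function(origin, partner, linked, distPx, targetAreaPx,
                       nx, ny, widthPx = 5L) {
  geom <- rootGeometry(origin, partner, linked, distPx)
  len0 <- max(geom$minTrunk + 4, targetAreaPx / widthPx)
  segs <- rootSegmentsFromGeometry(origin, geom, len0)
  ti <- tubeIndices(segs, nx, ny, widthPx)
  a0 <- length(ti$idx)
  if (a0 > 0 && abs(a0 - targetAreaPx) / targetAreaPx > 0.02) {
    len1 <- max(geom$minTrunk + 4, len0 * targetAreaPx / a0)
    segs <- rootSegmentsFromGeometry(origin, geom, len1)
    ti <- tubeIndices(segs, nx, ny, widthPx)
  }
  ti
}

# PSF blur, Poisson shot noise, Gaussian read noise and (when any noise is
# on) integer quantisation mimicking camera digitisation.
applyOptics <- function(img, psfSigmaPx, gaussianSd, poissonGain) {
  if (psfSigmaPx > 0)
    img <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                    sigma = psfSigmaPx))
  noisy <- FALSE
  if (poissonGain > 0) {
    img <- matrix(stats::rpois(length(img), pmax(img, 0) * poissonGain),
                  nrow(img)) / poissonGain
    noisy <- TRUE
  }
  if (gaussianSd > 0) {
    img <- img + matrix(stats::rnorm(length(img), 0, gaussianSd), nrow(img))
    noisy <- TRUE
  }
  if (noisy) img <- pmax(round(img), 0)
  img
}

cohered99 <- function(config) {
  config@coheredDistUm[1] + stats::qnorm(0.99) * config@coheredDistUm[2]
}

# Draw one pair distance (um) and its split flag. Cohered draws are clipped
# below the 99th percentile so that splitFlag <=> distance above the
# cohered regime holds exactly.
drawPairDistance <- function(config) {
  c99 <- cohered99(config)
  if (length(config@distanceRangeUm) == 2) {
    d <- stats::runif(1, config@distanceRangeUm[1], config@distanceRangeUm[2])
    return(list(d = d, split = d > c99))
  }
  split <- stats::runif(1) < config@pSplit
  d <- if (split) {
    stats::runif(1, config@splitDistUm[1], config@splitDistUm[2])
  } else {
    min(max(0.05, stats::rnorm(1, config@coheredDistUm[1],
                               config@coheredDistUm[2])), c99)
  }
  list(d = d, split = split)
}

# --- population scenes -----------------------------------------------------

#' Simulate a fixed multi-cell field with ground truth
#'
#' Renders a four-channel field (DNA, centriole, PCM, rootletin). Cells are
#' placed by rejection sampling without nucleus overlap; each cell carries a
#' centriole pair (or two pairs) whose inter-centriole distance is drawn
#' from the cohered/split mixture of the configuration; each interphase
#' centriole grows a branched root fibre (one bifurcation) whose pixel area
#' is calibrated to \code{rootAreaScale} times the centriole-focus area.
#' The roots of a pair are rendered overlapping with probability given by a
#' decreasing logistic of the pair distance; the ground-truth linkage flag
#' is then measured from the rendered masks (one-pixel-dilation overlap), so
#' the truth invariant holds by construction. Mitotic cells are rendered
#' with condensed chromatin (smaller, brighter nuclei) and no roots.
#' Finally each channel is PSF-blurred and carries Poisson shot noise plus
#' Gaussian read noise.
#'
#' Identical \code{(config, seed)} give bit-identical output.
#'
#' @param config a \linkS4class{SceneConfig}.
#' @param seed integer seed for all randomness.
#' @return a \linkS4class{Scene}.
#' @examples
#' sc <- simulateField(sceneConfig(nCells = 3L, fieldPx = 300L), seed = 1)
#' sc
#' @export
simulateField <- function(config, seed) {
  validObject(config)
  withSeed(seed, {
    ps <- config@pixelSizeUm
    n <- config@fieldPx
    chans <- c("dna", "centriole", "pcm", "rootletin")
    chDna <- matrix(0, n, n); chCent <- matrix(0, n, n)
    chPcm <- matrix(0, n, n); chRtl <- matrix(0, n, n)
    nucleusLabels <- matrix(0L, n, n)
    rootLabelsM <- matrix(0L, n, n)

    # nucleus placement by rejection sampling
    rNucPx <- config@nucleusRadiusUm / ps
    marginPx <- rNucPx + 2
    minSepPx <- config@minSeparationUm / ps
    centers <- matrix(NA_real_, config@nCells, 2)
    if (config@nCells > 0) {
      if (n - 2 * marginPx < 1)
        stop("field too small for the configured nucleus radius")
      for (k in seq_len(config@nCells)) {
        placed <- FALSE
        for (try in seq_len(200)) {
          cand <- stats::runif(2, 1 + marginPx, n - marginPx)
          if (k == 1 || all(sqrt(rowSums(
            (centers[seq_len(k - 1), , drop = FALSE] -
               matrix(cand, k - 1, 2, byrow = TRUE))^2)) >= minSepPx)) {
            centers[k, ] <- cand
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop(sprintf(paste0(
            "could not place cell %d of %d after 200 attempts: cell ",
            "density too high for field of %d px at %.1f um separation"),
            k, config@nCells, n, config@minSeparationUm))
      }
    }

    cells <- data.frame(cell = integer(0), nucXUm = numeric(0),
                        nucYUm = numeric(0), nucleusRadiusUm = numeric(0),
                        mitotic = logical(0), splitFlag = logical(0),
                        pairDistanceUm = numeric(0))
    centrioles <- data.frame(id = integer(0), cell = integer(0),
                             pairId = integer(0), xUm = numeric(0),
                             yUm = numeric(0), pairDistanceUm = numeric(0),
                             splitFlag = logical(0))
    roots <- data.frame(id = integer(0), cell = integer(0),
                        centrioleId = integer(0), pairId = integer(0),
                        areaPx = integer(0), areaUm2 = numeric(0),
                        linked = logical(0))

    rCentPx <- 0.3 / ps
    rPcmPx <- 0.4 / ps
    rootWidthPx <- 5L
    centId <- 0L; rootId <- 0L; pairId <- 0L
    fieldCenter <- c((n + 1) / 2, (n + 1) / 2)
    edgeGuardPx <- 8 / ps

    for (k in seq_len(config@nCells)) {
      mitotic <- stats::runif(1) < config@pMitotic
      rNuc <- rNucPx * (if (mitotic) 0.55 else stats::runif(1, 0.9, 1.1))
      dnaLevel <- config@intensity["dna"] *
        (if (mitotic) 3 else stats::runif(1, 0.9, 1.1))
      cx <- centers[k, 1]; cy <- centers[k, 2]
      chDna <- addDisc(chDna, cx, cy, rNuc, dnaLevel)
      nucleusLabels <- setDiscLabel(nucleusLabels, cx, cy, rNuc, k)

      # centrosome site just outside the nucleus, biased inwards near edges
      nearEdge <- min(cx, cy, n - cx, n - cy) < edgeGuardPx
      ang <- if (nearEdge) {
        atan2(fieldCenter[2] - cy, fieldCenter[1] - cx) +
          stats::runif(1, -pi / 3, pi / 3)
      } else stats::runif(1, 0, 2 * pi)
      siteDist <- rNuc + config@centrioleOffsetUm / ps
      nPairs <- config@nCentrioles %/% 2L
      site0 <- c(cx + siteDist * cos(ang), cy + siteDist * sin(ang))
      cellSplit <- FALSE; cellDist <- NA_real_

      for (p in seq_len(nPairs)) {
        pairId <- pairId + 1L
        site <- site0
        if (p > 1) {  # second pair offset by its own cohered/split draw
          off <- drawPairDistance(config)
          oa <- stats::runif(1, 0, 2 * pi)
          site <- site0 + off$d / ps * c(cos(oa), sin(oa))
        }
        dp <- drawPairDistance(config)
        if (p == 1) { cellSplit <- dp$split; cellDist <- dp$d }
        phi <- stats::runif(1, 0, 2 * pi)
        half <- dp$d / 2 / ps
        p1 <- site + half * c(cos(phi), sin(phi))
        p2 <- site - half * c(cos(phi), sin(phi))
        pos <- rbind(p1, p2)

        tubes <- vector("list", 2)
        intendedLink <- stats::runif(1) <
          linkProbability(dp$d, config@linkMidpointUm, config@linkSteepness)
        for (m in 1:2) {
          centId <- centId + 1L
          centrioles <- rbind(centrioles, data.frame(
            id = centId, cell = k, pairId = pairId,
            xUm = pxToUm(pos[m, 1], ps), yUm = pxToUm(pos[m, 2], ps),
            pairDistanceUm = dp$d, splitFlag = dp$split))
          chCent <- addDisc(chCent, pos[m, 1], pos[m, 2], rCentPx,
                            config@intensity["centriole"])
          chPcm <- addDisc(chPcm, pos[m, 1], pos[m, 2], rPcmPx,
                           config@intensity["pcm"])
          if (!mitotic) {
            focusPx <- discPixelCount(pos[m, 1], pos[m, 2], rCentPx)
            tubes[[m]] <- renderRoot(
              pos[m, ], pos[3 - m, ], intendedLink, dp$d / ps,
              config@rootAreaScale * focusPx, n, n, rootWidthPx)
          }
        }
        if (!mitotic) {
          linkedMeasured <- length(intersect(tubes[[1]]$idxDil,
                                             tubes[[2]]$idx)) > 0
          for (m in 1:2) {
            rootId <- rootId + 1L
            idx <- tubes[[m]]$idx
            chRtl[idx] <- chRtl[idx] + config@intensity["rootletin"]
            free <- idx[rootLabelsM[idx] == 0L]
            rootLabelsM[free] <- rootId
            roots <- rbind(roots, data.frame(
              id = rootId, cell = k, centrioleId = centId - 2L + m,
              pairId = pairId, areaPx = length(idx),
              areaUm2 = length(idx) * ps^2, linked = linkedMeasured))
          }
        }
      }
      cells <- rbind(cells, data.frame(
        cell = k, nucXUm = pxToUm(cx, ps), nucYUm = pxToUm(cy, ps),
        nucleusRadiusUm = rNuc * ps, mitotic = mitotic,
        splitFlag = cellSplit, pairDistanceUm = cellDist))
    }

    psfPx <- config@psfSigmaUm / ps
    img <- array(0, dim = c(n, n, 4), dimnames = list(NULL, NULL, chans))
    raw <- list(chDna, chCent, chPcm, chRtl)
    for (ci in 1:4)
      img[, , ci] <- applyOptics(raw[[ci]], psfPx,
                                 config@noiseGaussianSd,
                                 config@noisePoissonGain)

    new("Scene", images = img,
        truth = list(cells = cells, centrioles = centrioles, roots = roots,
                     nucleusLabels = nucleusLabels,
                     rootLabels = rootLabelsM),
        config = config, seed = as.integer(seed))
  })
}

# --- time-lapse ------------------------------------------------------------

#' Simulate the two-state split/rejoin state sequence
#'
#' Continuous-time two-state Markov process (cohered/split) sampled at the
#' frame interval: per frame, a cohered pair splits with probability
#' \code{1 - exp(-splitRatePerH * dtH)} and a split pair rejoins with
#' probability \code{1 - exp(-rejoinRatePerH * dtH)}. The stationary split
#' fraction is \code{splitRate / (splitRate + rejoinRate)}.
#'
#' @param nFrames number of frames.
#' @param dtH frame interval in hours.
#' @param splitRatePerH,rejoinRatePerH transition rates per hour.
#' @param startSplit initial state.
#' @return logical vector, \code{TRUE} = split.
#' @export
simulateSplitStates <- function(nFrames, dtH, splitRatePerH, rejoinRatePerH,
                                startSplit = FALSE) {
  pSplit <- 1 - exp(-splitRatePerH * dtH)
  pRejoin <- 1 - exp(-rejoinRatePerH * dtH)
  s <- logical(nFrames)
  s[1] <- startSplit
  if (nFrames > 1) {
    u <- stats::runif(nFrames - 1)
    for (i in 2:nFrames)
      s[i] <- if (s[i - 1]) u[i - 1] >= pRejoin else u[i - 1] < pSplit
  }
  s
}

#' Noiseless kinetic model trace of a time-lapse configuration
#'
#' The per-centrosome rootletin intensity the generator renders, before
#' optics and noise: plateau, linear pre-anaphase release, post-anaphase
#' saturating-exponential assembly, and the optional FRAP bleach/recovery
#' factor.
#'
#' @param config a \linkS4class{TimelapseConfig}.
#' @param timeH times (hours from movie start) at which to evaluate.
#' @return numeric vector of intensities.
#' @export
kineticModelTrace <- function(config, timeH) {
  P <- config@assemblyPlateau
  base <- rep(P, length(timeH))
  if (!is.na(config@anaphaseTimeH)) {
    ta <- config@anaphaseTimeH
    lead <- config@releaseLeadH
    declining <- timeH >= (ta - lead) & timeH < ta
    base[declining] <- P * (ta - timeH[declining]) / lead
    post <- timeH >= ta
    base[post] <- P * (1 - exp(-(timeH[post] - ta) / config@assemblyTauH))
  }
  if (!is.na(config@frapBleachTimeH)) {
    tb <- config@frapBleachTimeH
    d <- config@frapBleachDepth
    fm <- config@frapMobileFraction
    tr <- config@frapRecoveryTauH
    after <- timeH >= tb
    rec <- if (tr > 0) 1 - exp(-(timeH[after] - tb) / tr) else 1
    base[after] <- base[after] * ((1 - d) + d * fm * rec)
  }
  base
}

#' Simulate a single-cell time-lapse with ground truth
#'
#' Renders a movie with \code{pcm} and \code{rootletin} channels. The PCM
#' channel carries a constant total intensity per centrosome (the tracking
#' marker); the rootletin channel carries the kinetic model of
#' [kineticModelTrace()], split equally between the two centrioles. The
#' pair follows the two-state split/rejoin process; within a state the
#' distance relaxes smoothly towards the state's regime so frame-to-frame
#' displacements stay small. The truth records the noiseless
#' per-centrosome trace, the state sequence, positions, and the anaphase
#' and bleach frames.
#'
#' @param config a \linkS4class{TimelapseConfig}.
#' @param seed integer seed.
#' @return a \linkS4class{Timelapse}.
#' @export
simulateTimelapse <- function(config, seed) {
  validObject(config)
  withSeed(seed, {
    ps <- config@pixelSizeUm
    n <- config@fieldPx
    dtH <- config@frameIntervalMin / 60
    nFrames <- floor(config@durationH / dtH) + 1L
    timeH <- (seq_len(nFrames) - 1) * dtH
    anaFrame <- if (is.na(config@anaphaseTimeH)) NA_integer_ else
      which(timeH >= config@anaphaseTimeH)[1]
    bleachFrame <- if (is.na(config@frapBleachTimeH)) NA_integer_ else
      which(timeH >= config@frapBleachTimeH)[1]
    if (!is.na(anaFrame) && !is.na(bleachFrame) &&
        abs(anaFrame - bleachFrame) < 1L)
      stop("FRAP bleach and anaphase fall in the same frame: annotation ",
           "would be ambiguous")

    trace <- kineticModelTrace(config, timeH)
    states <- simulateSplitStates(nFrames, dtH, config@splitRatePerH,
                                  config@rejoinRatePerH, startSplit = FALSE)

    c99 <- config@coheredDistUm[1] +
      stats::qnorm(0.99) * config@coheredDistUm[2]
    d <- numeric(nFrames)
    d[1] <- min(max(0.05, stats::rnorm(1, config@coheredDistUm[1],
                                       config@coheredDistUm[2])), c99)
    target <- NA_real_
    for (i in 2:nFrames) {
      if (states[i]) {
        if (!states[i - 1] || is.na(target))
          target <- stats::runif(1, config@splitDistUm[1],
                                 config@splitDistUm[2])
        d[i] <- d[i - 1] + 0.3 * (target - d[i - 1]) +
          stats::rnorm(1, 0, 0.05)
        d[i] <- min(max(d[i], 0.05), config@splitDistUm[2])
      } else {
        d[i] <- d[i - 1] + 0.25 * (config@coheredDistUm[1] - d[i - 1]) +
          stats::rnorm(1, 0, config@coheredDistUm[2] * 0.3)
        d[i] <- min(max(d[i], 0.05), c99)
      }
    }

    mid <- matrix(0, nFrames, 2)
    mid[1, ] <- c((n + 1) / 2, (n + 1) / 2)
    angle <- numeric(nFrames)
    angle[1] <- stats::runif(1, 0, 2 * pi)
    stepPx <- 0.05 / ps
    for (i in 2:nFrames) {
      mid[i, ] <- mid[i - 1, ] + stats::rnorm(2, 0, stepPx)
      # keep the cell comfortably inside the field
      mid[i, ] <- pmin(pmax(mid[i, ], n * 0.3), n * 0.7)
      angle[i] <- angle[i - 1] + stats::rnorm(1, 0, 0.05)
    }
    u <- cbind(cos(angle), sin(angle))
    halfPx <- d / 2 / ps
    p1 <- mid + halfPx * u
    p2 <- mid - halfPx * u

    chans <- c("pcm", "rootletin")
    frames <- array(0, dim = c(n, n, 2, nFrames),
                    dimnames = list(NULL, NULL, chans, NULL))
    psfPx <- config@psfSigmaUm / ps
    spotSigmaPx <- 0.2 / ps   # compact centrosomal focus, well above the noise floor
    for (i in seq_len(nFrames)) {
      pcm <- matrix(0, n, n)
      rtl <- matrix(0, n, n)
      for (pp in list(p1[i, ], p2[i, ])) {
        pcm <- addGaussianSpot(pcm, pp[1], pp[2], spotSigmaPx,
                               config@intensityPcm)
        rtl <- addGaussianSpot(rtl, pp[1], pp[2], spotSigmaPx,
                               trace[i] / 2)
      }
      frames[, , "pcm", i] <- applyOptics(pcm, psfPx,
                                          config@noiseGaussianSd,
                                          config@noisePoissonGain)
      frames[, , "rootletin", i] <- applyOptics(rtl, psfPx,
                                                config@noiseGaussianSd,
                                                config@noisePoissonGain)
    }

    truthTrace <- data.frame(
      frame = seq_len(nFrames), timeH = timeH, intensity = trace,
      split = states, distanceUm = d,
      x1Um = pxToUm(p1[, 1], ps), y1Um = pxToUm(p1[, 2], ps),
      x2Um = pxToUm(p2[, 1], ps), y2Um = pxToUm(p2[, 2], ps))
    new("Timelapse", frames = frames,
        truth = list(trace = truthTrace, anaphaseFrame = anaFrame,
                     bleachFrame = bleachFrame),
        config = config, seed = as.integer(seed))
  })
}

# --- fixtures --------------------------------------------------------------

#' Load a named fixture configuration
#'
#' Fixture populations shipped with the package (under
#' \code{inst/extdata}): \code{rpe_like} (low split prevalence, large
#' roots), \code{hela_like} (high split prevalence, short roots),
#' \code{overexpression_like} (rootletin-overexpressing cells with four
#' centrioles, strongly cohered), \code{linkage_sweep} (pair distances
#' drawn uniformly over 0.3--4 um for linkage-curve estimation),
#' \code{timelapse} (anaphase-aligned assembly kinetics) and \code{frap}
#' (whole-centrosome bleach). Numeric population parameters live in the
#' JSON fixtures, not in code.
#'
#' @param name fixture name.
#' @param ... overrides passed to [sceneConfig()] or [timelapseConfig()].
#' @return a \linkS4class{SceneConfig} or \linkS4class{TimelapseConfig}.
#' @examples
#' cfg <- fixtureConfig("rpe_like", nCells = 8L, fieldPx = 500L)
#' @export
fixtureConfig <- function(name, ...) {
  path <- system.file("extdata", paste0(name, ".json"),
                      package = "rootcohesion")
  if (path == "")
    stop("unknown fixture: ", name)
  fields <- jsonlite::read_json(path, simplifyVector = TRUE)
  type <- fields$type
  fields$type <- NULL
  # "none" is the JSON sentinel for a disabled (NA) scalar
  fields <- lapply(fields,
                   function(v) if (identical(v, "none")) NA_real_ else v)
  args <- utils::modifyList(fields, list(...))
  if (!is.null(args[["intensity"]]))
    args[["intensity"]] <- unlist(args[["intensity"]])
  if (identical(type, "timelapse")) do.call(timelapseConfig, args)
  else do.call(sceneConfig, args)
}
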