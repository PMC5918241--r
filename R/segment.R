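# Segmentation of nuclei, cytoplasm, foci and root fibres. The stages
# mirror a classic image-cytometry pipeline: global threshold + labelling
# for nuclei, seeded watershed outwards for cytoplasm, shape-based
# declumping for foci, and seeded propagation for root fibres.

#' Segment nuclei from a DNA channel
#'
#' Global threshold (Otsu or robust-background), hole filling, connected
#' component labelling (8-connectivity) and removal of objects below
#' \code{minAreaPx}. A blank image yields an empty label map, not an error.
#'
#' @param dna numeric matrix, DNA channel.
#' @param pixelSizeUm pixel size, micrometres.
#' @param minAreaPx minimum object area in pixels.
#' @param thresholdMethod \code{"otsu"} or \code{"robust_background"}.
#' @return a \linkS4class{LabelMap}.
#' @export
segmentNuclei <- function(dna, pixelSizeUm, minAreaPx = 200,
                          thresholdMethod = c("otsu", "robust_background")) {
  thresholdMethod <- match.arg(thresholdMethod)
  th <- autoThreshold(dna, thresholdMethod)
  mask <- dna > th
  if (!any(mask))
    return(labelMap(matrix(0L, nrow(dna), ncol(dna)), pixelSizeUm, "dna"))
  lab <- EBImage::bwlabel(EBImage::fillHull(EBImage::Image(mask * 1)))
  lab <- as.matrix(lab)
  areas <- tabulate(lab[lab > 0])
  small <- which(areas < minAreaPx)
  if (length(small)) lab[lab %in% small] <- 0L
  labelMap(lab, pixelSizeUm, "dna")
}

#' Assign cytoplasm to nuclei by seeded watershed
#'
#' Propagates nucleus labels outwards so that every pixel of the field is
#' assigned to exactly one nucleus; nucleus pixels keep their label. With a
#' reference channel the propagation front follows the inverted reference
#' intensity; with \code{reference = NULL} (a flat field) the assignment
#' reduces to geodesic nearest-seed, i.e. the boundary between two
#' equidistant nuclei runs along their perpendicular bisector.
#'
#' @param nuclei nucleus \linkS4class{LabelMap}.
#' @param reference optional numeric matrix guiding the watershed.
#' @return cytoplasm \linkS4class{LabelMap} (one region per nucleus).
#' @export
assignCytoplasm <- function(nuclei, reference = NULL) {
  seeds <- labelData(nuclei)
  if (is.null(reference)) {
    reference <- matrix(0, nrow(seeds), ncol(seeds))
  } else if (!all(dim(reference) == dim(seeds))) {
    stop(sprintf("reference (%d x %d) and nuclei (%d x %d) shapes differ",
                 nrow(reference), ncol(reference),
                 nrow(seeds), ncol(seeds)))
  } else {
    reference <- max(reference) - reference  # invert: bright = barrier
  }
  if (max(seeds) == 0)
    return(labelMap(matrix(0L, nrow(seeds), ncol(seeds)),
                    pixelSize(nuclei), "cytoplasm"))
  out <- EBImage::propagate(EBImage::Image(reference),
                            EBImage::Image(seeds), lambda = 1e-4)
  labelMap(as.matrix(out), pixelSize(nuclei), "cytoplasm")
}

#' Detect fluorescent foci
#'
#' Thresholds the channel and labels connected components; with
#' \code{declump = TRUE}, touching foci are split by a watershed on the
#' distance transform of the mask (distance-transform maxima act as
#' markers), the standard shape-based declumping. Each focus is assigned to
#' the cell whose region contains its centroid.
#'
#' @param channel numeric matrix.
#' @param cells optional cell \linkS4class{LabelMap} (from
#'   [assignCytoplasm()]); \code{NULL} leaves cell ids \code{NA}.
#' @param pixelSizeUm pixel size; taken from \code{cells} when given.
#' @param declump split touching foci by shape (default \code{TRUE}).
#' @param thresholdMethod \code{"otsu"} (default) or
#'   \code{"robust_background"}.
#' @param minAreaPx discard components smaller than this.
#' @param channelName stored in the output records.
#' @return data frame of focus records: \code{focusId}, \code{cell},
#'   \code{xUm}, \code{yUm}, \code{areaPx}, \code{areaUm2},
#'   \code{integrated}, \code{mean}, \code{channel}.
#' @export
detectFoci <- function(channel, cells = NULL, pixelSizeUm = NULL,
                       declump = TRUE,
                       thresholdMethod = c("otsu", "robust_background"),
                       minAreaPx = 4, channelName = "pcm") {
  thresholdMethod <- match.arg(thresholdMethod)
  if (is.null(pixelSizeUm)) {
    if (is.null(cells)) stop("pixelSizeUm required when cells is NULL")
    pixelSizeUm <- pixelSize(cells)
  }
  if (!is.null(cells) && !all(dim(channel) == dim(labelData(cells))))
    stop("channel and cell map shapes differ")
  th <- autoThreshold(channel, thresholdMethod)
  mask <- channel > th
  empty <- data.frame(focusId = integer(0), cell = integer(0),
                      xUm = numeric(0), yUm = numeric(0),
                      areaPx = integer(0), areaUm2 = numeric(0),
                      integrated = numeric(0), mean = numeric(0),
                      channel = character(0))
  if (!any(mask)) return(empty)
  if (declump) {
    dm <- EBImage::distmap(EBImage::Image(mask * 1))
    lab <- as.matrix(EBImage::watershed(dm, tolerance = 1, ext = 1))
  } else {
    lab <- as.matrix(EBImage::bwlabel(EBImage::Image(mask * 1)))
  }
  areas <- tabulate(lab[lab > 0])
  small <- which(areas < minAreaPx)
  if (length(small)) lab[lab %in% small] <- 0L
  if (!any(lab > 0)) return(empty)
  lm <- labelMap(lab, pixelSizeUm, channelName)
  st <- labelStats(labelData(lm), channel, pixelSizeUm)
  cellId <- rep(NA_integer_, nrow(st))
  if (!is.null(cells)) {
    cl <- labelData(cells)
    ci <- pmin(pmax(round(st$xUm / pixelSizeUm) + 1, 1), nrow(cl))
    cj <- pmin(pmax(round(st$yUm / pixelSizeUm) + 1, 1), ncol(cl))
    cellId <- cl[cbind(ci, cj)]
    cellId[cellId == 0] <- NA_integer_
  }
  data.frame(focusId = st$label, cell = cellId, xUm = st$xUm, yUm = st$yUm,
             areaPx = st$areaPx, areaUm2 = st$areaUm2,
             integrated = st$integrated, mean = st$mean,
             channel = channelName)
}

#' Segment root fibres
#'
#' With \code{method = "propagation"} (the default), the rootletin channel
#' is thresholded and labels are grown outwards from PCM seed regions
#' across the thresholded pixels, so each root pixel is assigned to the
#' seed reached first along connected paths; the resulting labels partition
#' the thresholded mask. With \code{method = "direct"}, roots are plain
#' connected components without seed identity.
#'
#' @param rootletin numeric matrix, rootletin channel.
#' @param pcmFoci focus records (from [detectFoci()]) used as seeds;
#'   required for propagation.
#' @param pixelSizeUm pixel size, micrometres.
#' @param method \code{"propagation"} or \code{"direct"}.
#' @param thresholdMethod \code{"otsu"} (default) or
#'   \code{"robust_background"} (5% trim, mean + k SD).
#' @param k SD multiplier for the robust-background threshold.
#' @param seedRadiusUm radius of the rendered seed disc per PCM focus.
#' @return a \linkS4class{RootSet}.
#' @export
segmentRoots <- function(rootletin, pcmFoci = NULL, pixelSizeUm,
                         method = c("propagation", "direct"),
                         thresholdMethod = c("otsu", "robust_background"),
                         k = 2, seedRadiusUm = 0.3) {
  method <- match.arg(method)
  thresholdMethod <- match.arg(thresholdMethod)
  th <- autoThreshold(rootletin, thresholdMethod, k = k)
  mask <- rootletin > th
  emptyInfo <- data.frame(rootId = integer(0), seedFocusId = integer(0),
                          cell = integer(0), areaPx = integer(0),
                          areaUm2 = numeric(0))
  if (method == "direct") {
    lab <- if (any(mask))
      as.matrix(EBImage::bwlabel(EBImage::Image(mask * 1)))
    else matrix(0L, nrow(rootletin), ncol(rootletin))
    lm <- labelMap(lab, pixelSizeUm, "rootletin")
    st <- labelStats(labelData(lm), pixelSizeUm = pixelSizeUm)
    info <- data.frame(rootId = st$label,
                       seedFocusId = rep(NA_integer_, nrow(st)),
                       cell = rep(NA_integer_, nrow(st)),
                       areaPx = st$areaPx, areaUm2 = st$areaUm2)
    return(new("RootSet", labels = lm, info = info))
  }
  if (is.null(pcmFoci) || nrow(pcmFoci) == 0)
    stop("propagation requires at least one PCM seed focus")
  seeds <- matrix(0L, nrow(rootletin), ncol(rootletin))
  rPx <- seedRadiusUm / pixelSizeUm
  for (i in seq_len(nrow(pcmFoci)))
    seeds <- setDiscLabel(seeds, pcmFoci$xUm[i] / pixelSizeUm + 1,
                          pcmFoci$yUm[i] / pixelSizeUm + 1, rPx, i)
  propMask <- mask | seeds > 0
  lab <- as.matrix(EBImage::propagate(EBImage::Image(rootletin),
                                      EBImage::Image(seeds),
                                      mask = EBImage::Image(propMask * 1),
                                      lambda = 1e-4))
  lab[!mask] <- 0L  # root pixels are thresholded pixels only
  present <- sort(unique(lab[lab > 0]))
  if (length(present) == 0)
    return(new("RootSet",
               labels = labelMap(lab, pixelSizeUm, "rootletin"),
               info = emptyInfo))
  remap <- integer(max(present)); remap[present] <- seq_along(present)
  lab[lab > 0] <- remap[lab[lab > 0]]
  lm <- labelMap(lab, pixelSizeUm, "rootletin")
  st <- labelStats(labelData(lm), pixelSizeUm = pixelSizeUm)
  cellCol <- if ("cell" %in% names(pcmFoci)) pcmFoci$cell[present]
             else rep(NA_integer_, length(present))
  info <- data.frame(rootId = st$label,
                     seedFocusId = pcmFoci$focusId[present],
                     cell = cellCol, areaPx = st$areaPx,
                     areaUm2 = st$areaUm2)
  new("RootSet", labels = lm, info = info)
}

#' Measure labelled objects against an intensity channel
#'
#' Per label: pixel and physical area, centroid (micrometres), and
#' integrated and mean background-subtracted intensity. The background is
#' the median of non-object pixels within the owning cell when a cell map
#' is supplied, otherwise the global median of non-object pixels.
#'
#' @param labels a \linkS4class{LabelMap}.
#' @param intensity numeric matrix, aligned with \code{labels}.
#' @param cells optional cell \linkS4class{LabelMap} for per-cell
#'   background estimation.
#' @return data frame: \code{label}, \code{cell}, \code{areaPx},
#'   \code{areaUm2}, \code{xUm}, \code{yUm}, \code{integrated},
#'   \code{mean}, \code{background}.
#' @export
measureObjects <- function(labels, intensity, cells = NULL) {
  lab <- labelData(labels)
  if (!all(dim(lab) == dim(intensity)))
    stop("labels and intensity shapes differ")
  ps <- pixelSize(labels)
  st <- labelStats(lab, intensity, ps)
  if (nrow(st) == 0)
    return(data.frame(label = integer(0), cell = integer(0),
                      areaPx = integer(0), areaUm2 = numeric(0),
                      xUm = numeric(0), yUm = numeric(0),
                      integrated = numeric(0), mean = numeric(0),
                      background = numeric(0)))
  if (is.null(cells)) {
    bg <- stats::median(intensity[lab == 0])
    cellId <- rep(NA_integer_, nrow(st))
    bgs <- rep(bg, nrow(st))
  } else {
    cl <- labelData(cells)
    ci <- pmin(pmax(round(st$xUm / ps) + 1, 1), nrow(cl))
    cj <- pmin(pmax(round(st$yUm / ps) + 1, 1), ncol(cl))
    cellId <- cl[cbind(ci, cj)]
    bgPerCell <- vapply(seq_len(max(cl)), function(cc) {
      px <- intensity[cl == cc & lab == 0]
      if (length(px)) stats::median(px) else 0
    }, numeric(1))
    bgs <- ifelse(cellId > 0, bgPerCell[pmax(cellId, 1)],
                  stats::median(intensity[lab == 0]))
    cellId[cellId == 0] <- NA_integer_
  }
  data.frame(label = st$label, cell = cellId, areaPx = st$areaPx,
             areaUm2 = st$areaUm2, xUm = st$xUm, yUm = st$yUm,
             integrated = st$integrated - bgs * st$areaPx,
             mean = st$mean - bgs, background = bgs)
}

#' Flag mitotic cells from condensed chromatin
#'
#' A cell is flagged mitotic when its DNA object is both brighter and more
#' compact than the field: mean intensity above \code{intensityFactor}
#' times the field median, and area below \code{1 / areaFactor} times the
#' field median. Raising either factor makes the rule stricter, so the
#' flag count is monotone non-increasing in both.
#'
#' @param dna numeric matrix, DNA channel.
#' @param nuclei nucleus \linkS4class{LabelMap}.
#' @param intensityFactor brightness multiplier over the field median.
#' @param areaFactor compactness divisor; flagged cells have area below
#'   \code{median / areaFactor}.
#' @return data frame: \code{cell}, \code{meanIntensity}, \code{areaPx},
#'   \code{mitotic}.
#' @export
excludeMitotic <- function(dna, nuclei, intensityFactor = 2,
                           areaFactor = 1.4) {
  st <- labelStats(labelData(nuclei), dna, pixelSize(nuclei))
  if (nrow(st) == 0)
    return(data.frame(cell = integer(0), meanIntensity = numeric(0),
                      areaPx = integer(0), mitotic = logical(0)))
  medInt <- stats::median(st$mean)
  medArea <- stats::median(st$areaPx)
  data.frame(cell = st$label, meanIntensity = st$mean, areaPx = st$areaPx,
             mitotic = st$mean > intensityFactor * medInt &
               st$areaPx < medArea / areaFactor)
}
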