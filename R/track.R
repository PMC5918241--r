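# Centrosome tracking: frame-to-frame optimal assignment with a per-link
# displacement cap, then gap closing between track ends and starts. Scoped
# to the few-objects-per-frame regime of centrosome movies; the assignment
# is solved exactly by branch and bound.

# Exact minimum-cost assignment of rows to columns of `cost` (Inf =
# forbidden), where an unassigned row costs `dummyCost`. Returns an
# integer vector: column per row, NA = unassigned.
solveAssignment <- function(cost, dummyCost) {
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0) return(integer(0))
  if (nr > 12 || nc > 12)
    stop("assignment instance too large for exact solver (> 12 objects)")
  env <- new.env()
  env$bestCost <- Inf
  env$bestAssign <- rep(NA_integer_, nr)
  assign <- rep(NA_integer_, nr)
  usedCols <- logical(nc)
  recurse <- function(row, acc) {
    if (acc >= env$bestCost) return()
    if (row > nr) {
      env$bestCost <- acc
      env$bestAssign <- assign
      return()
    }
    for (j in order(cost[row, ])) {
      if (usedCols[j] || !is.finite(cost[row, j])) next
      usedCols[j] <<- TRUE; assign[row] <<- j
      recurse(row + 1, acc + cost[row, j])
      usedCols[j] <<- FALSE; assign[row] <<- NA_integer_
    }
    recurse(row + 1, acc + dummyCost)
  }
  recurse(1, 0)
  env$bestAssign
}

#' Link detections across frames into tracks
#'
#' Two-pass linking: (1) frame-to-frame assignment minimising total
#' squared displacement, with links capped at \code{maxDispUm} and
#' unmatched detections starting new tracks; (2) gap closing, where track
#' ends are re-joined to later track starts across at most
#' \code{maxGapFrames} missing frames by the same cost rule (the cap
#' scales with the gap length). Closed gap frames receive linearly
#' interpolated positions and are flagged.
#'
#' Detections within a frame are processed in a canonical order, so the
#' result is invariant to their input order.
#'
#' @param detections data frame with columns \code{frame}, \code{xUm},
#'   \code{yUm}, one row per detection.
#' @param maxDispUm maximum per-frame displacement, micrometres.
#' @param maxGapFrames maximum number of missing frames to close.
#' @return data frame: \code{trackId}, \code{frame}, \code{xUm},
#'   \code{yUm}, \code{gap} (\code{TRUE} for interpolated frames).
#' @export
linkTracks <- function(detections, maxDispUm = 1.5, maxGapFrames = 2) {
  empty <- data.frame(trackId = integer(0), frame = integer(0),
                      xUm = numeric(0), yUm = numeric(0), gap = logical(0))
  if (is.null(detections) || nrow(detections) == 0) return(empty)
  det <- detections[order(detections$frame, detections$xUm,
                          detections$yUm), c("frame", "xUm", "yUm")]
  tracks <- list()

  lastRow <- function(ti) tracks[[ti]][nrow(tracks[[ti]]), ]
  for (f in sort(unique(det$frame))) {
    cur <- det[det$frame == f, , drop = FALSE]
    linkable <- which(vapply(tracks, function(tr)
      tr$frame[nrow(tr)] == f - 1, logical(1)))
    assign <- integer(0)
    if (length(linkable)) {
      cost <- matrix(Inf, length(linkable), nrow(cur))
      for (a in seq_along(linkable)) {
        e <- lastRow(linkable[a])
        dd <- (cur$xUm - e$xUm)^2 + (cur$yUm - e$yUm)^2
        cost[a, ] <- ifelse(dd <= maxDispUm^2, dd, Inf)
      }
      assign <- solveAssignment(cost, dummyCost = maxDispUm^2)
    }
    taken <- logical(nrow(cur))
    for (a in seq_along(assign)) {
      j <- assign[a]
      if (!is.na(j)) {
        ti <- linkable[a]
        tracks[[ti]] <- rbind(tracks[[ti]], data.frame(
          frame = f, xUm = cur$xUm[j], yUm = cur$yUm[j], gap = FALSE))
        taken[j] <- TRUE
      }
    }
    for (j in which(!taken))
      tracks[[length(tracks) + 1]] <- data.frame(
        frame = f, xUm = cur$xUm[j], yUm = cur$yUm[j], gap = FALSE)
  }

  # gap closing: match track ends to later track starts, iterating since
  # merges can chain across several dropouts
  if (maxGapFrames > 0 && length(tracks) > 1) {
    repeat {
      nT <- length(tracks)
      ends <- do.call(rbind, lapply(tracks, function(tr)
        tr[nrow(tr), c("frame", "xUm", "yUm")]))
      starts <- do.call(rbind, lapply(tracks, function(tr)
        tr[1, c("frame", "xUm", "yUm")]))
      cost <- matrix(Inf, nT, nT)
      for (a in seq_len(nT)) for (b in seq_len(nT)) {
        if (a == b) next
        gap <- starts$frame[b] - ends$frame[a] - 1
        if (gap < 1 || gap > maxGapFrames) next
        dd <- (starts$xUm[b] - ends$xUm[a])^2 +
          (starts$yUm[b] - ends$yUm[a])^2
        if (dd <= (maxDispUm * (gap + 1))^2) cost[a, b] <- dd
      }
      if (!any(is.finite(cost))) break
      assign <- solveAssignment(cost,
                                dummyCost = (maxDispUm *
                                             (maxGapFrames + 1))^2 + 1)
      pairs <- data.frame(a = seq_len(nT), b = assign)
      pairs <- pairs[!is.na(pairs$b), , drop = FALSE]
      if (nrow(pairs) == 0) break
      # one merge per pass: merges can chain, and the repeat loop
      # re-solves the assignment on the updated track set
      a <- pairs$a[1]; b <- pairs$b[1]
      ea <- tracks[[a]][nrow(tracks[[a]]), ]
      sb <- tracks[[b]][1, ]
      gapFrames <- (ea$frame + 1):(sb$frame - 1)
      interp <- data.frame(
        frame = gapFrames,
        xUm = ea$xUm + (sb$xUm - ea$xUm) *
          (gapFrames - ea$frame) / (sb$frame - ea$frame),
        yUm = ea$yUm + (sb$yUm - ea$yUm) *
          (gapFrames - ea$frame) / (sb$frame - ea$frame),
        gap = TRUE)
      tracks[[a]] <- rbind(tracks[[a]], interp, tracks[[b]])
      tracks <- tracks[-b]
    }
  }

  out <- do.call(rbind, lapply(seq_along(tracks), function(ti)
    cbind(trackId = ti, tracks[[ti]])))
  rownames(out) <- NULL
  out
}

#' Extract a background-corrected intensity trace along a track
#'
#' For every frame of the track, integrates the measurement channel in a
#' disc of radius \code{radiusUm} centred on the tracked centroid and
#' subtracts a local background (median of an annulus from \code{radiusUm}
#' to \code{radiusUm + 0.5} um) times the disc area. Gap frames use the
#' interpolated positions and are flagged. Frames whose disc is clipped by
#' the image border are measured on the clipped disc.
#'
#' @param track rows of one track from [linkTracks()].
#' @param frames movie array (x, y, channel, frame) with channel dimnames.
#' @param channel measurement channel name (default \code{"rootletin"},
#'   deliberately distinct from the tracking channel).
#' @param radiusUm measurement disc radius (> 0), micrometres.
#' @param pixelSizeUm pixel size, micrometres.
#' @param frameIntervalMin acquisition interval, minutes.
#' @param anaphaseFrame,bleachFrame optional event annotations.
#' @return an \linkS4class{IntensityTrace}.
#' @export
extractTrace <- function(track, frames, channel = "rootletin",
                         radiusUm = 1.0, pixelSizeUm, frameIntervalMin,
                         anaphaseFrame = NA, bleachFrame = NA) {
  if (radiusUm <= 0) stop("measurement disc radius must be > 0")
  if (nrow(track) == 0) stop("empty track")
  nx <- dim(frames)[1]; ny <- dim(frames)[2]
  rPx <- radiusUm / pixelSizeUm
  annPx <- (radiusUm + 0.5) / pixelSizeUm
  vals <- numeric(nrow(track))
  for (i in seq_len(nrow(track))) {
    cx <- track$xUm[i] / pixelSizeUm + 1
    cy <- track$yUm[i] / pixelSizeUm + 1
    x0 <- max(1L, floor(cx - annPx)); x1 <- min(nx, ceiling(cx + annPx))
    y0 <- max(1L, floor(cy - annPx)); y1 <- min(ny, ceiling(cy + annPx))
    xs <- x0:x1; ys <- y0:y1
    d2 <- outer((xs - cx)^2, (ys - cy)^2, "+")
    sub <- frames[xs, ys, channel, track$frame[i]]
    disc <- d2 <= rPx^2
    ann <- d2 > rPx^2 & d2 <= annPx^2
    bg <- if (any(ann)) stats::median(sub[ann]) else 0
    vals[i] <- sum(sub[disc]) - bg * sum(disc)
  }
  dtH <- frameIntervalMin / 60
  intensityTrace(timeH = (track$frame - 1) * dtH, intensity = vals,
                 frames = track$frame,
                 anaphaseFrame = anaphaseFrame, bleachFrame = bleachFrame,
                 gapFrames = track$frame[track$gap],
                 trackId = track$trackId[1])
}

#' Align intensity traces to anaphase and average
#'
#' Shifts every trace so that its anaphase frame defines time zero, then
#' computes the mean and SD per relative timepoint over the traces covering
#' it. The output window is trimmed to timepoints covered by at least
#' three traces (or all traces, when fewer than three are supplied).
#' Trace values are never altered; only the time axis shifts.
#'
#' @param traces list of \linkS4class{IntensityTrace}.
#' @param anaphaseFrames optional integer vector overriding the traces'
#'   own anaphase annotations. Traces without an anaphase frame are
#'   skipped with a message.
#' @return list: \code{relTimeH}, \code{mean}, \code{sd}, \code{n}, and
#'   \code{values} (trace x timepoint matrix, NA where uncovered).
#' @export
alignTraces <- function(traces, anaphaseFrames = NULL) {
  ana <- if (is.null(anaphaseFrames))
    vapply(traces, function(tr) tr@anaphaseFrame, integer(1))
  else as.integer(anaphaseFrames)
  keep <- !is.na(ana)
  if (any(!keep))
    message(sum(!keep), " trace(s) skipped: no anaphase annotation")
  traces <- traces[keep]; ana <- ana[keep]
  if (length(traces) == 0) stop("no annotated traces to align")
  dtH <- stats::median(diff(traces[[1]]@timeH))
  rel <- lapply(seq_along(traces), function(i)
    traces[[i]]@frames - ana[i])
  relRange <- range(unlist(rel))
  relPts <- relRange[1]:relRange[2]
  vals <- matrix(NA_real_, length(traces), length(relPts))
  for (i in seq_along(traces))
    vals[i, match(rel[[i]], relPts)] <- traces[[i]]@intensity
  n <- colSums(!is.na(vals))
  minN <- min(3, length(traces))
  keepPt <- n >= minN
  vals <- vals[, keepPt, drop = FALSE]
  relPts <- relPts[keepPt]
  nKept <- n[keepPt]
  sdv <- apply(vals, 2, stats::sd, na.rm = TRUE)
  sdv[nKept < 2] <- 0
  list(relTimeH = relPts * dtH,
       mean = colMeans(vals, na.rm = TRUE),
       sd = sdv, n = nKept, values = vals)
}
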