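# File formats and orchestration: multi-page TIFF stacks, CSV truth and
# result tables, JSON configuration, and the end-to-end pipeline runner.

#' Write a multi-channel stack as multi-page TIFF
#'
#' Pages are ordered channel-fastest: for a time-lapse, frame 1 channels,
#' then frame 2 channels, and so on. Pixels are stored as 16-bit unsigned
#' integers (values are rounded and clipped to [0, 65535]), the camera
#' digitisation convention the generator also uses.
#'
#' @param images 3D array (x, y, channel) or 4D array (x, y, channel,
#'   frame), channel dimnames set.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(images, path) {
  if (length(dim(images)) == 3)
    dim(images) <- c(dim(images), 1)
  pages <- list()
  for (f in seq_len(dim(images)[4]))
    for (ch in seq_len(dim(images)[3]))
      pages[[length(pages) + 1]] <-
        t(pmin(pmax(round(images[, , ch, f]), 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read a multi-channel stack from multi-page TIFF
#'
#' Inverse of [writeStack()]: pages are grouped channel-fastest into
#' frames. The page count must be divisible by the number of channels.
#'
#' @param path TIFF file.
#' @param channels channel names in page order within a frame.
#' @return 3D array (x, y, channel) for a single frame, otherwise a 4D
#'   array (x, y, channel, frame); integer-valued intensities.
#' @export
readStack <- function(path, channels = c("dna", "centriole", "pcm",
                                         "rootletin")) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  nC <- length(channels)
  if (length(pages) %% nC != 0)
    stop(sprintf("page count (%d) is not divisible by channel count (%d)",
                 length(pages), nC))
  nF <- length(pages) %/% nC
  nx <- ncol(pages[[1]]); ny <- nrow(pages[[1]])
  out <- array(0, dim = c(nx, ny, nC, nF),
               dimnames = list(NULL, NULL, channels, NULL))
  k <- 1
  for (f in seq_len(nF)) for (ch in seq_len(nC)) {
    out[, , ch, f] <- t(pages[[k]])
    k <- k + 1
  }
  if (nF == 1) out <- out[, , , 1, drop = TRUE]
  out
}

configAsList <- function(config) {
  out <- lapply(methods::slotNames(class(config)), function(s)
    methods::slot(config, s))
  names(out) <- methods::slotNames(class(config))
  out
}

#' Write a simulated scene to disk
#'
#' Writes \code{images.tif} (pages in channel order dna, centriole, pcm,
#' rootletin), the truth tables \code{cells.csv}, \code{centrioles.csv}
#' and \code{roots.csv}, and the resolved configuration as
#' \code{config.json}.
#'
#' @param scene a \linkS4class{Scene}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeScene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeStack(scene@images, file.path(dir, "images.tif"))
  tr <- scene@truth
  utils::write.csv(tr$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(tr$centrioles, file.path(dir, "centrioles.csv"),
                   row.names = FALSE)
  utils::write.csv(tr$roots, file.path(dir, "roots.csv"),
                   row.names = FALSE)
  cfg <- c(configAsList(scene@config), list(seed = scene@seed))
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write a simulated time-lapse to disk
#'
#' Writes \code{movie.tif} (pages channel-fastest: pcm, rootletin per
#' frame), the noiseless truth trace and state sequence as
#' \code{trace.csv}, event annotations as \code{events.csv}, and the
#' configuration as \code{config.json}.
#'
#' @param timelapse a \linkS4class{Timelapse}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeTimelapse <- function(timelapse, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeStack(timelapse@frames, file.path(dir, "movie.tif"))
  utils::write.csv(timelapse@truth$trace, file.path(dir, "trace.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(
    anaphaseFrame = timelapse@truth$anaphaseFrame,
    bleachFrame = timelapse@truth$bleachFrame),
    file.path(dir, "events.csv"), row.names = FALSE)
  cfg <- c(configAsList(timelapse@config), list(seed = timelapse@seed))
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run the census pipeline on one field
#'
#' The full fixed-field analysis: nucleus segmentation from the DNA
#' channel, cytoplasm assignment by seeded watershed, mitotic exclusion,
#' PCM focus detection, root segmentation by propagation from the PCM
#' foci, and the per-cell cohesion census.
#'
#' @param images 3D array (x, y, channel) with dna/centriole/pcm/rootletin
#'   channel dimnames.
#' @param pixelSizeUm pixel size, micrometres.
#' @param thresholdUm split-distance threshold.
#' @param declumpPcm declump PCM foci (default \code{FALSE}: cohered
#'   centrosomes group into one focus, the census convention).
#' @param withRoots also segment roots and classify linkage.
#' @param minNucleusAreaPx minimum nucleus area.
#' @return list: \code{census} (per-cell records with mitotic exclusions
#'   applied), \code{foci}, \code{roots} (a \linkS4class{RootSet} or
#'   \code{NULL}), \code{nuclei}, \code{cells}, \code{mitotic}.
#' @export
censusField <- function(images, pixelSizeUm, thresholdUm = 1.5,
                        declumpPcm = FALSE, withRoots = TRUE,
                        minNucleusAreaPx = 500) {
  nuclei <- segmentNuclei(images[, , "dna"], pixelSizeUm,
                          minAreaPx = minNucleusAreaPx)
  cells <- assignCytoplasm(nuclei)
  mit <- excludeMitotic(images[, , "dna"], nuclei)
  foci <- detectFoci(images[, , "pcm"], cells, declump = declumpPcm,
                     channelName = "pcm")
  roots <- NULL
  if (withRoots && nrow(foci) > 0)
    roots <- segmentRoots(images[, , "rootletin"], foci, pixelSizeUm)
  census <- cohesionCensus(foci, cellIds = seq_len(nObjects(nuclei)),
                           rootSet = roots, thresholdUm = thresholdUm)
  mitCells <- mit$cell[mit$mitotic]
  hit <- census$cell %in% mitCells
  census$excluded[hit] <- TRUE
  census$reason[hit] <- "mitotic"
  list(census = census, foci = foci, roots = roots, nuclei = nuclei,
       cells = cells, mitotic = mit)
}

#' Track a movie and extract the centrosomal intensity trace
#'
#' Detects PCM foci per frame, links them into tracks, keeps the longest
#' track and extracts the background-corrected rootletin trace along it.
#'
#' @param timelapse a \linkS4class{Timelapse} (or a 4D movie array with
#'   pcm/rootletin channel dimnames, in which case annotations must be
#'   passed explicitly).
#' @param maxDispUm,maxGapFrames tracking parameters.
#' @param radiusUm measurement disc radius.
#' @param anaphaseFrame,bleachFrame event annotations; default to the
#'   time-lapse truth.
#' @return an \linkS4class{IntensityTrace}.
#' @export
analyzeMovie <- function(timelapse, maxDispUm = 1.5, maxGapFrames = 2,
                         radiusUm = 1.0, anaphaseFrame = NULL,
                         bleachFrame = NULL) {
  if (is(timelapse, "Timelapse")) {
    frames <- timelapse@frames
    ps <- timelapse@config@pixelSizeUm
    dtMin <- timelapse@config@frameIntervalMin
    if (is.null(anaphaseFrame)) anaphaseFrame <- timelapse@truth$anaphaseFrame
    if (is.null(bleachFrame)) bleachFrame <- timelapse@truth$bleachFrame
  } else {
    stop("analyzeMovie expects a Timelapse object")
  }
  nF <- dim(frames)[4]
  det <- do.call(rbind, lapply(seq_len(nF), function(f) {
    d <- detectFoci(frames[, , "pcm", f], pixelSizeUm = ps,
                    declump = FALSE, channelName = "pcm")
    if (nrow(d) == 0) return(NULL)
    data.frame(frame = f, xUm = d$xUm, yUm = d$yUm)
  }))
  tracks <- linkTracks(det, maxDispUm, maxGapFrames)
  if (nrow(tracks) == 0) stop("no centrosome detections in movie")
  lens <- table(tracks$trackId)
  main <- tracks[tracks$trackId == as.integer(names(which.max(lens))), ]
  extractTrace(main, frames, "rootletin", radiusUm, ps, dtMin,
               anaphaseFrame = anaphaseFrame, bleachFrame = bleachFrame)
}

#' Compare split prevalence between two census runs
#'
#' Builds the 2x2 split/cohered table from two per-cell census tables
#' (non-excluded cells only), runs the exact test of
#' [compareSplitFractions()] and optionally writes the counts, odds ratio
#' and p-value as JSON.
#'
#' @param censusA,censusB per-cell census data frames (from
#'   [censusField()] or a \code{cohesion_summary.csv}).
#' @param labels condition names used in the output.
#' @param out optional path for \code{condition_comparison.json}.
#' @return list: per-condition counts, \code{oddsRatio}, \code{p}.
#' @export
compareConditions <- function(censusA, censusB,
                              labels = c("A", "B"), out = NULL) {
  okA <- !censusA$excluded; okB <- !censusB$excluded
  res <- compareSplitFractions(sum(censusA$splitFlag[okA]), sum(okA),
                               sum(censusB$splitFlag[okB]), sum(okB))
  summary <- list(
    conditions = list(
      list(label = labels[1], split = sum(censusA$splitFlag[okA]),
           total = sum(okA)),
      list(label = labels[2], split = sum(censusB$splitFlag[okB]),
           total = sum(okB))),
    oddsRatio = res$oddsRatio, p = res$p)
  if (!is.null(out))
    jsonlite::write_json(summary, out, auto_unbox = TRUE, digits = NA)
  summary
}

readRunConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$mode) ||
      !cfg$mode %in% c("census", "timelapse", "frap"))
    stop("config must set mode to census, timelapse or frap")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg
}

pipelineLog <- function(outDir, mode, seed, cfg) {
  hash <- fnv1a(jsonlite::toJSON(cfg, auto_unbox = TRUE))
  writeLines(c(
    sprintf("rootcohesion %s",
            as.character(utils::packageVersion("rootcohesion"))),
    sprintf("mode: %s", mode),
    sprintf("seed: %d", as.integer(seed)),
    sprintf("parameter hash: %s", hash)),
    file.path(outDir, "run.log"))
}

#' Run the pipeline end to end
#'
#' Orchestrates a whole run from a configuration list (or JSON path):
#' \code{census} mode simulates (or reads) fixed fields and writes the
#' segmentation and cohesion tables; \code{timelapse} mode simulates
#' movies, tracks them, aligns traces to anaphase and fits assembly and
#' release-onset kinetics; \code{frap} mode fits the recovery model per
#' movie. Every output is a CSV or JSON file under \code{outDir}, plus a
#' \code{run.log} recording version, seed and a parameter hash. The same
#' configuration and seed give byte-identical outputs.
#'
#' @param config list or path to a JSON file. Fields: \code{mode}
#'   (\code{census}/\code{timelapse}/\code{frap}), \code{seed},
#'   \code{simulate} (\code{fixture} name, optional \code{overrides},
#'   \code{n_fields} or \code{n_movies}), optional \code{input} (census
#'   only: \code{images} TIFF paths, \code{pixel_size_um}), and optional
#'   \code{params} (\code{threshold_um}, \code{bin_width_um},
#'   \code{max_disp_um}, \code{max_gap_frames}, \code{radius_um}).
#' @param outDir output directory.
#' @return invisibly, a list of the main computed results.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- readRunConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  mode <- config$mode
  seed <- as.integer(if (is.null(config$seed)) 1L else config$seed)
  params <- config$params
  p <- function(name, default)
    if (is.null(params[[name]])) default else params[[name]]
  result <- switch(
    mode,
    census = {
      thresholdUm <- p("threshold_um", 1.5)
      fields <- list()
      if (!is.null(config$input)) {
        ps <- config$input$pixel_size_um
        for (f in config$input$images)
          fields[[length(fields) + 1]] <-
            list(images = readStack(f), pixelSizeUm = ps)
      } else {
        sim <- config$simulate
        nFields <- if (is.null(sim$n_fields)) 1L else as.integer(sim$n_fields)
        overrides <- if (is.null(sim$overrides)) list() else sim$overrides
        cfg <- do.call(fixtureConfig, c(list(sim$fixture), overrides))
        for (f in seq_len(nFields)) {
          sc <- simulateField(cfg, seed = seed + f - 1L)
          fields[[f]] <- list(images = sc@images,
                              pixelSizeUm = cfg@pixelSizeUm)
        }
      }
      allCensus <- NULL; allFoci <- NULL
      for (f in seq_along(fields)) {
        res <- censusField(fields[[f]]$images, fields[[f]]$pixelSizeUm,
                           thresholdUm = thresholdUm)
        res$census$field <- f
        res$foci$field <- f
        allCensus <- rbind(allCensus, res$census)
        allFoci <- rbind(allFoci, res$foci)
      }
      utils::write.csv(allCensus, file.path(outDir, "cohesion_summary.csv"),
                       row.names = FALSE)
      utils::write.csv(allFoci, file.path(outDir, "foci.csv"),
                       row.names = FALSE)
      ok <- !allCensus$excluded
      curve <- linkageVsDistance(allCensus$distanceUm[ok],
                                 allCensus$linked[ok],
                                 binWidthUm = p("bin_width_um", 0.25))
      utils::write.csv(curve, file.path(outDir, "linkage_curve.csv"),
                       row.names = FALSE)
      list(census = allCensus,
           percentSplit = 100 * mean(allCensus$splitFlag[ok]),
           linkageCurve = curve)
    },
    timelapse = {
      sim <- config$simulate
      nMovies <- if (is.null(sim$n_movies)) 1L else as.integer(sim$n_movies)
      overrides <- if (is.null(sim$overrides)) list() else sim$overrides
      cfg <- do.call(fixtureConfig, c(list(sim$fixture), overrides))
      traces <- list(); anaFrames <- integer(0)
      for (m in seq_len(nMovies)) {
        tl <- simulateTimelapse(cfg, seed = seed + m - 1L)
        traces[[m]] <- analyzeMovie(tl, p("max_disp_um", 1.5),
                                    p("max_gap_frames", 2),
                                    p("radius_um", 1.0))
        anaFrames[m] <- tl@truth$anaphaseFrame
      }
      aligned <- alignTraces(traces, anaFrames)
      utils::write.csv(data.frame(relTimeH = aligned$relTimeH,
                                  mean = aligned$mean, sd = aligned$sd,
                                  n = aligned$n),
                       file.path(outDir, "aligned_trace.csv"),
                       row.names = FALSE)
      post <- aligned$relTimeH >= 0
      fit <- estimateAssembly(aligned$relTimeH[post], aligned$mean[post])
      pre <- aligned$relTimeH <= 0
      onset <- estimateReleaseOnset(aligned$relTimeH[pre],
                                    aligned$mean[pre])
      jsonlite::write_json(
        list(amplitude = fit@amplitude, tauH = fit@tauH, t90H = fit@t90H,
             releaseOnsetH = onset$onsetH),
        file.path(outDir, "assembly_fit.json"), auto_unbox = TRUE,
        digits = NA)
      list(aligned = aligned, assembly = fit, onset = onset)
    },
    frap = {
      sim <- config$simulate
      nMovies <- if (is.null(sim$n_movies)) 1L else as.integer(sim$n_movies)
      overrides <- if (is.null(sim$overrides)) list() else sim$overrides
      cfg <- do.call(fixtureConfig, c(list(sim$fixture), overrides))
      rows <- NULL; fits <- list()
      for (m in seq_len(nMovies)) {
        tl <- simulateTimelapse(cfg, seed = seed + m - 1L)
        tr <- analyzeMovie(tl, p("max_disp_um", 1.5),
                           p("max_gap_frames", 2), p("radius_um", 1.0))
        fit <- fitRecovery(normalizeFrap(tr))
        fits[[m]] <- fit
        rows <- rbind(rows, data.frame(
          movie = m, mobileFraction = fit@mobileFraction,
          tauH = fit@tauH,
          plateauRecoveryPct = fit@plateauRecoveryPct))
      }
      utils::write.csv(rows, file.path(outDir, "frap_fits.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(meanPlateauRecoveryPct = mean(rows$plateauRecoveryPct)),
        file.path(outDir, "frap_summary.json"), auto_unbox = TRUE,
        digits = NA)
      list(fits = fits, meanPlateauRecoveryPct =
             mean(rows$plateauRecoveryPct))
    })
  pipelineLog(outDir, mode, seed, config)
  invisible(result)
}
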