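# Cohesion statistics: split classification, root linkage, the empirical
# split-distance threshold, four-centriole configurations and condition
# comparisons.

#' Pairwise 2D Euclidean distances between focus centroids
#'
#' @param xUm,yUm centroid coordinates in micrometres.
#' @return data frame \code{i}, \code{j}, \code{distanceUm} for every
#'   unordered pair; zero rows (with a \code{reason} attribute) when fewer
#'   than two foci are supplied.
#' @examples
#' pairwiseDistances(c(0, 3), c(0, 4))  # 5 um
#' @export
pairwiseDistances <- function(xUm, yUm) {
  n <- length(xUm)
  if (n < 2) {
    out <- data.frame(i = integer(0), j = integer(0),
                      distanceUm = numeric(0))
    attr(out, "reason") <- "fewer than 2 foci"
    return(out)
  }
  idx <- utils::combn(n, 2)
  data.frame(i = idx[1, ], j = idx[2, ],
             distanceUm = sqrt((xUm[idx[1, ]] - xUm[idx[2, ]])^2 +
                               (yUm[idx[1, ]] - yUm[idx[2, ]])^2))
}

#' Classify a centriole pair as split or cohered
#'
#' A pair is split when its inter-centroid distance strictly exceeds the
#' threshold (default 1.5 um); a pair at exactly the threshold is cohered.
#'
#' @param distanceUm non-negative distance(s) in micrometres.
#' @param thresholdUm split threshold, micrometres.
#' @return logical vector, \code{TRUE} = split.
#' @export
classifySplit <- function(distanceUm, thresholdUm = 1.5) {
  if (any(distanceUm < 0, na.rm = TRUE))
    stop("distances must be non-negative")
  distanceUm > thresholdUm
}

#' Classify two roots as linked or unlinked
#'
#' Linked means the one-pixel dilation of one root's mask intersects the
#' other's mask: this captures both genuinely shared pixels and the
#' 8-adjacency that seeded propagation produces when it partitions a joint
#' mask between two seeds.
#'
#' @param rootSet a \linkS4class{RootSet}.
#' @param rootA,rootB root ids of roots from distinct PCM seeds.
#' @return \code{TRUE} if linked.
#' @export
classifyLinkage <- function(rootSet, rootA, rootB) {
  info <- rootInfo(rootSet)
  sa <- info$seedFocusId[info$rootId == rootA]
  sb <- info$seedFocusId[info$rootId == rootB]
  if (length(sa) == 0 || length(sb) == 0)
    stop("unknown root id")
  if (!is.na(sa) && !is.na(sb) && sa == sb)
    stop("roots share the same PCM seed")
  lab <- labelData(rootLabels(rootSet))
  maskA <- lab == rootA
  maskB <- lab == rootB
  any(dilate1px(maskA) & maskB)
}

#' Per-cell cohesion census from detected PCM foci
#'
#' Applies the census rules: cells with 0 detected PCM foci or more than
#' \code{maxFoci} are excluded (and counted); a single focus is a cohered
#' (grouped) pair; with two or more foci the two brightest are paired and
#' classified by [classifySplit()]. When a \linkS4class{RootSet} is given,
#' the pair's root linkage is classified via [classifyLinkage()].
#'
#' @param foci focus records from [detectFoci()] (PCM channel).
#' @param cellIds cell ids to report (e.g. non-mitotic cells); defaults to
#'   the cells present in \code{foci}.
#' @param rootSet optional \linkS4class{RootSet} segmented from the same
#'   field with these foci as seeds.
#' @param thresholdUm split threshold, micrometres.
#' @param maxFoci cells with more foci than this are excluded.
#' @return data frame of per-cell records: \code{cell}, \code{nFoci},
#'   \code{distanceUm}, \code{splitFlag}, \code{linked}, \code{excluded},
#'   \code{reason}.
#' @export
cohesionCensus <- function(foci, cellIds = NULL, rootSet = NULL,
                           thresholdUm = 1.5, maxFoci = 4) {
  if (is.null(cellIds))
    cellIds <- sort(unique(foci$cell[!is.na(foci$cell)]))
  rows <- lapply(cellIds, function(cc) {
    f <- foci[!is.na(foci$cell) & foci$cell == cc, , drop = FALSE]
    nF <- nrow(f)
    rec <- data.frame(cell = cc, nFoci = nF, distanceUm = NA_real_,
                      splitFlag = NA, linked = NA, excluded = FALSE,
                      reason = "", stringsAsFactors = FALSE)
    if (nF == 0) {
      rec$excluded <- TRUE; rec$reason <- "no PCM foci"
      return(rec)
    }
    if (nF > maxFoci) {
      rec$excluded <- TRUE
      rec$reason <- sprintf("more than %d PCM foci", maxFoci)
      return(rec)
    }
    if (nF == 1) {
      rec$splitFlag <- FALSE  # grouped pair detected as one focus
      rec$distanceUm <- 0
      return(rec)
    }
    f <- f[order(-f$integrated), , drop = FALSE][1:2, ]
    rec$distanceUm <- sqrt((f$xUm[1] - f$xUm[2])^2 +
                           (f$yUm[1] - f$yUm[2])^2)
    rec$splitFlag <- classifySplit(rec$distanceUm, thresholdUm)
    if (!is.null(rootSet)) {
      info <- rootInfo(rootSet)
      ra <- info$rootId[match(f$focusId[1], info$seedFocusId)]
      rb <- info$rootId[match(f$focusId[2], info$seedFocusId)]
      if (!is.na(ra) && !is.na(rb))
        rec$linked <- classifyLinkage(rootSet, ra, rb)
    }
    rec
  })
  do.call(rbind, rows)
}

#' Linked fraction as a function of centriole spacing
#'
#' Bins per-cell records by pair distance and reports the linked fraction
#' per bin. Empty bins are reported with \code{n = 0} and an undefined
#' (\code{NA}) fraction.
#'
#' @param distanceUm pair distances, micrometres.
#' @param linked logical linkage classifications, same length.
#' @param binWidthUm bin width (default 0.25 um).
#' @param maxUm upper edge of the last bin; defaults to cover the data.
#' @return data frame: \code{binStart}, \code{binEnd}, \code{n},
#'   \code{fractionLinked}.
#' @export
linkageVsDistance <- function(distanceUm, linked, binWidthUm = 0.25,
                              maxUm = NULL) {
  keep <- !is.na(distanceUm) & !is.na(linked)
  distanceUm <- distanceUm[keep]; linked <- linked[keep]
  if (is.null(maxUm))
    maxUm <- if (length(distanceUm)) max(distanceUm) else binWidthUm
  edges <- seq(0, ceiling(maxUm / binWidthUm) * binWidthUm, binWidthUm)
  if (length(edges) < 2) edges <- c(0, binWidthUm)
  bin <- findInterval(distanceUm, edges, rightmost.closed = TRUE,
                      left.open = TRUE)
  bin[distanceUm == 0] <- 1L
  nb <- length(edges) - 1
  n <- tabulate(bin, nbins = nb)
  linkedN <- vapply(seq_len(nb), function(b) sum(linked[bin == b]),
                    numeric(1))
  data.frame(binStart = edges[-length(edges)], binEnd = edges[-1], n = n,
             fractionLinked = ifelse(n > 0, linkedN / n, NA_real_))
}

#' Derive the empirical split-distance threshold from a linkage curve
#'
#' Applies isotonic (non-increasing) smoothing to the per-bin linked
#' fractions and returns the lower edge of the first bin whose smoothed
#' fraction falls below \code{rareFraction}: the distance above which
#' roots rarely link centrioles.
#'
#' @param curve a linkage curve from [linkageVsDistance()].
#' @param rareFraction operational definition of "rarely" (default 0.1).
#' @return distance in micrometres.
#' @export
deriveSplitThreshold <- function(curve, rareFraction = 0.1) {
  occ <- curve[curve$n > 0, , drop = FALSE]
  if (nrow(occ) < 2)
    stop("need occupied bins on both sides of the linkage transition")
  iso <- stats::isoreg(seq_len(nrow(occ)), -occ$fractionLinked)
  smoothed <- -iso$yf
  below <- which(smoothed < rareFraction)
  if (length(below) == 0)
    stop("no transition: all bins above the rare fraction (all linked)")
  if (length(below) == nrow(occ))
    stop("no transition: all bins below the rare fraction (all unlinked)")
  occ$binStart[below[1]]
}

#' Classify the configuration of a four-centriole cell
#'
#' Single-linkage clustering of the four positions with linking distance
#' equal to the split threshold; the multiset of cluster sizes maps to the
#' configuration class: \code{\{4\}} grouped, \code{\{2,2\}} two_pairs,
#' \code{\{3,1\}} three_plus_one, \code{\{2,1,1\}} two_plus_one_plus_one,
#' \code{\{1,1,1,1\}} all_split.
#'
#' @param xUm,yUm coordinates of exactly four centrioles, micrometres.
#' @param thresholdUm linking distance (default 1.5 um); positions at or
#'   below this distance cluster together.
#' @return one of \code{"grouped"}, \code{"two_pairs"},
#'   \code{"three_plus_one"}, \code{"two_plus_one_plus_one"},
#'   \code{"all_split"}.
#' @export
classifyConfiguration <- function(xUm, yUm, thresholdUm = 1.5) {
  if (length(xUm) != 4 || length(yUm) != 4)
    stop("exactly 4 centriole positions required")
  d <- stats::dist(cbind(xUm, yUm))
  cl <- stats::cutree(stats::hclust(d, method = "single"),
                      h = thresholdUm)
  sizes <- sort(tabulate(cl), decreasing = TRUE)
  key <- paste(sizes[sizes > 0], collapse = "+")
  switch(key,
         "4" = "grouped",
         "2+2" = "two_pairs",
         "3+1" = "three_plus_one",
         "2+1+1" = "two_plus_one_plus_one",
         "1+1+1+1" = "all_split")
}

#' Compare split fractions between two conditions (exact test)
#'
#' Two-sided exact test on the 2x2 table of split/cohered counts, computed
#' by hypergeometric enumeration over all tables with the observed margins:
#' the p-value sums the probabilities of every table whose probability does
#' not exceed the observed table's (probability-mass ordering, the
#' convention of common statistical software). The odds ratio uses the
#' Haldane correction (+0.5 to every cell) when any cell is zero.
#'
#' @param splitA,totalA split count and total in condition A.
#' @param splitB,totalB split count and total in condition B.
#' @return list: \code{oddsRatio}, \code{p}, \code{table}.
#' @export
compareSplitFractions <- function(splitA, totalA, splitB, totalB) {
  counts <- c(splitA, totalA - splitA, splitB, totalB - splitB)
  if (any(counts < 0)) stop("negative counts")
  if (totalA <= 0 || totalB <= 0) stop("totals must be positive")
  m <- splitA + splitB            # first-row margin (split)
  n <- (totalA - splitA) + (totalB - splitB)
  kk <- totalA                    # first-column margin (condition A)
  lo <- max(0, kk - n); hi <- min(kk, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n, kk)
  pObs <- stats::dhyper(splitA, m, n, kk)
  p <- min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
  tab <- matrix(counts, 2, 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("split", "cohered")))
  orTab <- if (any(tab == 0)) tab + 0.5 else tab
  or <- (orTab[1, 1] * orTab[2, 2]) / (orTab[1, 2] * orTab[2, 1])
  list(oddsRatio = or, p = p, table = tab)
}

#' Welch two-sample t test for measurement symmetry
#'
#' Unequal-variance (Welch) t test with Welch--Satterthwaite degrees of
#' freedom, e.g. for comparing root areas at mother versus daughter
#' centrioles.
#'
#' @param groupA,groupB numeric vectors, each of length >= 2.
#' @return list: \code{t}, \code{df}, \code{p}, \code{meanA}, \code{meanB}.
#' @export
symmetryTest <- function(groupA, groupB) {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("each group needs at least 2 values")
  if (stats::sd(groupA) == 0 && stats::sd(groupB) == 0 &&
      mean(groupA) == mean(groupB))
    return(list(t = 0, df = length(groupA) + length(groupB) - 2, p = 1,
                meanA = mean(groupA), meanB = mean(groupB)))
  ht <- stats::t.test(groupA, groupB, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, meanA = mean(groupA), meanB = mean(groupB))
}
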