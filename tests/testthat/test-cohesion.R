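# Cohesion statistics: distances, split/linkage classification, threshold
# derivation, configuration classes and the two condition tests, each
# checked against an independent oracle.

test_that("pairwise distances match hand and brute-force values", {
  expect_equal(pairwiseDistances(c(0, 3), c(0, 4))$distanceUm, 5)
  expect_equal(pairwiseDistances(c(2, 2), c(7, 7))$distanceUm, 0)
  one <- pairwiseDistances(1, 1)
  expect_equal(nrow(one), 0)
  expect_match(attr(one, "reason"), "fewer")

  xy <- rootcohesion:::withSeed(4, matrix(runif(8, 0, 10), 4, 2))
  got <- pairwiseDistances(xy[, 1], xy[, 2])
  expect_equal(nrow(got), 6)
  for (r in seq_len(6)) {               # exhaustive double-loop oracle
    i <- got$i[r]; j <- got$j[r]
    expect_equal(got$distanceUm[r],
                 sqrt(sum((xy[i, ] - xy[j, ])^2)))
  }
})

test_that("split classification is strict at the threshold and monotone", {
  expect_false(classifySplit(1.0))
  expect_false(classifySplit(1.5))      # exactly at threshold: cohered
  expect_true(classifySplit(1.6))
  expect_error(classifySplit(-0.1), "non-negative")

  d <- rootcohesion:::withSeed(2, runif(500, 0, 4))
  counts <- vapply(seq(0.5, 3, 0.25),
                   function(th) sum(classifySplit(d, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))   # raising threshold never adds splits
})

makeRootSet <- function(lab, seeds = seq_len(max(lab))) {
  st <- rootcohesion:::labelStats(lab, pixelSizeUm = 0.1)
  new("RootSet", labels = labelMap(lab, 0.1, "rootletin"),
      info = data.frame(rootId = st$label, seedFocusId = seeds[st$label],
                        cell = 1L, areaPx = st$areaPx,
                        areaUm2 = st$areaUm2))
}

test_that("linkage needs one-pixel contact between roots of distinct seeds", {
  lab <- matrix(0L, 40, 40)
  lab[5:10, 5] <- 1L; lab[25:30, 5] <- 2L       # 15 px apart
  expect_false(classifyLinkage(makeRootSet(lab), 1, 2))

  lab2 <- matrix(0L, 40, 40)
  lab2[5:10, 5] <- 1L; lab2[11:16, 5] <- 2L     # touching end to end
  expect_true(classifyLinkage(makeRootSet(lab2), 1, 2))

  expect_error(classifyLinkage(makeRootSet(lab, seeds = c(3L, 3L)), 1, 2),
               "same PCM seed")
})

test_that("linkage curve bins match a hand count", {
  allL <- linkageVsDistance(c(0.5, 1.1, 2.3), rep(TRUE, 3), 1)
  expect_true(all(allL$fractionLinked[allL$n > 0] == 1))
  allU <- linkageVsDistance(c(0.5, 1.1, 2.3), rep(FALSE, 3), 1)
  expect_true(all(allU$fractionLinked[allU$n > 0] == 0))

  cv <- linkageVsDistance(c(0.2, 0.5, 0.9, 2.1, 2.5, 2.9),
                          c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), 1)
  expect_equal(cv$fractionLinked[1], 1)   # (0,1]
  expect_equal(cv$n[2], 0)                # (1,2] empty
  expect_true(is.na(cv$fractionLinked[2]))
  expect_equal(cv$fractionLinked[3], 0)   # (2,3]
})

test_that("split threshold is the first bin below the rare fraction", {
  step <- data.frame(binStart = seq(0, 2.75, 0.25),
                     binEnd = seq(0.25, 3, 0.25))
  step$n <- 20
  step$fractionLinked <- ifelse(step$binStart < 1.5, 1, 0)
  expect_equal(deriveSplitThreshold(step), 1.5)

  mono <- data.frame(binStart = seq(1.0, 1.9, 0.1),
                     binEnd = seq(1.1, 2.0, 0.1), n = 50)
  mono$fractionLinked <- c(.9, .7, .5, .3, .15, .08, .05, .03, .01, 0)
  expect_equal(deriveSplitThreshold(mono), 1.5)  # crosses 0.1 at bin [1.5,1.6)

  allLinked <- data.frame(binStart = 0:3, binEnd = 1:4, n = 5,
                          fractionLinked = 1)
  expect_error(deriveSplitThreshold(allLinked), "all bins above")
  allUn <- data.frame(binStart = 0:3, binEnd = 1:4, n = 5,
                      fractionLinked = 0)
  expect_error(deriveSplitThreshold(allUn), "below")
})

test_that("non-monotone curves are isotonically smoothed before scanning", {
  bumpy <- data.frame(binStart = seq(0, 2.75, 0.25),
                      binEnd = seq(0.25, 3, 0.25), n = 30)
  bumpy$fractionLinked <- c(1, .95, .9, .6, .8, .4, .05, .12, 0, 0, 0, 0)
  # isotonic fit pools the 0.05/0.12 violation to ~0.085 < 0.1, so the
  # transition is at the [1.5, 1.75) bin despite the bump
  expect_equal(deriveSplitThreshold(bumpy), 1.5)
})

test_that("configuration classes match the brute-force single-linkage oracle", {
  expect_equal(classifyConfiguration(c(0, .5, 0, .5), c(0, 0, .5, .5)),
               "grouped")
  expect_equal(classifyConfiguration(c(0, .5, 5, 5.5), c(0, 0, 0, 0)),
               "two_pairs")
  for (i in 1:100) {
    xy <- rootcohesion:::withSeed(1000 + i, matrix(runif(8, 0, 5), 4, 2))
    want <- configKeyFromSizes(
      bruteForceClusterSizes(xy[, 1], xy[, 2], 1.5))
    expect_equal(classifyConfiguration(xy[, 1], xy[, 2]), want)
  }
  expect_error(classifyConfiguration(1:3, 1:3), "4")
})

test_that("exact split-fraction test agrees with full enumeration", {
  expect_equal(compareSplitFractions(10, 100, 10, 100)$p, 1)
  # frozen oracle value, confirmed by hypergeometric enumeration
  expect_equal(compareSplitFractions(1, 10, 11, 14)$p, 0.002759,
               tolerance = 1e-3)

  for (tA in c(3, 7, 12)) for (tB in c(4, 9, 12)) {
    for (sA in 0:tA) for (sB in 0:tB) {
      got <- compareSplitFractions(sA, tA, sB, tB)
      ref <- stats::fisher.test(matrix(c(sA, tA - sA, sB, tB - sB), 2,
                                       byrow = TRUE))
      expect_equal(got$p, ref$p.value, tolerance = 1e-9)
      expect_true(got$p > 0 && got$p <= 1)
      swapped <- compareSplitFractions(sB, tB, sA, tA)
      expect_equal(got$p, swapped$p, tolerance = 1e-12)
    }
  }
  expect_error(compareSplitFractions(-1, 5, 2, 5), "negative")
})

test_that("Welch test matches the direct formula", {
  same <- symmetryTest(c(4, 5, 6), c(4, 5, 6))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  got <- symmetryTest(c(1, 2, 3), c(4, 5, 6))
  oracle <- welchOracle(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$t, -3.674, tolerance = 1e-3)
  expect_equal(got$t, oracle$t, tolerance = 1e-10)
  expect_equal(got$df, oracle$df, tolerance = 1e-10)
  expect_equal(got$p, oracle$p, tolerance = 1e-10)
  expect_error(symmetryTest(1, c(2, 3)), "at least 2")
})

test_that("mother/daughter root areas test as symmetric under the null", {
  sc <- stdScene()
  roots <- sceneTruth(sc)$roots
  pairs <- split(roots$areaPx, roots$pairId)
  pairs <- pairs[vapply(pairs, length, integer(1)) == 2]
  rejections <- rootcohesion:::withSeed(99, vapply(1:100, function(i) {
    pick <- vapply(pairs, function(pr) sample(pr, 1), numeric(1))
    other <- mapply(function(pr, pk) setdiff(pr, pk)[1], pairs, pick)
    other[is.na(other)] <- pick[is.na(other)]  # equal-area pairs
    symmetryTest(pick, other)$p <= 0.05
  }, logical(1)))
  expect_gte(mean(!rejections), 0.9)
})

test_that("census rules: grouping, pairing the brightest, and exclusions", {
  foci <- data.frame(
    focusId = 1:7,
    cell = c(1, 2, 2, 3, 3, 3, NA),
    xUm = c(5, 10, 12, 20, 21, 23, 0),
    yUm = c(5, 10, 10, 20, 20, 20, 0),
    areaPx = 10, areaUm2 = 0.1,
    integrated = c(100, 90, 80, 100, 95, 20, 50),
    mean = 10, channel = "pcm")
  cen <- cohesionCensus(foci, cellIds = 1:4)
  expect_equal(cen$splitFlag[cen$cell == 1], FALSE)   # single focus
  expect_equal(cen$distanceUm[cen$cell == 2], 2)
  expect_true(cen$splitFlag[cen$cell == 2])
  # cell 3: two brightest foci are at x = 20 and 21 -> 1 um, cohered
  expect_equal(cen$distanceUm[cen$cell == 3], 1)
  expect_false(cen$splitFlag[cen$cell == 3])
  expect_true(cen$excluded[cen$cell == 4])            # no foci
  expect_match(cen$reason[cen$cell == 4], "no PCM")
})
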