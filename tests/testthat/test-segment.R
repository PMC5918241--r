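# Segmentation stages: nuclei, cytoplasm, foci, roots, measurements and
# mitotic exclusion, validated against ground truth and small geometric
# constructions.

test_that("blank images yield empty label maps, not errors", {
  blank <- matrix(0, 64, 64)
  expect_equal(nObjects(segmentNuclei(blank, 0.1)), 0)
  expect_equal(nrow(detectFoci(blank, pixelSizeUm = 0.1)), 0)
  rs <- segmentRoots(blank, pixelSizeUm = 0.1, method = "direct")
  expect_equal(nrow(rootInfo(rs)), 0)
})

test_that("a single noiseless disc is recovered with its area", {
  img <- discImage(100, 100, cbind(50, 50), 20, value = 300)
  nuc <- segmentNuclei(img, 0.1, minAreaPx = 50)
  expect_equal(nObjects(nuc), 1)
  trueArea <- sum(img > 0)
  segArea <- sum(labelData(nuc) == 1)
  expect_lt(abs(segArea - trueArea) / trueArea, 0.05)
})

test_that("all nuclei of a noisy 50-cell field are found", {
  sc <- stdScene()
  nuc <- segmentNuclei(sceneImages(sc)[, , "dna"], 0.1)
  expect_equal(nObjects(nuc), 50)
})

test_that("flat-field watershed splits two nuclei along the bisector", {
  seeds <- discImage(120, 80, rbind(c(30, 40)), 10, value = 1) +
    2 * discImage(120, 80, rbind(c(90, 40)), 10, value = 1)
  nuc <- labelMap(seeds, 0.1, "dna")
  cyt <- assignCytoplasm(nuc)
  lab <- labelData(cyt)
  expect_true(all(lab > 0))              # every pixel assigned
  expect_identical(lab[labelData(nuc) == 1], labelData(nuc)[labelData(nuc) == 1])
  # nearest-seed oracle: boundary along x = 60 within 1 px
  for (x in c(1, 30, 58)) expect_true(all(lab[x, ] == 1))
  for (x in c(63, 90, 120)) expect_true(all(lab[x, ] == 2))
})

test_that("cytoplasm regions own their cell's centrioles", {
  sc <- stdScene()
  nuc <- segmentNuclei(sceneImages(sc)[, , "dna"], 0.1)
  cyt <- assignCytoplasm(nuc)
  tr <- sceneTruth(sc)
  # match segmented nuclei to truth cells by nucleus centroid
  st <- rootcohesion:::labelStats(labelData(nuc), pixelSizeUm = 0.1)
  truthIdx <- vapply(seq_len(nrow(st)), function(i)
    which.min((tr$cells$nucXUm - st$xUm[i])^2 +
              (tr$cells$nucYUm - st$yUm[i])^2), integer(1))
  lab <- labelData(cyt)
  own <- mapply(function(cid, label) {
    cents <- tr$centrioles[tr$centrioles$cell == cid, ]
    ij <- cbind(round(cents$xUm / 0.1) + 1, round(cents$yUm / 0.1) + 1)
    mean(lab[ij] == label)
  }, truthIdx, st$label)
  expect_gte(mean(own), 0.95)
})

test_that("shape mismatches between channels are rejected", {
  nuc <- labelMap(matrix(0L, 10, 10), 0.1)
  expect_error(assignCytoplasm(nuc, reference = matrix(0, 5, 5)), "differ")
  expect_error(measureObjects(nuc, matrix(0, 5, 5)), "differ")
})

test_that("declumping separates touching foci and grouping merges them", {
  # two discs radius 6 whose masks overlap by a sliver
  img <- discImage(80, 40, rbind(c(30, 20), c(41, 20)), 6, value = 200)
  one <- detectFoci(img, pixelSizeUm = 0.1, declump = FALSE)
  expect_equal(nrow(one), 1)
  two <- detectFoci(img, pixelSizeUm = 0.1, declump = TRUE)
  expect_equal(nrow(two), 2)
  # well-separated discs (3 um apart): 2 foci in either mode
  far <- discImage(80, 40, rbind(c(20, 20), c(50, 20)), 6, value = 200)
  expect_equal(nrow(detectFoci(far, pixelSizeUm = 0.1, declump = FALSE)), 2)
  expect_equal(nrow(detectFoci(far, pixelSizeUm = 0.1, declump = TRUE)), 2)
})

test_that("PCM focus detection recovers the truth census on a field", {
  sc <- stdScene()
  nuc <- segmentNuclei(sceneImages(sc)[, , "dna"], 0.1)
  cyt <- assignCytoplasm(nuc)
  foci <- detectFoci(sceneImages(sc)[, , "pcm"], cyt, declump = TRUE)
  tr <- sceneTruth(sc)
  # a pair counts as detected when a focus lies within 0.3 um of either
  # centriole, or (for cohered pairs merged into one focus even under
  # declumping) within 0.5 um of the pair midpoint
  pairHit <- vapply(unique(tr$centrioles$pairId), function(pid) {
    cents <- tr$centrioles[tr$centrioles$pairId == pid, ]
    dCent <- vapply(seq_len(nrow(cents)), function(i)
      min(sqrt((foci$xUm - cents$xUm[i])^2 +
               (foci$yUm - cents$yUm[i])^2)), numeric(1))
    dMid <- min(sqrt((foci$xUm - mean(cents$xUm))^2 +
                     (foci$yUm - mean(cents$yUm))^2))
    any(dCent < 0.3) || dMid < 0.5
  }, logical(1))
  expect_gte(mean(pairHit), 0.95)
})

test_that("robust-background threshold shifts exactly with an offset", {
  x <- rootcohesion:::withSeed(5, matrix(rnorm(4000, 10, 2), 80, 50))
  expect_equal(robustBackgroundThreshold(x + 37),
               robustBackgroundThreshold(x) + 37, tolerance = 1e-10)
  # segmentation with robust_background is offset-invariant
  img <- discImage(80, 50, cbind(40, 25), 8, value = 300) +
    rootcohesion:::withSeed(6, matrix(rnorm(4000, 0, 3), 80, 50))
  f0 <- detectFoci(img, pixelSizeUm = 0.1,
                   thresholdMethod = "robust_background", minAreaPx = 10)
  f1 <- detectFoci(img + 55, pixelSizeUm = 0.1,
                   thresholdMethod = "robust_background", minAreaPx = 10)
  expect_equal(f0$areaPx, f1$areaPx)
  expect_equal(f0$xUm, f1$xUm)
})

test_that("root propagation partitions the thresholded mask by seed", {
  # one cohered cell, noiseless: roots overlap their pair partner's
  cfg <- do.call(sceneConfig,
                 c(list(nCells = 1L, fieldPx = 300L, pSplit = 0,
                        pMitotic = 0), noiselessArgs))
  sc <- simulateField(cfg, seed = 3)
  img <- sceneImages(sc)
  foci <- detectFoci(img[, , "pcm"], pixelSizeUm = 0.1, declump = TRUE)
  rs <- segmentRoots(img[, , "rootletin"], foci, 0.1)
  lab <- labelData(rootLabels(rs))
  th <- rootcohesion:::autoThreshold(img[, , "rootletin"], "otsu")
  mask <- img[, , "rootletin"] > th
  # partition: every thresholded pixel gets exactly one root label
  expect_true(all(lab[mask] > 0))
  expect_true(all(lab[!mask] == 0))
  expect_equal(sum(rootInfo(rs)$areaPx), sum(mask))
  expect_equal(nrow(rootInfo(rs)), nrow(foci))
})

test_that("a single root's segmented area matches truth within 10%", {
  cfg <- do.call(sceneConfig,
                 c(list(nCells = 1L, fieldPx = 300L, pSplit = 0,
                        pMitotic = 0), noiselessArgs))
  sc <- simulateField(cfg, seed = 6)
  img <- sceneImages(sc)
  foci <- detectFoci(img[, , "pcm"], pixelSizeUm = 0.1, declump = TRUE)
  rs <- segmentRoots(img[, , "rootletin"], foci, 0.1)
  truthArea <- sum(sceneTruth(sc)$rootLabels > 0)
  expect_lt(abs(sum(rootInfo(rs)$areaPx) - truthArea) / truthArea, 0.10)
})

test_that("propagation without seeds is an error", {
  img <- matrix(0, 32, 32)
  expect_error(segmentRoots(img, pcmFoci = NULL, pixelSizeUm = 0.1,
                            method = "propagation"), "seed")
})

test_that("measureObjects integrates uniform objects exactly", {
  img <- discImage(60, 60, cbind(30, 30), 10, value = 7)
  lm <- labelMap((img > 0) * 1L, 0.1)
  m1 <- measureObjects(lm, img)
  expect_equal(m1$integrated, 7 * sum(img > 0))  # zero background
  expect_equal(m1$areaUm2, sum(img > 0) * 0.01)
  m2 <- measureObjects(lm, img)
  expect_identical(m1, m2)                       # deterministic
})

test_that("segmented root/centriole area ratio tracks the configured scale", {
  cfg <- do.call(sceneConfig,
                 c(list(nCells = 4L, fieldPx = 420L, pMitotic = 0,
                        pSplit = 0), noiselessArgs))
  sc <- simulateField(cfg, seed = 8)
  img <- sceneImages(sc)
  cent <- detectFoci(img[, , "centriole"], pixelSizeUm = 0.1,
                     declump = TRUE, channelName = "centriole")
  pcm <- detectFoci(img[, , "pcm"], pixelSizeUm = 0.1, declump = TRUE)
  rs <- segmentRoots(img[, , "rootletin"], pcm, 0.1)
  ratio <- sum(rootInfo(rs)$areaPx) / sum(cent$areaPx)
  expect_lt(abs(ratio - cfg@rootAreaScale) / cfg@rootAreaScale, 0.15)
})

test_that("mitotic flags match truth and respond monotonically", {
  sc <- stdScene()
  nucAll <- segmentNuclei(sceneImages(sc)[, , "dna"], 0.1)
  flagsClean <- excludeMitotic(sceneImages(sc)[, , "dna"], nucAll)
  expect_equal(sum(flagsClean$mitotic), 0)   # all-interphase scene

  scM <- cached("mitoticScene", simulateField(
    sceneConfig(nCells = 40L, fieldPx = 900L, pMitotic = 0.15), seed = 17))
  nuc <- segmentNuclei(sceneImages(scM)[, , "dna"], 0.1)
  fl <- excludeMitotic(sceneImages(scM)[, , "dna"], nuc)
  tr <- sceneTruth(scM)
  st <- rootcohesion:::labelStats(labelData(nuc), pixelSizeUm = 0.1)
  truthIdx <- vapply(seq_len(nrow(st)), function(i)
    which.min((tr$cells$nucXUm - st$xUm[i])^2 +
              (tr$cells$nucYUm - st$yUm[i])^2), integer(1))
  truthFlag <- tr$cells$mitotic[truthIdx]
  sens <- mean(fl$mitotic[truthFlag])
  spec <- mean(!fl$mitotic[!truthFlag])
  expect_gte((sens + spec) / 2, 0.9)

  stricter <- excludeMitotic(sceneImages(scM)[, , "dna"], nuc,
                             intensityFactor = 4, areaFactor = 2.8)
  expect_lte(sum(stricter$mitotic), sum(fl$mitotic))
})
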