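# Synthetic scene generator: determinism, degenerate cases, rendering
# identities and the statistical properties of the simulated populations.

test_that("identical config and seed give bit-identical scenes", {
  cfg <- smallSceneConfig(pMitotic = 0.2)
  a <- simulateField(cfg, seed = 7)
  b <- simulateField(cfg, seed = 7)
  expect_identical(sceneImages(a), sceneImages(b))
  expect_identical(sceneTruth(a), sceneTruth(b))
  c <- simulateField(cfg, seed = 8)
  expect_false(identical(sceneImages(a), sceneImages(c)))
})

test_that("generation restores the caller's RNG state", {
  set.seed(123); before <- .Random.seed
  invisible(simulateField(smallSceneConfig(nCells = 2L), seed = 1))
  expect_identical(before, .Random.seed)
})

test_that("zero cells give a blank field and empty truth", {
  cfg <- do.call(sceneConfig,
                 c(list(nCells = 0L, fieldPx = 64L), noiselessArgs))
  sc <- simulateField(cfg, seed = 1)
  expect_equal(sum(sceneImages(sc)), 0)
  expect_equal(nrow(sceneTruth(sc)$cells), 0)
  expect_equal(nrow(sceneTruth(sc)$centrioles), 0)
})

test_that("overcrowded configurations fail with a density error", {
  cfg <- sceneConfig(nCells = 60L, fieldPx = 200L)
  expect_error(simulateField(cfg, seed = 1), "density")
})

test_that("noiseless rootletin pixels equal the union of truth root masks", {
  cfg <- do.call(sceneConfig,
                 c(list(nCells = 1L, fieldPx = 300L, pSplit = 0,
                        pMitotic = 0), noiselessArgs))
  sc <- simulateField(cfg, seed = 3)
  rendered <- sceneImages(sc)[, , "rootletin"] > 0
  truthUnion <- sceneTruth(sc)$rootLabels > 0
  expect_identical(rendered, truthUnion)
})

test_that("rendered root areas match the configured area scale", {
  cfg <- do.call(sceneConfig,
                 c(list(nCells = 4L, fieldPx = 420L, pMitotic = 0),
                   noiselessArgs))
  sc <- simulateField(cfg, seed = 5)
  tr <- sceneTruth(sc)
  focusPx <- pi * 3^2  # centriole rendered as a 0.3-um (3-px) disc
  ratio <- tr$roots$areaPx / focusPx
  expect_true(all(abs(ratio - cfg@rootAreaScale) / cfg@rootAreaScale < 0.15))
})

test_that("PSF blur conserves total intensity within rasterisation error", {
  base <- list(nCells = 3L, fieldPx = 400L, pMitotic = 0)
  sharp <- simulateField(do.call(sceneConfig, c(base, noiselessArgs)),
                         seed = 11)
  blurred <- simulateField(
    do.call(sceneConfig, c(base, list(psfSigmaUm = 0.15,
                                      noiseGaussianSd = 0,
                                      noisePoissonGain = 0))), seed = 11)
  for (ch in c("dna", "centriole", "pcm", "rootletin")) {
    s0 <- sum(sceneImages(sharp)[, , ch])
    s1 <- sum(sceneImages(blurred)[, , ch])
    expect_lt(abs(s1 - s0) / s0, 0.01)
  }
})

test_that("truth split flags obey the distance rule and the binomial rate", {
  # flags on a rendered scene are exactly the distance rule
  cfg <- smallSceneConfig(pSplit = 0.5)
  sc <- simulateField(cfg, seed = 9)
  tr <- sceneTruth(sc)
  c99 <- cfg@coheredDistUm[1] + qnorm(0.99) * cfg@coheredDistUm[2]
  expect_identical(tr$cells$splitFlag, tr$cells$pairDistanceUm > c99)

  # empirical split fraction across 10 seeds at n = 1000 draws each,
  # against an independent re-count of the flags
  p <- 0.1
  drawCfg <- sceneConfig(pSplit = p)
  for (s in 1:10) {
    draws <- rootcohesion:::withSeed(s, replicate(1000, {
      rootcohesion:::drawPairDistance(drawCfg)$split
    }))
    frac <- sum(draws) / 1000            # independent direct count
    expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 1000))
  }
})

test_that("truth linkage flags reflect rendered mask adjacency", {
  cfg <- do.call(sceneConfig,
                 c(list(nCells = 8L, fieldPx = 500L, pMitotic = 0,
                        distanceRangeUm = c(0.3, 4)), noiselessArgs))
  sc <- simulateField(cfg, seed = 13)
  tr <- sceneTruth(sc)
  lab <- tr$rootLabels
  for (pid in unique(tr$roots$pairId)) {
    ids <- tr$roots$id[tr$roots$pairId == pid]
    # labels are first-claim, so measure adjacency on the label image:
    # linked pairs must touch after 1-px dilation
    mA <- lab == ids[1]; mB <- lab == ids[2]
    touching <- any(rootcohesion:::dilate1px(mA) & mB)
    flagged <- unique(tr$roots$linked[tr$roots$pairId == pid])
    if (flagged) expect_true(touching)
  }
})

test_that("two-state occupancy matches the analytic stationary fraction", {
  sr <- 0.3; rr <- 0.7
  stationary <- sr / (sr + rr)
  nChains <- 60
  finals <- rootcohesion:::withSeed(21, vapply(seq_len(nChains), function(i)
    tail(simulateSplitStates(600, 0.2, sr, rr, startSplit = FALSE), 1),
    logical(1)))
  # after 600 frames the chain has long forgotten its start, so terminal
  # states are independent Bernoulli(stationary) draws
  expect_lt(abs(mean(finals) - stationary),
            3 * sqrt(stationary * (1 - stationary) / nChains))
})

test_that("absorbing cohered state never splits when the rate is zero", {
  s <- rootcohesion:::withSeed(1, simulateSplitStates(200, 0.2, 0, 1))
  expect_false(any(s))
})

test_that("kinetic model encodes release, assembly and FRAP closed forms", {
  cfg <- timelapseConfig(anaphaseTimeH = 4, releaseLeadH = 2.5,
                         assemblyTauH = 2, assemblyPlateau = 100)
  expect_equal(kineticModelTrace(cfg, 1), 100)            # plateau
  expect_equal(kineticModelTrace(cfg, 2.75), 50)          # mid-release
  expect_equal(kineticModelTrace(cfg, 4), 0)              # anaphase
  expect_equal(kineticModelTrace(cfg, 4 + 2 * log(10)),
               90, tolerance = 1e-9)                      # 90% at tau*ln10

  # FRAP plateau: (1 - depth) + depth * mobile = 0.5 + 0.5 * 0.3 = 0.65
  frapCfg <- timelapseConfig(anaphaseTimeH = NA, frapBleachTimeH = 1,
                             frapBleachDepth = 0.5, frapMobileFraction = 0.3,
                             frapRecoveryTauH = 0.5, assemblyPlateau = 100)
  expect_equal(kineticModelTrace(frapCfg, 20), 65, tolerance = 1e-6)

  # instant full recovery: back to pre-bleach level by the next frame
  inst <- timelapseConfig(anaphaseTimeH = NA, frapBleachTimeH = 1,
                          frapBleachDepth = 0.5, frapMobileFraction = 1,
                          frapRecoveryTauH = 1e-6, assemblyPlateau = 100)
  expect_equal(kineticModelTrace(inst, 1.2), 100, tolerance = 1e-6)
})

test_that("time-lapse truth records events and stays deterministic", {
  cfg <- fixtureConfig("timelapse", durationH = 6, fieldPx = 96L)
  a <- simulateTimelapse(cfg, seed = 2)
  b <- simulateTimelapse(cfg, seed = 2)
  expect_identical(a@frames, b@frames)
  expect_identical(a@truth$trace, b@truth$trace)
  expect_equal(a@truth$anaphaseFrame,
               which((a@truth$trace$timeH) >= cfg@anaphaseTimeH)[1])
  expect_false(any(a@truth$trace$split))  # splitRatePerH = 0 fixture
})

test_that("FRAP bleach colliding with anaphase is rejected", {
  cfg <- timelapseConfig(anaphaseTimeH = 4, frapBleachTimeH = 3.95,
                         durationH = 8)
  expect_error(simulateTimelapse(cfg, seed = 1), "ambiguous")
})

test_that("config invariants are enforced", {
  expect_error(sceneConfig(pSplit = 1.5), "pSplit")
  expect_error(sceneConfig(splitDistUm = c(0.8, 4)), "99th percentile")
  expect_error(timelapseConfig(durationH = 2, anaphaseTimeH = 4),
               "cover")
  expect_error(timelapseConfig(frapBleachTimeH = 1, frapBleachDepth = 0),
               "frapBleachDepth")
})
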