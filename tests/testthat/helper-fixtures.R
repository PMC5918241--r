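# Shared fixtures and independent oracles. Scenes are generated in code at
# test time; the larger ones are cached per session so several tests can
# share them.

smallSceneConfig <- function(...) {
  do.call(sceneConfig, utils::modifyList(
    list(nCells = 6L, fieldPx = 420L), list(...)))
}

noiselessArgs <- list(psfSigmaUm = 0, noiseGaussianSd = 0,
                      noisePoissonGain = 0)

.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# a mid-size noisy field shared across segmentation tests
stdScene <- function() cached("stdScene", {
  simulateField(sceneConfig(nCells = 50L, fieldPx = 1000L, pMitotic = 0),
                seed = 42)
})

# image with uniform discs *set* (not summed) to a value
discImage <- function(nx, ny, centers, radiusPx, value = 100) {
  m <- matrix(0, nx, ny)
  for (i in seq_len(nrow(centers))) {
    xs <- 1:nx; ys <- 1:ny
    m[outer((xs - centers[i, 1])^2, (ys - centers[i, 2])^2, "+") <=
        radiusPx^2] <- value
  }
  m
}

# greedy nearest-neighbour matcher: oracle upper bound on assignment cost
greedyMatchCost <- function(cost, dummyCost) {
  total <- 0
  nr <- nrow(cost)
  usedR <- logical(nr); usedC <- logical(ncol(cost))
  repeat {
    cc <- cost
    cc[usedR, ] <- Inf; cc[, usedC] <- Inf
    if (!any(is.finite(cc))) break
    ij <- which(cc == min(cc), arr.ind = TRUE)[1, ]
    total <- total + cost[ij[1], ij[2]]
    usedR[ij[1]] <- TRUE; usedC[ij[2]] <- TRUE
  }
  total + sum(!usedR) * dummyCost
}

# brute-force single-linkage at a fixed cut: connected components of the
# "distance <= h" graph, found by breadth-first search
bruteForceClusterSizes <- function(x, y, h) {
  n <- length(x)
  adj <- as.matrix(stats::dist(cbind(x, y))) <= h
  seen <- logical(n)
  sizes <- integer(0)
  for (i in seq_len(n)) {
    if (seen[i]) next
    queue <- i; comp <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE; comp <- c(comp, v)
      queue <- c(queue, which(adj[v, ] & !seen))
    }
    sizes <- c(sizes, length(comp))
  }
  sort(sizes, decreasing = TRUE)
}

configKeyFromSizes <- function(sizes) {
  switch(paste(sizes, collapse = "+"),
         "4" = "grouped", "2+2" = "two_pairs", "3+1" = "three_plus_one",
         "2+1+1" = "two_plus_one_plus_one", "1+1+1+1" = "all_split")
}

# direct Welch formula, independent of stats::t.test
welchOracle <- function(a, b) {
  va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# synthetic intensity trace following the kinetic model plus iid noise
syntheticTrace <- function(config, seed, noiseSd = 0) {
  dtH <- config@frameIntervalMin / 60
  nFrames <- floor(config@durationH / dtH) + 1L
  timeH <- (seq_len(nFrames) - 1) * dtH
  y <- kineticModelTrace(config, timeH)
  if (noiseSd > 0) {
    y <- rootcohesion:::withSeed(seed,
                                 y + stats::rnorm(length(y), 0, noiseSd))
  }
  anaF <- if (is.na(config@anaphaseTimeH)) NA_integer_ else
    which(timeH >= config@anaphaseTimeH)[1]
  blF <- if (is.na(config@frapBleachTimeH)) NA_integer_ else
    which(timeH >= config@frapBleachTimeH)[1]
  intensityTrace(timeH, y, anaphaseFrame = anaF, bleachFrame = blF)
}
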