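# Internal helpers shared across modules. Images are plain numeric matrices
# with dim (nx, ny); pixel (i, j) is 1-based, its physical position is
# ((i-1) * pixelSizeUm, (j-1) * pixelSizeUm), origin top-left.

# Evaluate expr with a private RNG stream; the caller's RNG state is
# restored afterwards so simulation never perturbs user code.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

umToPx <- function(um, pixelSizeUm) um / pixelSizeUm + 1
pxToUm <- function(px, pixelSizeUm) (px - 1) * pixelSizeUm

logistic <- function(x) 1 / (1 + exp(-x))

# Decreasing logistic linkage probability vs distance.
linkProbability <- function(distUm, midpointUm, steepness) {
  logistic(-(distUm - midpointUm) / steepness)
}

#' Robust-background intensity threshold
#'
#' Discards the dimmest and brightest \code{trim} fraction of pixel values,
#' then returns mean + \code{k} * SD of the remainder. Designed for images
#' whose pixels are predominantly background, where a bimodal method such as
#' Otsu is unreliable. Adding a constant offset to the image shifts the
#' threshold by exactly that offset.
#'
#' @param x numeric matrix or vector of intensities.
#' @param k number of SDs above the trimmed mean (default 2).
#' @param trim fraction trimmed from each tail (default 0.05).
#' @return scalar threshold.
#' @export
robustBackgroundThreshold <- function(x, k = 2, trim = 0.05) {
  v <- sort(as.numeric(x))
  n <- length(v)
  lo <- floor(n * trim) + 1
  hi <- n - floor(n * trim)
  core <- v[lo:hi]
  mean(core) + k * stats::sd(core)
}

# Threshold dispatcher used by the segmentation operations.
autoThreshold <- function(img, method = c("otsu", "robust_background"),
                          k = 2) {
  method <- match.arg(method)
  if (method == "otsu") {
    rng <- range(img)
    if (diff(rng) == 0) return(rng[1] + 1)  # flat image: nothing above
    sc <- (img - rng[1]) / diff(rng)
    EBImage::otsu(EBImage::Image(sc), range = c(0, 1)) * diff(rng) + rng[1]
  } else {
    robustBackgroundThreshold(img, k = k)
  }
}

# Per-label area, centroid (um) and intensity sums over a label matrix.
# Returns a data.frame ordered by label.
labelStats <- function(labels, intensity = NULL, pixelSizeUm = 1) {
  lab <- as.integer(labels)
  keep <- lab > 0
  if (!any(keep)) {
    return(data.frame(label = integer(0), areaPx = integer(0),
                      areaUm2 = numeric(0), xUm = numeric(0),
                      yUm = numeric(0), integrated = numeric(0),
                      mean = numeric(0)))
  }
  lab <- lab[keep]
  idx <- which(keep)
  nx <- nrow(labels)
  xi <- ((idx - 1) %% nx)            # 0-based x
  yi <- ((idx - 1) %/% nx)           # 0-based y
  area <- tabulate(lab)
  labs <- which(area > 0)
  sx <- rowsum(xi, lab)[, 1]
  sy <- rowsum(yi, lab)[, 1]
  out <- data.frame(label = labs, areaPx = area[labs],
                    areaUm2 = area[labs] * pixelSizeUm^2,
                    xUm = sx / area[labs] * pixelSizeUm,
                    yUm = sy / area[labs] * pixelSizeUm)
  if (!is.null(intensity)) {
    si <- rowsum(as.numeric(intensity)[idx], lab)[, 1]
    out$integrated <- si
    out$mean <- si / out$areaPx
  } else {
    out$integrated <- NA_real_
    out$mean <- NA_real_
  }
  rownames(out) <- NULL
  out
}

# --- rendering primitives --------------------------------------------------

# Add a uniform disc of given value; cx, cy are 1-based continuous pixel
# coordinates. Clipped at image borders.
addDisc <- function(img, cx, cy, radiusPx, value) {
  nx <- nrow(img); ny <- ncol(img)
  x0 <- max(1L, floor(cx - radiusPx)); x1 <- min(nx, ceiling(cx + radiusPx))
  y0 <- max(1L, floor(cy - radiusPx)); y1 <- min(ny, ceiling(cy + radiusPx))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  dx2 <- (xs - cx)^2
  dy2 <- (ys - cy)^2
  inside <- outer(dx2, dy2, "+") <= radiusPx^2
  img[xs, ys][inside] <- img[xs, ys][inside] + value
  img
}

# Mask (logical) of a disc, used for truth geometry.
discMask <- function(nx, ny, cx, cy, radiusPx) {
  m <- matrix(FALSE, nx, ny)
  x0 <- max(1L, floor(cx - radiusPx)); x1 <- min(nx, ceiling(cx + radiusPx))
  y0 <- max(1L, floor(cy - radiusPx)); y1 <- min(ny, ceiling(cy + radiusPx))
  if (x0 > x1 || y0 > y1) return(m)
  xs <- x0:x1; ys <- y0:y1
  m[xs, ys] <- outer((xs - cx)^2, (ys - cy)^2, "+") <= radiusPx^2
  m
}

# Add an isotropic Gaussian spot whose *total* (untruncated) integral is
# `total`; used for time-lapse spots where integrated intensity carries the
# kinetic signal.
addGaussianSpot <- function(img, cx, cy, sigmaPx, total) {
  nx <- nrow(img); ny <- ncol(img)
  r <- ceiling(4 * sigmaPx)
  x0 <- max(1L, floor(cx - r)); x1 <- min(nx, ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(ny, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  gx <- exp(-((xs - cx)^2) / (2 * sigmaPx^2))
  gy <- exp(-((ys - cy)^2) / (2 * sigmaPx^2))
  amp <- total / (2 * pi * sigmaPx^2)
  img[xs, ys] <- img[xs, ys] + amp * outer(gx, gy)
  img
}

# Pixels covered by a polyline (list of segments, each a 2x2 matrix of
# 1-based px endpoints), by dense sampling. Returns an index matrix.
polylinePixels <- function(segments, nx, ny) {
  pts <- do.call(rbind, lapply(segments, function(s) {
    len <- sqrt(sum((s[2, ] - s[1, ])^2))
    n <- max(2L, ceiling(len * 4))
    t <- seq(0, 1, length.out = n)
    cbind(s[1, 1] + t * (s[2, 1] - s[1, 1]),
          s[1, 2] + t * (s[2, 2] - s[1, 2]))
  }))
  pts <- round(pts)
  keep <- pts[, 1] >= 1 & pts[, 1] <= nx & pts[, 2] >= 1 & pts[, 2] <= ny
  unique(pts[keep, , drop = FALSE])
}

# Logical mask of a polyline dilated to a tube of the given brush width.
tubeMask <- function(segments, nx, ny, widthPx) {
  px <- polylinePixels(segments, nx, ny)
  m <- matrix(0L, nx, ny)
  if (nrow(px) == 0) return(m > 0)
  m[px] <- 1L
  if (widthPx > 1) {
    brush <- EBImage::makeBrush(max(3L, widthPx + (widthPx + 1) %% 2), "disc")
    m <- as.matrix(EBImage::dilate(EBImage::Image(m), brush))
  }
  m > 0
}

# Dilate a logical mask by one pixel (3x3 box, 8-connectivity).
dilate1px <- function(mask) {
  m <- EBImage::dilate(EBImage::Image(mask * 1),
                       EBImage::makeBrush(3, "box"))
  as.matrix(m) > 0
}

# FNV-1a 32-bit hash of a character string, as hex; used for parameter
# hashes in run logs.
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256                      # xor touches the low byte only
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply via 16-bit split (exact in doubles)
    hi <- h %/% 65536; lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
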