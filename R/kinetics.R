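# Kinetic analyses of centrosomal intensity traces: FRAP normalization and
# recovery fitting, post-anaphase assembly fitting, and pre-anaphase
# release-onset estimation.

#' Normalize a FRAP trace
#'
#' \eqn{R(t) = (I(t) - I_{post}) / (I_{pre} - I_{post})}, where
#' \eqn{I_{pre}} is the mean of the pre-bleach frames and \eqn{I_{post}}
#' the first post-bleach frame, so \eqn{R = 0} at the bleach and
#' \eqn{R = 1} at full recovery. The normalization cancels any affine
#' transformation of the raw intensities.
#'
#' @param trace an \linkS4class{IntensityTrace} with a bleach frame and at
#'   least 3 pre-bleach frames.
#' @return list: \code{timeH} (hours post-bleach), \code{R}, \code{iPre},
#'   \code{iPost}.
#' @export
normalizeFrap <- function(trace) {
  bf <- trace@bleachFrame
  if (is.na(bf)) stop("trace has no bleach frame")
  pre <- trace@frames < bf
  if (sum(pre) < 3) stop("need at least 3 pre-bleach frames")
  post <- trace@frames >= bf
  iPre <- mean(trace@intensity[pre])
  iPost <- trace@intensity[which(post)[1]]
  if (iPre <= iPost)
    stop("no bleach detected: pre-bleach level does not exceed ",
         "post-bleach level")
  t0 <- trace@timeH[which(post)[1]]
  list(timeH = trace@timeH[post] - t0,
       R = (trace@intensity[post] - iPost) / (iPre - iPost),
       iPre = iPre, iPost = iPost)
}

#' Fit a single-exponential FRAP recovery
#'
#' Least-squares fit of \eqn{R(t) = f_m (1 - e^{-t/\tau})} to a
#' normalized recovery curve, multi-started over
#' \eqn{\tau \in \{0.5, 2, 8\}} h to avoid local minima. The mobile
#' fraction is constrained to [0, 1] (recovery cannot exceed the
#' pre-bleach level) and \eqn{\tau} to the observation window, beyond
#' which the plateau is unidentifiable. The plateau recovery percentage
#' is \eqn{100 f_m}; \eqn{1 - f_m} is the immobile fraction.
#'
#' @param norm output of [normalizeFrap()] (or any list with \code{timeH}
#'   and \code{R}).
#' @return a \linkS4class{FrapFit}.
#' @export
fitRecovery <- function(norm) {
  tt <- norm$timeH; R <- norm$R
  if (length(tt) < 5) stop("need at least 5 post-bleach timepoints")
  # fm is bounded by physics (recovery cannot exceed the pre-bleach
  # level); tau is bounded by the observation window, beyond which the
  # plateau is unidentifiable and the fit degenerates into a linear ramp
  tauMax <- max(tt)
  fits <- lapply(c(0.5, 2, 8), function(tau0) {
    tryCatch(minpack.lm::nls.lm(
      par = list(fm = max(0.05, min(0.95, max(R))),
                 tau = min(tau0, tauMax)),
      fn = function(p) R - p$fm * (1 - exp(-tt / p$tau)),
      lower = c(fm = 0, tau = 1e-3), upper = c(fm = 1, tau = tauMax),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) == 0)
    stop("FRAP recovery fit failed to converge from all starting values")
  rss <- vapply(fits, function(f) sum(f$fvec^2), numeric(1))
  best <- fits[[which.min(rss)]]
  co <- unlist(best$par)
  fm <- unname(co["fm"])
  clipped <- fm < 0 || fm > 1
  if (clipped) {
    message("mobile fraction ", signif(fm, 4), " clipped to [0, 1]")
    fm <- min(max(fm, 0), 1)
  }
  new("FrapFit", mobileFraction = fm, tauH = unname(co["tau"]),
      plateauRecoveryPct = 100 * fm,
      iPre = if (!is.null(norm$iPre)) norm$iPre else NA_real_,
      iPost = if (!is.null(norm$iPost)) norm$iPost else NA_real_,
      residSS = min(rss), nPoints = length(tt))
}

#' Fit post-anaphase assembly kinetics
#'
#' Least-squares fit of the saturating exponential
#' \eqn{I(t) = I_0 + A (1 - e^{-t/\tau_a})} to an anaphase-aligned mean
#' trace (time zero at anaphase). The operational assembly duration is
#' \eqn{t_{90} = \tau_a \ln 10}, the time at which 90% of the plateau
#' increase is reached.
#'
#' @param timeH time from anaphase, hours (>= 0); at least 10 points.
#' @param intensity trace values.
#' @return an \linkS4class{AssemblyFit}.
#' @export
estimateAssembly <- function(timeH, intensity) {
  if (length(timeH) < 10) stop("need at least 10 post-anaphase timepoints")
  amp0 <- max(intensity) - min(intensity)
  rng <- if (amp0 > 0) amp0 else 1
  fits <- lapply(c(1, 3, 8), function(tau0) {
    tryCatch(minpack.lm::nls.lm(
      par = list(i0 = min(intensity), A = max(amp0, 1e-6), tau = tau0),
      fn = function(p) intensity - p$i0 - p$A * (1 - exp(-timeH / p$tau)),
      lower = c(i0 = -Inf, A = -Inf, tau = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) == 0) stop("assembly fit failed to converge")
  rss <- vapply(fits, function(f) sum(f$fvec^2), numeric(1))
  best <- fits[[which.min(rss)]]
  co <- unlist(best$par)
  if (co["A"] <= 0 || co["A"] < 0.05 * rng)
    stop("no assembly detected: fitted amplitude is not positive")
  new("AssemblyFit", i0 = unname(co["i0"]), amplitude = unname(co["A"]),
      tauH = unname(co["tau"]), t90H = unname(co["tau"]) * log(10),
      residSS = min(rss), nPoints = length(timeH))
}

#' Estimate the onset of pre-anaphase release
#'
#' Fits a piecewise model to the pre-anaphase segment of an
#' anaphase-aligned trace (time <= 0, anaphase at 0): a constant plateau
#' up to a breakpoint, then a linear decline towards anaphase. The
#' breakpoint is found by exhaustive scan over the frames, solving the
#' two-parameter linear least-squares problem at each candidate, and the
#' onset is the breakpoint's lead time before anaphase.
#'
#' @param timeH time relative to anaphase, hours (non-positive), covering
#'   at least 2 h.
#' @param intensity trace values.
#' @return list: \code{onsetH} (hours before anaphase, \code{NA} when no
#'   decline is detected), \code{slope} (per hour), \code{plateau},
#'   \code{sse}, \code{declineDetected}.
#' @export
estimateReleaseOnset <- function(timeH, intensity) {
  ord <- order(timeH)
  timeH <- timeH[ord]; intensity <- intensity[ord]
  if (any(timeH > 1e-9)) stop("trace must be pre-anaphase (time <= 0)")
  if (diff(range(timeH)) < 2)
    stop("need at least 2 h of pre-anaphase coverage")
  n <- length(timeH)
  best <- list(sse = Inf)
  for (k in 2:(n - 1)) {          # breakpoint at frame k
    tb <- timeH[k]
    x <- pmax(timeH - tb, 0)      # 0 before break, (t - tb) after
    X <- cbind(1, x)
    fit <- stats::lm.fit(X, intensity)
    sse <- sum(fit$residuals^2)
    if (sse < best$sse)
      best <- list(sse = sse, k = k, plateau = fit$coefficients[1],
                   slope = fit$coefficients[2], breakTimeH = tb)
  }
  # a genuine decline, not numerical dust on a flat trace
  tol <- 1e-8 * max(abs(intensity), 1)
  decline <- is.finite(best$slope) && best$slope < -tol
  list(onsetH = if (decline) -best$breakTimeH else NA_real_,
       slope = unname(best$slope), plateau = unname(best$plateau),
       sse = best$sse, declineDetected = decline)
}
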