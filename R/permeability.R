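# fast OLS of y on x: slope, intercept, r^2
.ols <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) return(list(slope = 0, intercept = my, r2 = 0))
  sxy <- sum((x - mx) * (y - my))
  syy <- sum((y - my)^2)
  slope <- sxy / sxx
  r2 <- if (syy == 0) 1 else (sxy^2) / (sxx * syy)
  list(slope = slope, intercept = my - slope * mx, r2 = r2)
}

#' Initial slope of the gel intensity trace
#'
#' Ordinary least-squares slope of the mean gel intensity against time over
#' the frames \code{[t0, t0 + fitWindow)}, with its coefficient of
#' determination. This is the rate-of-change term of the permeability
#' formula when the transmembrane intensity difference is treated as constant
#' over the window.
#'
#' @param trace an [IntensityTrace-class].
#' @param fitWindow number of frames in the fit (>= 3 available after t0).
#' @return A list: \code{slope} (intensity/s), \code{rSquared},
#'   \code{nFitFrames}.
#' @export
fitInitialSlope <- function(trace, fitWindow = 10L) {
  stopifnot(is(trace, "IntensityTrace"))
  n <- length(trace@times)
  idx <- trace@t0Index:min(n, trace@t0Index + fitWindow - 1L)
  if (length(idx) < 3L)
    stop("need at least 3 frames at/after t0 for the slope fit; have ",
         length(idx))
  fit <- .ols(trace@times[idx], trace@iAveGel[idx])
  list(slope = fit$slope, rSquared = fit$r2, nFitFrames = length(idx))
}

#' Permeability coefficient from the ROI quantities
#'
#' \deqn{P_d = \frac{A_{gel}\,(dI_{ave,gel}/dt)}
#'                  {w_{monolayer}\,(I_{lumen} - I_{y=0})_{t=0}}}
#' with geometry in micrometres; the result is converted to cm/s. The ratio
#' is homogeneous of degree 0 in intensity, so camera gain cancels.
#'
#' @param slope rate of change of mean gel intensity, intensity/s.
#' @param deltaI transmembrane intensity difference at t0 (> 0).
#' @param AUm2 gel-box area, um^2.
#' @param wUm interface (monolayer) width, um.
#' @return Permeability in cm/s.
#' @examples
#' computePd(slope = 1, deltaI = 1000, AUm2 = 1e4, wUm = 100)  # 1e-5 cm/s
#' @export
computePd <- function(slope, deltaI, AUm2, wUm) {
  if (!is.finite(deltaI) || deltaI <= 0)
    stop("'deltaI' must be positive (saturated interface or mis-detected t0)")
  if (AUm2 <= 0 || wUm <= 0) stop("geometry must be positive")
  (AUm2 * slope) / (wUm * deltaI) * 1e-4      # um/s -> cm/s
}

#' Fit the permeability coefficient from one trace
#'
#' Two estimators are available. \code{"linear"} is the literal ROI formula:
#' OLS slope of the gel intensity over the early window divided by the
#' transmembrane intensity difference at t0 (see [computePd()]). The default
#' \code{"flux"} generalises it: since the instantaneous influx is
#' proportional to the measured \eqn{\Delta I(t) = I_{lumen}(t) - I_{y=0}(t)},
#' the gel intensity is regressed on the cumulative time-integral of
#' \eqn{\Delta I(t)} (trapezoid rule); the regression slope times
#' \eqn{A_{gel}/w} is \eqn{P_d}. The two coincide when \eqn{\Delta I} is
#' constant over the window; the flux fit stays unbiased when the interface
#' concentration builds up during the window (fast membranes, slow gels).
#'
#' A front guard truncates the window at the first frame where the far edge
#' of the gel box carries signal (front reaching the end of the measurement
#' volume breaks the ROI mass balance); at least \code{minFitFrames} frames
#' are always kept and \code{frontReached} reports the truncation.
#'
#' @param trace an [IntensityTrace-class].
#' @param triple the matching [RoiTriple-class] (geometry source).
#' @param fitWindow maximal number of frames after t0 (default 10).
#' @param method \code{"flux"} (default) or \code{"linear"}.
#' @param frontGuard enable far-edge truncation (default TRUE).
#' @param minFitFrames minimal frames kept (default 3).
#' @return A list: \code{pd} (cm/s), \code{slope} (time-OLS slope,
#'   intensity/s), \code{deltaI}, \code{rSquared} (of the fit used),
#'   \code{nFitFrames}, \code{frontReached}, \code{t0Index}.
#' @export
fitPd <- function(trace, triple, fitWindow = 10L,
                  method = c("flux", "linear"), frontGuard = TRUE,
                  minFitFrames = 3L) {
  stopifnot(is(trace, "IntensityTrace"), is(triple, "RoiTriple"))
  method <- match.arg(method)
  n <- length(trace@times)
  t0 <- trace@t0Index
  idx <- t0:min(n, t0 + fitWindow - 1L)
  if (length(idx) < minFitFrames)
    stop("need at least ", minFitFrames, " frames at/after t0; have ",
         length(idx))
  frontReached <- FALSE
  if (frontGuard) {
    pre <- seq_len(t0 - 1L)
    noiseFloor <- if (length(pre) >= 3L) sd(trace@iFar[pre]) else 0
    contaminated <- trace@iFar[idx] >
      pmax(0.02 * trace@iY0[idx], 3 * noiseFloor)
    first <- which(contaminated)[1L]
    if (!is.na(first)) {
      frontReached <- TRUE
      keep <- max(minFitFrames, first - 1L)
      idx <- idx[seq_len(min(keep, length(idx)))]
    }
  }
  deltaI <- trace@iLumen[t0] - trace@iY0[t0]
  if (!is.finite(deltaI) || deltaI <= 0)
    stop("'deltaI' at t0 is not positive (saturated interface or bad t0)")
  tfit <- .ols(trace@times[idx], trace@iAveGel[idx])
  if (method == "linear") {
    pd <- computePd(tfit$slope, deltaI, triple@AUm2, triple@wUm)
    r2 <- tfit$r2
  } else {
    dI <- trace@iLumen[idx] - trace@iY0[idx]
    dt <- diff(trace@times[idx])
    X <- c(0, cumsum((dI[-1L] + dI[-length(dI)]) / 2 * dt))
    ffit <- .ols(X, trace@iAveGel[idx])
    pd <- ffit$slope * (triple@AUm2 / triple@wUm) * 1e-4
    r2 <- ffit$r2
  }
  list(pd = pd, slope = tfit$slope, deltaI = deltaI, rSquared = r2,
       nFitFrames = length(idx), frontReached = frontReached, t0Index = t0)
}

#' Focal-leak detection on the interface profile
#'
#' A focal leak (a localised defect of the monolayer) produces a bright plume
#' at the interface. The spatial intensity profile along the interface line is
#' averaged over \code{window} frames after t0; the leak score is
#' \eqn{(\max - \mathrm{median}) / \mathrm{median}} of that profile, and the
#' measurement is flagged when the score exceeds \code{threshold}. A
#' non-positive median yields a flagged measurement with an infinite score.
#'
#' @param stack an [ImageStack-class].
#' @param triple a [RoiTriple-class].
#' @param background a [BackgroundModel-class] or \code{NULL}.
#' @param t0Index 1-based filling frame (from [extractTraces()]).
#' @param window frames after t0 entering the profile average (default 10).
#' @param threshold flag threshold on the score (default 1.0).
#' @return A list: \code{flag} (logical), \code{score}.
#' @export
detectFocalLeak <- function(stack, triple, background = NULL, t0Index,
                            window = 10L, threshold = 1.0) {
  stopifnot(is(stack, "ImageStack"), is(triple, "RoiTriple"))
  n <- nFrames(stack)
  if (t0Index >= n) stop("need at least 2 frames after t0 for leak QC")
  idx <- t0Index:min(n, t0Index + window - 1L)
  rows <- (triple@interfaceRows[1L] + 1L):triple@interfaceRows[2L]
  col <- triple@interfaceCol + 1L
  prof <- stack@frames[idx, rows, col, drop = FALSE]
  dim(prof) <- c(length(idx), length(rows))
  profile <- colMeans(prof)
  if (!is.null(background)) {
    bg <- if (background@mode == "scalar") background@value
          else background@value[rows, col]
    profile <- pmax(profile - bg, 0)
  }
  med <- median(profile)
  if (!is.finite(med) || med <= 0)
    return(list(flag = TRUE, score = Inf))
  score <- (max(profile) - med) / med
  list(flag = score > threshold, score = score)
}

#' Measure the permeability of every data point in a device
#'
#' Composes the whole pipeline for one stack: background estimation from the
#' pre-injection frames, ROI construction (unless explicit triples are
#' given), trace extraction, lumen-filling detection, permeability fitting
#' and focal-leak QC. Per-triple failures are recorded as failed rows (with
#' the error message), never aborting the device.
#'
#' @param stack an [ImageStack-class].
#' @param triples list of [RoiTriple-class], or \code{NULL} to build them
#'   from \code{geometry}.
#' @param geometry a [DeviceGeometry-class] (required when \code{triples} is
#'   \code{NULL}).
#' @param background a [BackgroundModel-class]; when \code{NULL} it is
#'   estimated from the first \code{nPreFrames} frames.
#' @param nPreFrames pre-injection frames for background estimation
#'   (default 5).
#' @param gelDepth,lumenMargin passed to [buildRoiTriples()].
#' @param fitWindow,method,frontGuard passed to [fitPd()]; the guard is
#'   disabled automatically for gel boxes reaching the gel midline (two
#'   seeded channels) or the far gel wall, where the box mass balance is
#'   closed and no truncation is needed.
#' @param plateauFraction,t0 passed to [detectT0()].
#' @param leakWindow,leakThreshold passed to [detectFocalLeak()].
#' @param rSquaredWarn fits with \eqn{r^2} below this raise a QC warning flag
#'   (not an exclusion; default 0.9).
#' @return data.frame with one row per triple: \code{triple_id}, \code{side},
#'   \code{slope}, \code{delta_I}, \code{A_gel_um2}, \code{w_um},
#'   \code{Pd_cm_s}, \code{r2}, \code{focal_leak}, \code{leak_score},
#'   \code{t0_index}, \code{n_fit_frames}, \code{front_reached},
#'   \code{qc_warning}, \code{error}. The evaluated configuration is attached
#'   as attribute \code{"config"}.
#' @examples
#' cfg <- simulationConfig(pdTrue = 2e-5, duration = 600, gelHalfWidth = 200,
#'                         lumenWidth = 40, gapWidth = 60, nGaps = 2L,
#'                         gridDx = 5, pixelSize = 5, seed = 11)
#' tr <- simulateDevice(cfg)
#' measureDevice(tr@stack, geometry = tr@geometry)
#' @export
measureDevice <- function(stack, triples = NULL, geometry = NULL,
                          background = NULL, nPreFrames = 5L,
                          gelDepth = NULL, lumenMargin = 50,
                          fitWindow = 10L, method = c("flux", "linear"),
                          frontGuard = TRUE, plateauFraction = 0.95,
                          t0 = NULL, leakWindow = 10L, leakThreshold = 1.0,
                          rSquaredWarn = 0.9) {
  stopifnot(is(stack, "ImageStack"))
  method <- match.arg(method)
  if (is.null(triples)) {
    if (is.null(geometry))
      stop("supply either 'triples' or 'geometry'")
    if (geometry@axis == "y") {     # transpose to the canonical orientation
      stack@frames <- aperm(stack@frames, c(1L, 3L, 2L))
      geometry@axis <- "x"
    }
    triples <- buildRoiTriples(geometry, pixelSize = pixelSize(stack),
                               gelDepth = gelDepth,
                               lumenMargin = lumenMargin)
  }
  if (is.null(background))
    background <- estimateBackground(stack, nPreFrames = nPreFrames)
  # when a gel box reaches the midline (two seeded channels) or the far gel
  # wall (one channel), the net flux through its far edge vanishes and the
  # front guard must not truncate the window
  guardFor <- function(tr) {
    if (!frontGuard) return(FALSE)
    if (is.null(geometry)) return(TRUE)
    W <- geometry@gelCols[2L] - geometry@gelCols[1L]
    depthPx <- tr@gelRect[4L] - tr@gelRect[3L]
    closed <- if (length(geometry@monolayerCols) == 2L)
      depthPx >= W %/% 2L else depthPx >= W
    !closed
  }
  rows <- vector("list", length(triples))
  for (i in seq_along(triples)) {
    tr <- triples[[i]]
    row <- data.frame(
      triple_id = tr@id, side = tr@side, slope = NA_real_,
      delta_I = NA_real_, A_gel_um2 = tr@AUm2, w_um = tr@wUm,
      Pd_cm_s = NA_real_, r2 = NA_real_, focal_leak = NA,
      leak_score = NA_real_, t0_index = NA_integer_,
      n_fit_frames = NA_integer_, front_reached = NA,
      qc_warning = NA, error = NA_character_)
    res <- tryCatch({
      trace <- extractTraces(stack, tr, background,
                             plateauFraction = plateauFraction, t0 = t0)
      fit <- fitPd(trace, tr, fitWindow = fitWindow, method = method,
                   frontGuard = guardFor(tr))
      leak <- detectFocalLeak(stack, tr, background,
                              t0Index = trace@t0Index, window = leakWindow,
                              threshold = leakThreshold)
      row$slope <- fit$slope
      row$delta_I <- fit$deltaI
      row$Pd_cm_s <- fit$pd
      row$r2 <- fit$rSquared
      row$focal_leak <- leak$flag
      row$leak_score <- leak$score
      row$t0_index <- fit$t0Index
      row$n_fit_frames <- fit$nFitFrames
      row$front_reached <- fit$frontReached
      row$qc_warning <- fit$rSquared < rSquaredWarn
      row
    }, error = function(e) {
      row$error <- conditionMessage(e)
      row
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- list(
    pixel_size_um = pixelSize(stack), frame_interval_s = frameInterval(stack),
    n_background_frames = nPreFrames, gel_depth_um = gelDepth,
    lumen_margin_um = lumenMargin, fit_window = fitWindow, method = method,
    front_guard = frontGuard, plateau_fraction = plateauFraction,
    leak_window = leakWindow, leak_threshold = leakThreshold,
    r_squared_warn = rSquaredWarn)
  out
}
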