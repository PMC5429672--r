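#' Detect the lumen-filling frame (t = 0)
#'
#' The reference time for the permeability fit is the frame at which the
#' tracer has completely filled the lumen. The plateau level is the median of
#' the top quartile of the lumen intensity trace; t0 is the first frame
#' reaching \code{plateauFraction} of it. An explicit \code{t0} overrides
#' detection.
#'
#' @param iLumen lumen mean-intensity trace (background-subtracted).
#' @param plateauFraction fraction of the plateau that counts as "filled"
#'   (default 0.95).
#' @param t0 optional user-supplied 1-based frame index.
#' @return 1-based frame index.
#' @examples
#' detectT0(c(0, 0, 100, 100, 100))   # 3
#' @export
detectT0 <- function(iLumen, plateauFraction = 0.95, t0 = NULL) {
  if (!is.null(t0)) {
    t0 <- as.integer(t0)
    if (t0 < 1L || t0 > length(iLumen)) stop("'t0' out of range")
    return(t0)
  }
  n <- length(iLumen)
  if (n < 2L) stop("lumen trace needs at least 2 frames")
  top <- sort(iLumen, decreasing = TRUE)[seq_len(ceiling(n / 4))]
  plateau <- median(top)
  if (!is.finite(plateau) || plateau <= 0)
    stop("lumen never fills: plateau intensity is not positive")
  idx <- which(iLumen >= plateauFraction * plateau)
  if (!length(idx))
    stop("lumen never reaches ", plateauFraction, " of its plateau")
  idx[1L]
}

# per-frame mean of a rectangular region for all frames, background-subtracted.
# The subtraction acts on the ROI mean and the mean is clipped at zero:
# clipping individual pixels would rectify camera noise and systematically
# shrink dim-signal slopes (per-pixel SNR < 1 is routine in the gel box at
# low permeability).
.regionTrace <- function(framesArr, rect, background) {
  d <- dim(framesArr)[2:3]
  idx <- .rectIdx(as.integer(rect), d)
  sub <- framesArr[, idx$rows, idx$cols, drop = FALSE]
  nf <- dim(sub)[1L]
  dim(sub) <- c(nf, prod(dim(sub)[-1L]))
  out <- rowMeans(sub)
  if (!is.null(background)) {
    bg <- if (background@mode == "scalar") background@value
          else mean(background@value[idx$rows, idx$cols])
    out <- pmax(out - bg, 0)
  }
  out
}

#' Extract background-subtracted intensity traces for one ROI triple
#'
#' Per-frame means of the lumen box, interface line, gel box and the far edge
#' of the gel box, with the lumen-filling frame attached.
#'
#' @param stack an [ImageStack-class].
#' @param triple a [RoiTriple-class].
#' @param background a [BackgroundModel-class] or \code{NULL}.
#' @param plateauFraction passed to [detectT0()].
#' @param t0 optional explicit filling frame.
#' @return An [IntensityTrace-class].
#' @export
extractTraces <- function(stack, triple, background = NULL,
                          plateauFraction = 0.95, t0 = NULL) {
  stopifnot(is(stack, "ImageStack"), is(triple, "RoiTriple"))
  f <- stack@frames
  lineRect <- c(triple@interfaceRows, triple@interfaceCol,
                triple@interfaceCol + 1L)
  farRect <- c(triple@interfaceRows, triple@farCol, triple@farCol + 1L)
  iLumen <- .regionTrace(f, triple@lumenRect, background)
  iY0 <- .regionTrace(f, lineRect, background)
  iAveGel <- .regionTrace(f, triple@gelRect, background)
  iFar <- .regionTrace(f, farRect, background)
  t0i <- detectT0(iLumen, plateauFraction = plateauFraction, t0 = t0)
  new("IntensityTrace",
      times = frameTimes(stack), iLumen = iLumen, iY0 = iY0,
      iAveGel = iAveGel, iFar = iFar, t0Index = as.integer(t0i))
}
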