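#' @rdname ImageStack-class
#' @param object,x an object.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname ImageStack-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname ImageStack-class
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname ImageStack-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname ImageStack-class
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname SyntheticTruth-class
#' @export
setGeneric("truePd", function(x) standardGeneric("truePd"))

#' @describeIn ImageStack-class the T x H x W intensity array.
#' @export
setMethod("frames", "ImageStack", function(x) x@frames)

#' @describeIn ImageStack-class micrometres per pixel.
#' @export
setMethod("pixelSize", "ImageStack", function(x) x@pixelSize)

#' @describeIn ImageStack-class seconds per frame.
#' @export
setMethod("frameInterval", "ImageStack", function(x) x@frameInterval)

#' @describeIn ImageStack-class number of frames.
#' @export
setMethod("nFrames", "ImageStack", function(x) dim(x@frames)[1L])

#' @describeIn ImageStack-class acquisition times in seconds (first frame 0).
#' @export
setMethod("frameTimes", "ImageStack",
          function(x) (seq_len(nFrames(x)) - 1L) * x@frameInterval)

#' @describeIn SyntheticTruth-class nominal ground-truth permeability, cm/s.
#' @export
setMethod("truePd", "SyntheticTruth", function(x) x@truePd)

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("ImageStack: %d frames of %d x %d px\n", d[1L], d[2L], d[3L]))
  cat(sprintf("  calibration: %.3g um/px, %.3g s/frame\n",
              object@pixelSize, object@frameInterval))
  if (nzchar(object@label)) cat("  label:", object@label, "\n")
  cat(sprintf("  intensity range: [%.4g, %.4g]\n",
              min(object@frames), max(object@frames)))
})

setMethod("show", "BackgroundModel", function(object) {
  if (object@mode == "scalar")
    cat(sprintf("BackgroundModel: scalar, value %.4g\n", object@value))
  else
    cat(sprintf("BackgroundModel: per-pixel, %d x %d map, mean %.4g\n",
                nrow(object@value), ncol(object@value), mean(object@value)))
})

setMethod("show", "DeviceGeometry", function(object) {
  cat(sprintf(
    "DeviceGeometry: %d monolayer(s), %d post gap(s), diffusion along %s\n",
    length(object@monolayerCols), length(object@postGaps), object@axis))
  cat(sprintf("  gel columns [%d, %d); monolayer column(s): %s\n",
              object@gelCols[1L], object@gelCols[2L],
              paste(object@monolayerCols, collapse = ", ")))
})

setMethod("show", "RoiTriple", function(object) {
  cat(sprintf(
    "RoiTriple #%d (%s): w = %.4g um, A_gel = %.4g um^2\n",
    object@id, object@side, object@wUm, object@AUm2))
  cat(sprintf("  interface line: col %d, rows [%d, %d)\n",
              object@interfaceCol, object@interfaceRows[1L],
              object@interfaceRows[2L]))
})

setMethod("show", "IntensityTrace", function(object) {
  cat(sprintf("IntensityTrace: %d frames, t0 at frame %d (t = %.4g s)\n",
              length(object@times), object@t0Index,
              object@times[object@t0Index]))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: Pd = %.3g cm/s, D_gel = %.3g cm^2/s, seed %d\n",
    object@pdTrue, object@dGel, object@seed))
  cat(sprintf("  device: %d monolayer(s) x %d gap(s) of %.3g um, gel 2 x %.3g um\n",
              object@nMonolayers, object@nGaps, object@gapWidth,
              object@gelHalfWidth))
  cat(sprintf("  acquisition: every %.3g s for %.3g s (+%d pre-frames)\n",
              object@frameInterval, object@duration, object@nPreFrames))
  if (!is.null(object@leak))
    cat(sprintf("  focal leak: gap %d, %.0f%% of width, x%.3g\n",
                object@leak$gap, 100 * object@leak$widthFraction,
                object@leak$multiplier))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: true Pd = %.3g cm/s, lumen full at frame %d\n",
              object@truePd, object@trueT0Frame))
  show(object@stack)
})
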