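#' @import methods
NULL

#' Calibrated time-lapse image stack
#'
#' Container for a grayscale time-lapse acquisition: a \code{T x H x W} array
#' of non-negative intensities together with the physical calibration needed
#' to convert pixels and frames into micrometres and seconds. All downstream
#' geometry (monolayer width, gel area) and every permeability coefficient
#' derive their physical units from these two numbers.
#'
#' @slot frames numeric array, time x row x column; finite, non-negative.
#' @slot pixelSize micrometres per pixel (> 0).
#' @slot frameInterval seconds between consecutive frames (> 0).
#' @slot label free-text label (probe name, condition, device id).
#'
#' @seealso [readStack()], [writeStack()], [estimateBackground()]
#' @export
setClass("ImageStack",
  representation(
    frames        = "array",
    pixelSize     = "numeric",
    frameInterval = "numeric",
    label         = "character"
  )
)

setValidity("ImageStack", function(object) {
  f <- object@frames
  if (length(dim(f)) != 3L)
    return("'frames' must be a 3-D array (time x row x column)")
  if (dim(f)[1L] < 2L)
    return("a stack needs at least 2 frames")
  if (!all(is.finite(f)))
    return("frame intensities must be finite")
  if (min(f) < 0)
    return("frame intensities must be non-negative")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("'pixelSize' must be a single positive number (um/px)")
  if (length(object@frameInterval) != 1L || !is.finite(object@frameInterval) ||
      object@frameInterval <= 0)
    return("'frameInterval' must be a single positive number (s)")
  TRUE
})

#' Construct an ImageStack
#'
#' @param frames 3-D numeric array ordered time x row x column.
#' @param pixelSize micrometres per pixel.
#' @param frameInterval seconds per frame.
#' @param label optional free-text label.
#' @return An [ImageStack-class] object.
#' @examples
#' s <- ImageStack(array(0:23, c(2, 3, 4)), pixelSize = 2, frameInterval = 30)
#' nFrames(s)
#' @export
ImageStack <- function(frames, pixelSize, frameInterval, label = "") {
  new("ImageStack", frames = frames, pixelSize = as.numeric(pixelSize),
      frameInterval = as.numeric(frameInterval), label = as.character(label))
}

#' Background intensity model
#'
#' Camera background estimated from pre-injection frames, subtracted from all
#' intensity values before any permeability arithmetic. Either a single scalar
#' (default, one number for the whole field of view) or a per-pixel map.
#'
#' @slot mode \code{"scalar"} or \code{"per-pixel"}.
#' @slot value single non-negative intensity, or an H x W matrix.
#' @seealso [estimateBackground()]
#' @export
setClass("BackgroundModel",
  representation(mode = "character", value = "ANY")
)

setValidity("BackgroundModel", function(object) {
  if (!object@mode %in% c("scalar", "per-pixel"))
    return("'mode' must be \"scalar\" or \"per-pixel\"")
  v <- object@value
  if (object@mode == "scalar") {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      return("scalar background must be a single non-negative number")
  } else {
    if (!is.matrix(v) || !all(is.finite(v)) || min(v) < 0)
      return("per-pixel background must be a finite non-negative matrix")
  }
  TRUE
})

#' Microfluidic device geometry
#'
#' Pixel-level description of the two-channel device: where the endothelial
#' monolayer(s) sit, which pixel columns belong to the central gel and to the
#' lumen channel(s), and the intervals along the monolayer where the barrier
#' is exposed between the supporting posts. One data point is measured per
#' post gap per monolayer.
#'
#' All pixel coordinates are 0-based and intervals are half-open
#' \code{[start, end)}, so lengths and areas are plain differences.
#'
#' @slot axis image axis along which diffusion proceeds: \code{"x"} (columns)
#'   or \code{"y"} (rows; the stack is transposed internally).
#' @slot monolayerCols one or two pixel columns holding the monolayer(s); with
#'   two, they must flank \code{gelCols}.
#' @slot gelCols integer \code{c(start, end)}: column extent of the gel.
#' @slot lumenCols list of integer \code{c(start, end)} column extents, one
#'   per lumen channel, same order as \code{monolayerCols}.
#' @slot postGaps list of integer \code{c(start, end)} row intervals where the
#'   monolayer is exposed between posts; non-overlapping.
#' @seealso [deviceGeometry()], [buildRoiTriples()]
#' @export
setClass("DeviceGeometry",
  representation(
    axis          = "character",
    monolayerCols = "integer",
    gelCols       = "integer",
    lumenCols     = "list",
    postGaps      = "list"
  )
)

.isInterval <- function(x) {
  is.numeric(x) && length(x) == 2L && all(is.finite(x)) &&
    all(x == round(x)) && x[2L] > x[1L] && x[1L] >= 0
}

setValidity("DeviceGeometry", function(object) {
  if (!object@axis %in% c("x", "y"))
    return("'axis' must be \"x\" or \"y\"")
  m <- object@monolayerCols
  if (!length(m) %in% 1:2 || any(m < 0))
    return("'monolayerCols' must hold one or two non-negative columns")
  if (!.isInterval(object@gelCols))
    return("'gelCols' must be an increasing half-open interval")
  if (length(object@lumenCols) != length(m))
    return("need one lumen column span per monolayer")
  for (lu in object@lumenCols) {
    if (!.isInterval(lu)) return("each lumen span must be a valid interval")
    if (lu[2L] > object@gelCols[1L] && lu[1L] < object@gelCols[2L])
      return("lumen spans must not intersect the gel span")
  }
  if (length(object@postGaps) < 1L)
    return("'postGaps' must list at least one exposed interval")
  gaps <- object@postGaps
  for (g in gaps) if (!.isInterval(g)) return("invalid post gap interval")
  if (length(gaps) > 1L) {
    o <- order(vapply(gaps, `[`, numeric(1), 1L))
    gs <- gaps[o]
    for (i in seq_len(length(gs) - 1L))
      if (gs[[i]][2L] > gs[[i + 1L]][1L]) return("post gaps overlap")
  }
  # monolayers must border the gel span
  for (i in seq_along(m)) {
    ok <- (m[i] == object@gelCols[1L] - 1L) || (m[i] == object@gelCols[2L])
    if (!ok) return("each monolayer column must border the gel span")
  }
  TRUE
})

#' One data point's ROI triple
#'
#' The three regions whose intensities yield a single permeability data point:
#' a lumen box inside the cell channel, a one-pixel-wide interface line in the
#' gel flush against the monolayer, and a gel box whose monolayer-side edge
#' coincides with the interface line. Rectangles are 0-based, half-open
#' \code{c(row0, row1, col0, col1)}.
#'
#' @slot id integer triple identifier within a device.
#' @slot side \code{"left"} or \code{"right"}: which monolayer it belongs to.
#' @slot lumenRect rectangle inside the lumen channel.
#' @slot gelRect rectangle inside the gel; contains the interface line on its
#'   monolayer-side edge.
#' @slot interfaceCol the single gel-side pixel column of the interface line.
#' @slot interfaceRows row interval of the interface line (one post gap).
#' @slot wUm physical length of the interface line, um.
#' @slot AUm2 physical area of the gel rectangle, um^2.
#' @slot farCol outermost gel column of \code{gelRect} (front-guard line).
#' @seealso [buildRoiTriples()], [extractTraces()]
#' @export
setClass("RoiTriple",
  representation(
    id            = "integer",
    side          = "character",
    lumenRect     = "integer",
    gelRect       = "integer",
    interfaceCol  = "integer",
    interfaceRows = "integer",
    wUm           = "numeric",
    AUm2          = "numeric",
    farCol        = "integer"
  )
)

.isRect <- function(r) {
  is.numeric(r) && length(r) == 4L && all(is.finite(r)) &&
    all(r == round(r)) && r[2L] > r[1L] && r[4L] > r[3L] && all(r[c(1, 3)] >= 0)
}

setValidity("RoiTriple", function(object) {
  if (!.isRect(object@lumenRect)) return("invalid 'lumenRect'")
  if (!.isRect(object@gelRect)) return("invalid 'gelRect'")
  if (!object@side %in% c("left", "right")) return("invalid 'side'")
  g <- object@gelRect
  ic <- object@interfaceCol
  if (!(ic == g[3L] || ic == g[4L] - 1L))
    return("interface line must lie on the monolayer-side edge of 'gelRect'")
  if (!identical(object@interfaceRows, g[1:2]))
    return("interface rows must match the gel rectangle rows")
  # lumen and gel boxes disjoint (column spans cannot meet: gel edge is at
  # the interface, lumen is across the monolayer)
  l <- object@lumenRect
  overlap <- l[4L] > g[3L] && g[4L] > l[3L] && l[2L] > g[1L] && g[2L] > l[1L]
  if (overlap) return("lumen and gel rectangles must be disjoint")
  if (object@wUm <= 0 || object@AUm2 <= 0)
    return("'wUm' and 'AUm2' must be positive")
  TRUE
})

#' Intensity traces for one ROI triple
#'
#' Per-frame, background-subtracted mean intensities of the three ROIs, plus
#' the far-edge line of the gel box (used to detect when the diffusion front
#' reaches the end of the measurement volume) and the detected lumen-filling
#' frame.
#'
#' @slot times seconds from acquisition start, strictly increasing.
#' @slot iLumen mean lumen-box intensity per frame.
#' @slot iY0 mean interface-line intensity per frame.
#' @slot iAveGel mean gel-box intensity per frame.
#' @slot iFar mean intensity of the outermost gel-box pixel line per frame.
#' @slot t0Index 1-based frame index at which the lumen is completely filled.
#' @seealso [extractTraces()], [fitPd()]
#' @export
setClass("IntensityTrace",
  representation(
    times   = "numeric",
    iLumen  = "numeric",
    iY0     = "numeric",
    iAveGel = "numeric",
    iFar    = "numeric",
    t0Index = "integer"
  )
)

setValidity("IntensityTrace", function(object) {
  n <- length(object@times)
  if (n < 2L) return("a trace needs at least 2 frames")
  for (nm in c("iLumen", "iY0", "iAveGel", "iFar")) {
    v <- slot(object, nm)
    if (length(v) != n) return("all trace arrays must share one length")
    if (!all(is.finite(v)) || min(v) < 0)
      return("trace intensities must be finite and non-negative")
  }
  dt <- diff(object@times)
  if (any(dt <= 0)) return("'times' must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6 * max(dt))
    return("'times' must be evenly spaced")
  if (object@t0Index < 1L || object@t0Index > n)
    return("'t0Index' out of range")
  TRUE
})

#' Synthetic-experiment configuration
#'
#' Ground-truth physics, device geometry, acquisition schedule and camera
#' noise for the forward simulator. Defaults describe a dextran-like tracer
#' on the reference two-channel device; see the methods vignette for the
#' reasoning behind each value.
#'
#' @slot pdTrue true membrane permeability, cm/s.
#' @slot dGel tracer diffusivity in the gel, cm^2/s.
#' @slot cLumen lumen concentration after filling, arbitrary units.
#' @slot gelHalfWidth half-width of the central gel, um.
#' @slot lumenWidth rendered lumen channel width, um.
#' @slot nGaps number of post gaps along the monolayer.
#' @slot gapWidth width of each post gap, um.
#' @slot postWidth width of each post, um.
#' @slot nMonolayers 1 or 2 seeded channels.
#' @slot gridDx solver grid spacing, um.
#' @slot pixelSize rendered pixel size, um/px.
#' @slot frameInterval s between frames.
#' @slot duration acquisition length after injection, s.
#' @slot fillTime s over which the lumen ramps to \code{cLumen}.
#' @slot nPreFrames background frames acquired before injection.
#' @slot photonGain expected counts per concentration unit.
#' @slot readNoiseSd Gaussian read noise, counts.
#' @slot offset camera offset, counts.
#' @slot gapPdCv lognormal coefficient of variation of per-gap-per-side true
#'   permeability around \code{pdTrue} (biological heterogeneity); 0 disables.
#' @slot leak \code{NULL}, or \code{list(gap, position, widthFraction,
#'   multiplier)} describing a focal leak.
#' @slot seed integer RNG seed used by the renderer.
#' @seealso [simulationConfig()], [simulateDevice()]
#' @export
setClass("SimulationConfig",
  representation(
    pdTrue        = "numeric",
    dGel          = "numeric",
    cLumen        = "numeric",
    gelHalfWidth  = "numeric",
    lumenWidth    = "numeric",
    nGaps         = "integer",
    gapWidth      = "numeric",
    postWidth     = "numeric",
    nMonolayers   = "integer",
    gridDx        = "numeric",
    pixelSize     = "numeric",
    frameInterval = "numeric",
    duration      = "numeric",
    fillTime      = "numeric",
    nPreFrames    = "integer",
    photonGain    = "numeric",
    readNoiseSd   = "numeric",
    offset        = "numeric",
    gapPdCv       = "numeric",
    leak          = "ANY",
    seed          = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  pos <- c(dGel = object@dGel, cLumen = object@cLumen,
           gelHalfWidth = object@gelHalfWidth, lumenWidth = object@lumenWidth,
           gapWidth = object@gapWidth, gridDx = object@gridDx,
           pixelSize = object@pixelSize, frameInterval = object@frameInterval,
           duration = object@duration)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad))
    return(paste0("'", bad[1L], "' must be positive"))
  if (object@pdTrue < 0) return("'pdTrue' must be >= 0")
  if (object@postWidth < 0 || object@fillTime < 0 || object@readNoiseSd < 0 ||
      object@offset < 0 || object@gapPdCv < 0 || object@photonGain < 0)
    return("'postWidth', 'fillTime', noise and CV parameters must be >= 0")
  if (object@nGaps < 1L) return("'nGaps' must be >= 1")
  if (!object@nMonolayers %in% 1:2) return("'nMonolayers' must be 1 or 2")
  if (object@nPreFrames < 1L) return("'nPreFrames' must be >= 1")
  if (!is.null(object@leak)) {
    lk <- object@leak
    need <- c("gap", "widthFraction", "multiplier")
    if (!is.list(lk) || !all(need %in% names(lk)))
      return("'leak' must be a list with gap, widthFraction, multiplier")
    if (lk$widthFraction <= 0 || lk$widthFraction >= 1)
      return("leak widthFraction must be in (0, 1)")
    if (lk$multiplier < 1) return("leak multiplier must be >= 1")
    if (lk$gap < 1 || lk$gap > object@nGaps) return("leak gap out of range")
  }
  TRUE
})

#' Rendered synthetic experiment with ground truth
#'
#' The output of the forward simulator: a noisy rendered stack, its noise-free
#' expectation, the generating configuration, the matching pixel geometry and
#' the ground-truth quantities recovery tests compare against.
#'
#' @slot config the generating [SimulationConfig-class].
#' @slot stack rendered noisy [ImageStack-class] (integer counts).
#' @slot noiseFreeStack expectation of \code{stack} under the noise model.
#' @slot geometry [DeviceGeometry-class] describing the rendered frames.
#' @slot truePd nominal true permeability, cm/s.
#' @slot gapPd matrix (gap x side) of realised per-gap true permeabilities.
#' @slot trueT0Frame 1-based frame index at which the lumen is full.
#' @seealso [simulateDevice()], [renderStack()]
#' @export
setClass("SyntheticTruth",
  representation(
    config         = "SimulationConfig",
    stack          = "ImageStack",
    noiseFreeStack = "ImageStack",
    geometry       = "DeviceGeometry",
    truePd         = "numeric",
    gapPd          = "matrix",
    trueT0Frame    = "integer"
  )
)
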