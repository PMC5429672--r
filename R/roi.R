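#' Construct a device geometry
#'
#' @param monolayerCols one or two pixel columns (0-based) holding the
#'   monolayer(s).
#' @param gelCols integer \code{c(start, end)}: half-open column extent of the
#'   central gel.
#' @param lumenCols list of half-open column extents, one per monolayer.
#' @param postGaps list of half-open row intervals where the monolayer is
#'   exposed between posts.
#' @param axis image axis along which diffusion proceeds (\code{"x"}:
#'   columns).
#' @return A [DeviceGeometry-class].
#' @examples
#' geom <- deviceGeometry(
#'   monolayerCols = c(59, 385), gelCols = c(60, 385),
#'   lumenCols = list(c(0, 59), c(386, 445)),
#'   postGaps = list(c(10, 70), c(90, 150))
#' )
#' geom
#' @export
deviceGeometry <- function(monolayerCols, gelCols, lumenCols, postGaps,
                           axis = "x") {
  if (is.numeric(lumenCols)) lumenCols <- list(lumenCols)
  new("DeviceGeometry",
      axis = axis,
      monolayerCols = as.integer(monolayerCols),
      gelCols = as.integer(gelCols),
      lumenCols = lapply(lumenCols, as.integer),
      postGaps = lapply(postGaps, as.integer))
}

#' Read a device geometry (and optional explicit ROIs) from YAML or JSON
#'
#' Expected keys: \code{axis}, \code{monolayer_cols}, \code{gel_cols},
#' \code{lumen_cols} (list of 2-vectors), \code{post_gaps} (list of
#' 2-vectors), and optionally \code{pixel_size_um}, \code{frame_interval_s},
#' \code{n_background_frames} and an explicit \code{rois} list (see
#' [roiTriplesFromList()]).
#'
#' @param path path to a YAML (\code{.yml}/\code{.yaml}) or JSON file.
#' @return A list with elements \code{geometry} ([DeviceGeometry-class]),
#'   \code{config} (the raw key-value list) and \code{rois} (list of
#'   [RoiTriple-class] or \code{NULL}).
#' @export
readGeometry <- function(path) {
  if (!file.exists(path)) stop("no such geometry file: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("monolayer_cols", "gel_cols", "lumen_cols", "post_gaps")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("geometry file misses keys: ", paste(miss, collapse = ", "))
  asIntervals <- function(x) {
    if (is.matrix(x)) x <- split(x, row(x))
    if (!is.list(x)) x <- list(x)
    lapply(x, as.integer)
  }
  geom <- deviceGeometry(
    monolayerCols = unlist(cfg$monolayer_cols),
    gelCols = unlist(cfg$gel_cols),
    lumenCols = asIntervals(cfg$lumen_cols),
    postGaps = asIntervals(cfg$post_gaps),
    axis = if (is.null(cfg$axis)) "x" else cfg$axis)
  rois <- NULL
  if (!is.null(cfg$rois) && !is.null(cfg$pixel_size_um))
    rois <- roiTriplesFromList(cfg$rois, cfg$pixel_size_um)
  list(geometry = geom, config = cfg, rois = rois)
}

#' Build ROI triples from explicit per-triple rectangles
#'
#' Mirrors manual ROI delineation on real images: each list element supplies
#' \code{lumen_rect}, \code{gel_rect} (0-based half-open
#' \code{c(row0, row1, col0, col1)}) and \code{side} (\code{"left"} if the
#' monolayer sits at the low-column edge of the gel rectangle).
#'
#' @param rois list of per-triple specifications.
#' @param pixelSize micrometres per pixel used for physical lengths/areas.
#' @return List of [RoiTriple-class].
#' @export
roiTriplesFromList <- function(rois, pixelSize) {
  out <- vector("list", length(rois))
  for (i in seq_along(rois)) {
    r <- rois[[i]]
    g <- as.integer(unlist(r$gel_rect))
    l <- as.integer(unlist(r$lumen_rect))
    side <- if (is.null(r$side)) "left" else r$side
    ic <- if (side == "left") g[3L] else g[4L] - 1L
    fc <- if (side == "left") g[4L] - 1L else g[3L]
    out[[i]] <- new("RoiTriple",
      id = i, side = side, lumenRect = l, gelRect = g,
      interfaceCol = ic, interfaceRows = g[1:2],
      wUm = (g[2L] - g[1L]) * pixelSize,
      AUm2 = (g[2L] - g[1L]) * (g[4L] - g[3L]) * pixelSize^2,
      farCol = fc)
  }
  out
}

#' Build the per-data-point ROI triples for a device
#'
#' One triple is produced per post gap per monolayer: a lumen box spanning the
#' gap and a \code{lumenMargin}-wide band of the channel next to the
#' monolayer; a one-pixel interface line on the first gel-side pixel column
#' adjacent to the monolayer (which is also the monolayer-side boundary column
#' of the gel box); and a gel box extending \code{gelDepth} into the gel,
#' interface included. The gel box must capture the tracer that has crossed
#' the monolayer: by default it extends to the gel midline, where the net
#' diffusive flux vanishes by symmetry, so the ROI mass balance is closed.
#'
#' @param geometry a [DeviceGeometry-class].
#' @param pixelSize micrometres per pixel.
#' @param gelDepth depth of the gel box, um; \code{NULL} (default) extends to
#'   the gel midline (or the full gel for a single monolayer).
#' @param lumenMargin width of the lumen box band, um (default 50).
#' @return List of [RoiTriple-class], gaps nested within monolayers.
#' @examples
#' geom <- deviceGeometry(c(59, 385), c(60, 385),
#'                        list(c(0, 59), c(386, 445)),
#'                        list(c(10, 70), c(90, 150)))
#' tr <- buildRoiTriples(geom, pixelSize = 2)
#' length(tr)   # 2 monolayers x 2 gaps
#' tr[[1]]
#' @export
buildRoiTriples <- function(geometry, pixelSize, gelDepth = NULL,
                            lumenMargin = 50) {
  stopifnot(is(geometry, "DeviceGeometry"))
  if (length(geometry@postGaps) == 0L) stop("geometry has no post gaps")
  if (pixelSize <= 0) stop("'pixelSize' must be positive")
  g0 <- geometry@gelCols[1L]; g1 <- geometry@gelCols[2L]
  W <- g1 - g0
  nMono <- length(geometry@monolayerCols)
  maxDepthPx <- if (nMono == 2L) W %/% 2L else W
  depthPx <- if (is.null(gelDepth)) maxDepthPx
             else as.integer(round(gelDepth / pixelSize))
  if (depthPx < 1L) stop("'gelDepth' is below one pixel")
  if (depthPx > maxDepthPx)
    stop("'gelDepth' exceeds the usable gel depth (",
         maxDepthPx * pixelSize, " um)")
  marginPx <- max(1L, as.integer(round(lumenMargin / pixelSize)))
  out <- list()
  id <- 0L
  for (k in seq_len(nMono)) {
    m <- geometry@monolayerCols[k]
    lu <- geometry@lumenCols[[k]]
    left <- (m == g0 - 1L)
    side <- if (left) "left" else "right"
    if (left) {
      gelRectCols <- c(g0, g0 + depthPx)
      ic <- g0; fc <- g0 + depthPx - 1L
      lumCols <- c(max(lu[1L], lu[2L] - marginPx), lu[2L])
    } else {
      gelRectCols <- c(g1 - depthPx, g1)
      ic <- g1 - 1L; fc <- g1 - depthPx
      lumCols <- c(lu[1L], min(lu[2L], lu[1L] + marginPx))
    }
    for (gap in geometry@postGaps) {
      id <- id + 1L
      out[[id]] <- new("RoiTriple",
        id = id, side = side,
        lumenRect = c(gap, lumCols),
        gelRect = c(gap, gelRectCols),
        interfaceCol = ic, interfaceRows = gap,
        wUm = (gap[2L] - gap[1L]) * pixelSize,
        AUm2 = (gap[2L] - gap[1L]) * depthPx * pixelSize^2,
        farCol = fc)
    }
  }
  out
}

# 0-based half-open rect -> R row/col index lists, with bounds checking
.rectIdx <- function(rect, dimHW) {
  if (rect[1L] < 0 || rect[3L] < 0 || rect[2L] > dimHW[1L] ||
      rect[4L] > dimHW[2L])
    stop("region [", paste(rect, collapse = ","),
         ") lies outside the ", dimHW[1L], " x ", dimHW[2L], " frame")
  list(rows = (rect[1L] + 1L):rect[2L], cols = (rect[3L] + 1L):rect[4L])
}

#' Mean background-subtracted intensity of a region
#'
#' Arithmetic mean of the pixel values of a rectangular region in one frame,
#' with the background subtracted from the mean and the result clipped at
#' zero (intensity is proportional to concentration, which is non-negative;
#' clipping the mean rather than each pixel avoids rectifying camera noise).
#'
#' @param stack an [ImageStack-class].
#' @param region 0-based half-open rectangle \code{c(row0, row1, col0, col1)}.
#' @param frame 1-based frame index.
#' @param background a [BackgroundModel-class] (default: zero background).
#' @return Mean intensity (scalar).
#' @export
meanIntensity <- function(stack, region, frame, background = NULL) {
  stopifnot(is(stack, "ImageStack"))
  if (frame < 1L || frame > nFrames(stack)) stop("'frame' out of range")
  d <- dim(stack@frames)[2:3]
  idx <- .rectIdx(as.integer(region), d)
  img <- stack@frames[frame, , ]
  m <- mean(img[idx$rows, idx$cols])
  if (!is.null(background)) {
    bg <- if (background@mode == "scalar") background@value
          else mean(background@value[idx$rows, idx$cols])
    m <- max(m - bg, 0)
  }
  m
}

#' Labelled ROI overlay mask
#'
#' Integer mask the shape of one frame for visual audit of ROI placement:
#' 1 = lumen box, 2 = gel box, 3 = interface line (drawn last so it stays
#' visible on the gel-box edge).
#'
#' @param triples list of [RoiTriple-class].
#' @param dim frame dimensions \code{c(rows, cols)}.
#' @return Integer matrix.
#' @export
roiMask <- function(triples, dim) {
  m <- matrix(0L, dim[1L], dim[2L])
  for (tr in triples) {
    i <- .rectIdx(tr@lumenRect, dim); m[i$rows, i$cols] <- 1L
    i <- .rectIdx(tr@gelRect, dim);   m[i$rows, i$cols] <- 2L
  }
  for (tr in triples) {
    rows <- (tr@interfaceRows[1L] + 1L):tr@interfaceRows[2L]
    m[rows, tr@interfaceCol + 1L] <- 3L
  }
  m
}
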