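#' Read a calibrated time-lapse stack from a multi-page TIFF
#'
#' Frames are returned in acquisition order with the supplied physical
#' calibration attached. Calibration is taken from the arguments (typically a
#' config file), not parsed from image metadata, to stay independent of TIFF
#' dialects; if the file carries a pixel-size hint it is checked and a warning
#' is issued on mismatch.
#'
#' Integer TIFFs (8/16-bit) are read as raw counts. 32-bit float TIFFs written
#' by [writeStack()] carry their intensity scale in a JSON sidecar next to
#' the image and are rescaled back automatically.
#'
#' @param path path to a multi-page grayscale TIFF.
#' @param pixelSize micrometres per pixel.
#' @param frameInterval seconds per frame.
#' @param label optional label attached to the stack.
#' @return An [ImageStack-class].
#' @seealso [writeStack()]
#' @export
readStack <- function(path, pixelSize, frameInterval, label = "") {
  if (!file.exists(path)) stop("cannot read stack: no such file: ", path)
  info <- tryCatch(tiff::readTIFF(path, payload = FALSE),
                   error = function(e) stop("unreadable TIFF '", path, "': ",
                                            conditionMessage(e)))
  isFloat <- identical(info$bits.per.sample[1L], 32L)
  # integer TIFFs are read as raw counts; 32-bit float pages are stored
  # normalised and rescaled via the sidecar below
  pages <- tiff::readTIFF(path, all = TRUE, as.is = !isFloat)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L)
    stop("stack '", path, "' has fewer than 2 frames")
  shp <- dim(pages[[1L]])
  for (p in pages) {
    if (length(dim(p)) != 2L)
      stop("stack '", path, "' is not single-channel grayscale")
    if (!identical(dim(p), shp))
      stop("inconsistent frame shapes in '", path, "'")
  }
  arr <- array(0, c(length(pages), shp))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.numeric(meta$intensity_scale) && meta$intensity_scale > 0)
      arr <- arr * meta$intensity_scale
  }
  ImageStack(arr, pixelSize = pixelSize, frameInterval = frameInterval,
             label = label)
}

#' Write a stack to a multi-page TIFF
#'
#' Integer-valued stacks (counts up to 65535) are stored as 16-bit and
#' round-trip bit-exactly through [readStack()]. Non-integer stacks are stored
#' as 32-bit float, normalised by a power-of-two scale recorded in a JSON
#' sidecar (\code{<path>.json}); they round-trip to single precision.
#'
#' @param stack an [ImageStack-class].
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  f <- stack@frames
  mx <- max(f)
  isInt <- all(f == round(f))
  pages <- vector("list", dim(f)[1L])
  if (isInt && mx <= 65535) {
    for (i in seq_along(pages)) pages[[i]] <- f[i, , ] / 65535
    ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 16L),
                   error = function(e) stop("cannot write '", path, "': ",
                                            conditionMessage(e)))
  } else {
    scale <- 2 ^ ceiling(log2(max(mx, 1)))
    for (i in seq_along(pages)) pages[[i]] <- f[i, , ] / scale
    ok <- tryCatch(
      tiff::writeTIFF(pages, path, bits.per.sample = 32L),
      error = function(e) stop("cannot write '", path, "': ",
                               conditionMessage(e)))
    jsonlite::write_json(list(intensity_scale = scale),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Estimate the camera background from pre-injection frames
#'
#' The first \code{nPreFrames} frames are acquired before the tracer is
#' injected and carry only camera background. The scalar mode (default)
#' averages them into a single intensity; the per-pixel mode keeps the
#' temporal mean per pixel (useful for structured offsets). The estimate is
#' invariant to frame order within the pre-injection window.
#'
#' @param stack an [ImageStack-class].
#' @param nPreFrames number of leading pre-injection frames, with
#'   \code{1 <= nPreFrames < nFrames(stack)}.
#' @param mode \code{"scalar"} or \code{"per-pixel"}.
#' @return A [BackgroundModel-class].
#' @examples
#' s <- ImageStack(array(100, c(4, 8, 8)), 2, 30)
#' estimateBackground(s, nPreFrames = 2)
#' @export
estimateBackground <- function(stack, nPreFrames,
                               mode = c("scalar", "per-pixel")) {
  stopifnot(is(stack, "ImageStack"))
  mode <- match.arg(mode)
  nf <- nFrames(stack)
  if (nPreFrames < 1L || nPreFrames >= nf)
    stop("'nPreFrames' must satisfy 1 <= nPreFrames < ", nf)
  pre <- stack@frames[seq_len(nPreFrames), , , drop = FALSE]
  if (mode == "scalar") {
    new("BackgroundModel", mode = "scalar", value = mean(pre))
  } else {
    new("BackgroundModel", mode = "per-pixel",
        value = apply(pre, c(2L, 3L), mean))
  }
}

#' Background model from a known value
#'
#' @param value single intensity or an H x W matrix.
#' @return A [BackgroundModel-class].
#' @export
backgroundModel <- function(value) {
  if (is.matrix(value)) new("BackgroundModel", mode = "per-pixel",
                            value = value)
  else new("BackgroundModel", mode = "scalar", value = as.numeric(value))
}
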