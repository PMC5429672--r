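# small, fast study configurations used across the unit tests; physics is the
# same as the reference conditions, only the device and acquisition are
# shrunk so a solve takes ~0.1 s

smallConfig <- function(...) {
  defaults <- list(gelHalfWidth = 200, lumenWidth = 40, gapWidth = 60,
                   nGaps = 2L, gridDx = 5, pixelSize = 5, duration = 600,
                   nPreFrames = 3L)
  args <- list(...)
  do.call(simulationConfig, c(args, defaults[setdiff(names(defaults),
                                                     names(args))]))
}

# a noisy random stack with a known seed
randomStack <- function(seed = 1, nf = 3L, h = 16L, w = 20L) {
  set.seed(seed)
  ImageStack(array(rpois(nf * h * w, 500), c(nf, h, w)),
             pixelSize = 2, frameInterval = 30)
}

# the reference two-lumen geometry used by the ROI tests (pixel units)
testGeometry <- function(nGaps = 3L, gapPx = 60L, postPx = 13L,
                         gelPx = 325L, lumenPx = 30L, nMono = 2L) {
  gaps <- lapply(seq_len(nGaps), function(g) {
    r0 <- postPx * g + gapPx * (g - 1L)
    c(r0, r0 + gapPx)
  })
  if (nMono == 2L)
    deviceGeometry(
      monolayerCols = c(lumenPx, lumenPx + 1L + gelPx),
      gelCols = c(lumenPx + 1L, lumenPx + 1L + gelPx),
      lumenCols = list(c(0L, lumenPx),
                       c(lumenPx + 2L + gelPx, 2L * lumenPx + 2L + gelPx)),
      postGaps = gaps)
  else
    deviceGeometry(
      monolayerCols = lumenPx,
      gelCols = c(lumenPx + 1L, lumenPx + 1L + gelPx),
      lumenCols = list(c(0L, lumenPx)),
      postGaps = gaps)
}
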