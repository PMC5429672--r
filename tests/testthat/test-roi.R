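test_that("one triple is built per post gap per monolayer", {
  g1 <- testGeometry(nGaps = 3L, nMono = 1L)
  expect_length(buildRoiTriples(g1, pixelSize = 2), 3L)

  g2 <- testGeometry(nGaps = 4L, nMono = 2L)
  tr <- buildRoiTriples(g2, pixelSize = 2)
  expect_length(tr, 8L)   # two opposite channels double the data points
  expect_equal(sum(vapply(tr, function(x) x@side, "") == "left"), 4L)
})

test_that("physical lengths and areas follow the pixel calibration", {
  g <- deviceGeometry(monolayerCols = 9L, gelCols = c(10L, 310L),
                      lumenCols = list(c(0L, 9L)),
                      postGaps = list(c(0L, 120L)))
  tr <- buildRoiTriples(g, pixelSize = 1, gelDepth = 100)[[1]]
  expect_equal(tr@wUm, 120)
  expect_equal(tr@AUm2, 12000)

  tr2 <- buildRoiTriples(g, pixelSize = 2, gelDepth = 100)[[1]]
  expect_equal(tr2@wUm, 240)          # 120 px at 2 um/px
  expect_equal(tr2@AUm2, 240 * 100)
})

test_that("emitted triples satisfy the ROI invariants for random geometries", {
  set.seed(20)
  for (i in 1:25) {
    nG <- sample(1:4, 1)
    gapPx <- sample(10:60, 1)
    postPx <- sample(2:15, 1)
    gelPx <- sample(40:400, 1)
    lumenPx <- sample(5:40, 1)
    nMono <- sample(1:2, 1)
    geom <- testGeometry(nG, gapPx, postPx, gelPx, lumenPx, nMono)
    expect_true(validObject(geom))
    px <- sample(c(1, 2, 5), 1)
    tr <- buildRoiTriples(geom, pixelSize = px)
    expect_length(tr, nG * nMono)
    for (x in tr) {
      expect_true(validObject(x))
      # interface flush to the monolayer, inside the gel, on the gel box edge
      g <- x@gelRect
      expect_true(x@interfaceCol >= geom@gelCols[1] &&
                    x@interfaceCol < geom@gelCols[2])
      expect_true(x@interfaceCol %in% c(g[3], g[4] - 1L))
      # gel box entirely within the gel span
      expect_gte(g[3], geom@gelCols[1])
      expect_lte(g[4], geom@gelCols[2])
    }
    # opposite-side boxes are disjoint
    if (nMono == 2L) {
      left <- tr[[1]]@gelRect
      right <- tr[[nG + 1]]@gelRect
      expect_lte(left[4], right[3])
    }
  }
})

test_that("depth limits and degenerate geometries error", {
  g <- testGeometry(nGaps = 2L, gelPx = 100L)
  expect_error(buildRoiTriples(g, pixelSize = 2, gelDepth = 150),
               "exceeds")
  expect_error(deviceGeometry(monolayerCols = 9L, gelCols = c(10L, 50L),
                              lumenCols = list(c(0L, 9L)), postGaps = list()),
               "postGaps")
  expect_error(deviceGeometry(monolayerCols = 9L, gelCols = c(10L, 50L),
                              lumenCols = list(c(0L, 9L)),
                              postGaps = list(c(0L, 20L), c(10L, 30L))),
               "overlap")
})

test_that("meanIntensity averages background-subtracted pixels", {
  f <- array(10, c(2, 8, 8))
  s <- ImageStack(f, 1, 1)
  expect_equal(meanIntensity(s, c(0, 4, 0, 4), 1, backgroundModel(10)), 0)

  f2 <- array(0, c(2, 8, 8))
  f2[1, 1, 1:3] <- c(1, 2, 3)
  s2 <- ImageStack(f2, 1, 1)
  expect_equal(meanIntensity(s2, c(0, 1, 0, 3), 1), 2)

  expect_error(meanIntensity(s, c(0, 9, 0, 4), 1), "outside")

  # translation invariance on a spatially uniform frame
  u <- ImageStack(array(7, c(2, 20, 20)), 1, 1)
  v1 <- meanIntensity(u, c(0, 5, 0, 5), 1)
  v2 <- meanIntensity(u, c(10, 15, 12, 17), 1)
  expect_identical(v1, v2)
})

test_that("ROI masks and explicit ROI lists are consistent", {
  g <- testGeometry(nGaps = 2L, gelPx = 60L, lumenPx = 10L, nMono = 1L)
  tr <- buildRoiTriples(g, pixelSize = 2, gelDepth = 60)
  m <- roiMask(tr, c(160, 200))
  expect_setequal(unique(as.integer(m)), c(0L, 1L, 2L, 3L))
  # interface line: one column per triple, gap rows long
  expect_equal(sum(m == 3L), sum(vapply(tr, function(x)
    x@interfaceRows[2] - x@interfaceRows[1], integer(1))))

  lst <- list(list(lumen_rect = c(0, 10, 0, 5), gel_rect = c(0, 10, 6, 20),
                   side = "left"))
  tr2 <- roiTriplesFromList(lst, pixelSize = 2)[[1]]
  expect_true(validObject(tr2))
  expect_equal(tr2@interfaceCol, 6L)
  expect_equal(tr2@wUm, 20)
  expect_equal(tr2@AUm2, 10 * 14 * 4)
})

test_that("geometry files round-trip through YAML", {
  g <- testGeometry(nGaps = 2L)
  cfg <- list(axis = "x",
              monolayer_cols = as.integer(g@monolayerCols),
              gel_cols = as.integer(g@gelCols),
              lumen_cols = lapply(g@lumenCols, as.integer),
              post_gaps = lapply(g@postGaps, as.integer),
              pixel_size_um = 2)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  rd <- readGeometry(path)
  expect_s4_class(rd$geometry, "DeviceGeometry")
  expect_equal(rd$geometry@monolayerCols, g@monolayerCols)
  expect_equal(rd$geometry@postGaps, g@postGaps)
  expect_equal(rd$config$pixel_size_um, 2)
})
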