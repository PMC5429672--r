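makeTrace <- function(iAveGel, iLumen = NULL, iY0 = NULL, dt = 30) {
  n <- length(iAveGel)
  if (is.null(iLumen)) iLumen <- rep(1000, n)
  if (is.null(iY0)) iY0 <- rep(0, n)
  new("IntensityTrace", times = (seq_len(n) - 1) * dt,
      iLumen = iLumen, iY0 = iY0, iAveGel = iAveGel,
      iFar = rep(0, n), t0Index = 1L)
}

test_that("initial slope is the OLS slope over the early window", {
  tt <- (0:9) * 30
  f <- fitInitialSlope(makeTrace(5 + 2 * tt))
  expect_equal(f$slope, 2)
  expect_equal(f$rSquared, 1)

  expect_equal(fitInitialSlope(makeTrace(rep(4, 10)))$slope, 0)
  expect_error(fitInitialSlope(makeTrace(c(1, 2))), "at least 3 frames")
})

test_that("the permeability formula does its unit conversion", {
  expect_equal(computePd(slope = 0, deltaI = 10, AUm2 = 1, wUm = 1), 0)
  # slope 1 /s, deltaI 1000, A 1e4 um^2, w 100 um -> 0.1 um/s = 1e-5 cm/s
  expect_equal(computePd(1, 1000, 1e4, 100), 1e-5)
  expect_error(computePd(1, 0, 1, 1), "deltaI")
  expect_error(computePd(1, -5, 1, 1), "deltaI")
  expect_error(computePd(1, 10, 0, 1), "geometry")
})

test_that("flux fit reduces to the literal formula when deltaI is constant", {
  tt <- (0:9) * 30
  trc <- makeTrace(2 + 0.5 * tt)
  triple <- buildRoiTriples(testGeometry(1L, nMono = 1L), pixelSize = 2)[[1]]
  lin <- fitPd(trc, triple, method = "linear")
  flx <- fitPd(trc, triple, method = "flux")
  expect_equal(flx$pd, lin$pd, tolerance = 1e-12)
  expect_equal(lin$pd, computePd(0.5, 1000, triple@AUm2, triple@wUm))
})

test_that("deltaI at t0 must be positive", {
  trc <- makeTrace(1:10, iLumen = rep(100, 10), iY0 = rep(100, 10))
  triple <- buildRoiTriples(testGeometry(1L, nMono = 1L), pixelSize = 2)[[1]]
  expect_error(fitPd(trc, triple), "not positive")
})

test_that("noise-free pipeline closes the loop on the true permeability", {
  cfg <- smallConfig(pdTrue = 3e-5, seed = 3)
  tr <- simulateDevice(cfg)
  m <- measureDevice(tr@noiseFreeStack, geometry = tr@geometry,
                     nPreFrames = cfg@nPreFrames)
  expect_true(all(is.na(m$error)))
  expect_true(all(abs(m$Pd_cm_s / 3e-5 - 1) < 0.05))
  # noisy pipeline at the same truth stays within 10%
  mn <- measureDevice(tr@stack, geometry = tr@geometry,
                      nPreFrames = cfg@nPreFrames)
  expect_lt(abs(median(mn$Pd_cm_s) / 3e-5 - 1), 0.1)
})

test_that("time-OLS slope matches the influx identity at low permeability", {
  # at low Pd the interface stays dilute and the early gel slope equals
  # Pd * w * deltaI / A_gel
  cfg <- smallConfig(pdTrue = 1e-6, seed = 4)
  tr <- simulateDevice(cfg)
  bg <- estimateBackground(tr@noiseFreeStack, cfg@nPreFrames)
  triple <- buildRoiTriples(tr@geometry, pixelSize = cfg@pixelSize)[[1]]
  trace <- extractTraces(tr@noiseFreeStack, triple, bg)
  fit <- fitInitialSlope(trace, fitWindow = 10L)
  deltaI <- trace@iLumen[trace@t0Index] - trace@iY0[trace@t0Index]
  expected <- (1e-6 * 1e4) * triple@wUm * deltaI / triple@AUm2
  expect_lt(abs(fit$slope / expected - 1), 0.05)
})

test_that("the estimate is invariant to intensity scaling", {
  cfg <- smallConfig(pdTrue = 2e-5, seed = 9)
  tr <- simulateDevice(cfg)
  m1 <- measureDevice(tr@stack, geometry = tr@geometry,
                      nPreFrames = cfg@nPreFrames)
  scaled <- ImageStack(frames(tr@stack) * 3.7, cfg@pixelSize,
                       cfg@frameInterval)
  m2 <- measureDevice(scaled, geometry = tr@geometry,
                      nPreFrames = cfg@nPreFrames)
  expect_equal(m2$Pd_cm_s, m1$Pd_cm_s, tolerance = 1e-10)
})

test_that("estimates agree between fast and slow diffusers", {
  # same membrane, gel diffusivity 4x apart: the estimator measures the
  # membrane, not the gel, because the gel box includes the interface
  pd <- 2e-5
  fast <- simulateDevice(smallConfig(pdTrue = pd, dGel = 1e-6, seed = 21))
  slow <- simulateDevice(smallConfig(pdTrue = pd, dGel = 2.45e-7, seed = 21))
  mf <- measureDevice(fast@noiseFreeStack, geometry = fast@geometry,
                      nPreFrames = 3L)
  ms <- measureDevice(slow@noiseFreeStack, geometry = slow@geometry,
                      nPreFrames = 3L)
  expect_lt(abs(median(mf$Pd_cm_s) / median(ms$Pd_cm_s) - 1), 0.1)
  expect_lt(abs(median(ms$Pd_cm_s) / pd - 1), 0.1)
})

test_that("doubling the gel-box depth barely moves the early-time estimate", {
  # premise of the check: the diffusion front stays inside both boxes over
  # the window, hence a slow (nanoparticle-like) diffuser
  cfg <- smallConfig(pdTrue = 2e-5, dGel = 2.45e-8, seed = 13)
  tr <- simulateDevice(cfg)
  m1 <- measureDevice(tr@noiseFreeStack, geometry = tr@geometry,
                      nPreFrames = 3L, gelDepth = 100)
  m2 <- measureDevice(tr@noiseFreeStack, geometry = tr@geometry,
                      nPreFrames = 3L, gelDepth = 200)
  expect_lt(max(abs(m2$Pd_cm_s / m1$Pd_cm_s - 1)), 0.05)
})

test_that("measureDevice is deterministic and fails per-triple, not globally", {
  cfg <- smallConfig(pdTrue = 2e-5, seed = 6)
  tr <- simulateDevice(cfg)
  m1 <- measureDevice(tr@stack, geometry = tr@geometry, nPreFrames = 3L)
  m2 <- measureDevice(tr@stack, geometry = tr@geometry, nPreFrames = 3L)
  expect_identical(m1, m2)
  expect_equal(nrow(m1), 4L)   # 2 gaps x 2 monolayers

  # a dead stack records an error per triple instead of aborting
  dead <- ImageStack(array(0, dim(frames(tr@stack))), cfg@pixelSize,
                     cfg@frameInterval)
  md <- measureDevice(dead, geometry = tr@geometry, nPreFrames = 3L)
  expect_equal(nrow(md), 4L)
  expect_true(all(!is.na(md$error)))
  expect_true(all(is.na(md$Pd_cm_s)))
})
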