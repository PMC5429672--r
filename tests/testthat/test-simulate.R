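test_that("Stokes-Einstein diffusivities are exact and proportional", {
  # direct evaluation with CODATA k_B
  expect_equal(stokesEinsteinD(1, temperature = 298, viscosity = 8.9e-4),
               4.905e-6, tolerance = 1e-3)
  d <- stokesEinsteinD(c(20, 40))
  expect_equal(d[1] / d[2], 2)  # D ~ 1/d_H
  expect_identical(stokesEinsteinD(50), stokesEinsteinD(50))
  expect_error(stokesEinsteinD(-1), "positive")
})

test_that("solver matches the closed-form Robin solution", {
  # semi-infinite setting: far boundary unfelt within the simulated time
  cfg <- simulationConfig(pdTrue = 3.5e-5, dGel = 1e-6, gelHalfWidth = 750,
                          nMonolayers = 1L, fillTime = 0, duration = 420,
                          nPreFrames = 1L, gridDx = 3)
  sol <- solveDiffusion(cfg)
  last <- nrow(sol$field)
  tEff <- sol$times[last] - cfg@nPreFrames * cfg@frameInterval
  ana <- robinConcentration(sol$y, tEff, 3.5e-5, 1e-6)
  relL2 <- sqrt(sum((sol$field[last, ] - ana)^2) / sum(ana^2))
  expect_lt(relL2, 0.01)
})

test_that("solver conserves mass and honors degenerate limits", {
  cfg <- smallConfig(pdTrue = 2e-5, seed = 1)
  sol <- solveDiffusion(cfg)
  mass <- rowSums(sol$field) * sol$dx
  expect_lt(max(abs(mass - sol$influx)) / max(mass), 1e-10)
  expect_true(min(sol$field) >= 0)

  # an impermeable membrane admits nothing
  sol0 <- solveDiffusion(smallConfig(pdTrue = 0))
  expect_true(all(sol0$field == 0))

  # long times equilibrate the gel to the lumen concentration
  cfgEq <- simulationConfig(pdTrue = 1e-4, dGel = 1e-6, gelHalfWidth = 40,
                            gridDx = 2, duration = 3600, nPreFrames = 1L,
                            nGaps = 1L, gapWidth = 40, lumenWidth = 20,
                            pixelSize = 2)
  solEq <- solveDiffusion(cfgEq)
  expect_equal(max(abs(solEq$field[nrow(solEq$field), ] - 1)), 0,
               tolerance = 0.02)
})

test_that("solution converges under grid refinement", {
  c1 <- smallConfig(pdTrue = 3e-5, gridDx = 5)
  c2 <- smallConfig(pdTrue = 3e-5, gridDx = 2.5)
  s1 <- solveDiffusion(c1)
  s2 <- solveDiffusion(c2)
  last <- nrow(s1$field)
  coarseOnFine <- approx(s2$y, s2$field[last, ], xout = s1$y)$y
  rel <- sqrt(sum((s1$field[last, ] - coarseOnFine)^2) /
                sum(coarseOnFine^2))
  expect_lt(rel, 0.005)
})

test_that("renderer is seed-reproducible with a faithful expectation", {
  cfg <- smallConfig(pdTrue = 2e-5, seed = 77)
  a <- simulateDevice(cfg)
  b <- simulateDevice(cfg)
  expect_identical(frames(a@stack), frames(b@stack))
  expect_false(identical(frames(a@stack),
                         frames(simulateDevice(smallConfig(pdTrue = 2e-5,
                                                           seed = 78))@stack)))

  # zero gain and zero read noise leave only the camera offset
  flat <- simulateDevice(smallConfig(photonGain = 0, readNoiseSd = 0))
  expect_true(all(frames(flat@stack) == flat@config@offset))

  # Monte-Carlo mean of noisy pixels approaches the noise-free expectation
  px <- frames(a@noiseFreeStack)[20, 10, 15]
  vals <- vapply(1:60, function(s) {
    cfg@seed <- as.integer(1000 + s)
    frames(simulateDevice(cfg)@stack)[20, 10, 15]
  }, numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - px), 4 * se + 0.5)  # 0.5 covers ADU rounding
})

test_that("the scheduled filling frame matches the rendered lumen", {
  cfg <- smallConfig(pdTrue = 1e-5, seed = 2)
  tr <- simulateDevice(cfg)
  lum <- permchip:::.lumenConc(cfg, permchip:::.simSchedule(cfg)$times)
  expect_equal(tr@trueT0Frame, which(lum >= cfg@cLumen)[1])
})

test_that("focal leaks render as localized interface plumes", {
  base <- smallConfig(pdTrue = 1e-5, duration = 720, seed = 31)
  same <- injectFocalLeak(base, gap = 1L, multiplier = 1)
  expect_identical(frames(simulateDevice(base)@stack),
                   frames(simulateDevice(same)@stack))

  leaky <- injectFocalLeak(base, gap = 1L, position = 0.45,
                           widthFraction = 0.1, multiplier = 10)
  tr <- simulateDevice(leaky)
  # interface profile of the leaking gap at 10 min: max/median ratio > 2
  geom <- tr@geometry
  triple <- buildRoiTriples(geom, pixelSize = base@pixelSize)[[1]]
  f10 <- tr@trueT0Frame + as.integer(600 / base@frameInterval)
  rows <- (triple@interfaceRows[1] + 1):triple@interfaceRows[2]
  prof <- frames(tr@noiseFreeStack)[f10, rows, triple@interfaceCol + 1] -
    base@offset
  expect_gt(max(prof) / median(prof), 2)

  # the plume follows the configured leak position
  shifted <- injectFocalLeak(base, gap = 1L, position = 0.1,
                             widthFraction = 0.1, multiplier = 10)
  trS <- simulateDevice(shifted)
  profS <- frames(trS@noiseFreeStack)[f10, rows, triple@interfaceCol + 1] -
    base@offset
  expect_lt(which.max(profS), which.max(prof))
  expect_error(injectFocalLeak(base, widthFraction = 1.2), "widthFraction")
})

test_that("simulation configs round-trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(pd_true = 2.5e-5, d_gel = 4e-7, duration = 900,
                        n_gaps = 2, seed = 9), path)
  cfg <- readSimulationConfig(path)
  expect_s4_class(cfg, "SimulationConfig")
  expect_equal(cfg@pdTrue, 2.5e-5)
  expect_equal(cfg@dGel, 4e-7)
  expect_equal(cfg@nGaps, 2L)
  expect_equal(cfg@seed, 9L)
  yaml::write_yaml(list(pd_true = 1e-5, bogus_key = 1), path)
  expect_error(readSimulationConfig(path), "unknown config keys")
})
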