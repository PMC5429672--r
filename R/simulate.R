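#' @useDynLib permchip, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx median rlnorm sd t.test var
NULL

#' Construct a simulation configuration
#'
#' Defaults describe the reference study conditions: a two-channel device with
#' a 1300-um-wide fibrin gel and three 120-um post gaps per monolayer, a
#' dextran-like tracer (D = 1e-6 cm^2/s) imaged every 30 s for 30 min after a
#' 60-s lumen fill, five pre-injection background frames, and EMCCD-like
#' counting noise. See the methods vignette for the rationale of each value.
#'
#' @param pdTrue true membrane permeability, cm/s (default 1e-5).
#' @param dGel gel diffusivity, cm^2/s (default 1e-6; see
#'   [stokesEinsteinD()] for particle sizes).
#' @param cLumen filled lumen concentration, arbitrary units.
#' @param gelHalfWidth half-width of the gel, um.
#' @param lumenWidth rendered lumen width, um.
#' @param nGaps post gaps per monolayer.
#' @param gapWidth gap width, um.
#' @param postWidth post width, um.
#' @param nMonolayers 1 or 2 seeded channels.
#' @param gridDx solver grid spacing, um.
#' @param pixelSize rendered pixel size, um/px.
#' @param frameInterval frame spacing, s.
#' @param duration acquisition time after injection, s.
#' @param fillTime lumen filling ramp, s.
#' @param nPreFrames pre-injection background frames.
#' @param photonGain counts per concentration unit.
#' @param readNoiseSd Gaussian read noise, counts.
#' @param offset camera offset, counts.
#' @param gapPdCv lognormal CV of per-gap-per-side true permeability.
#' @param leak \code{NULL} or a focal-leak spec; see [injectFocalLeak()].
#' @param seed integer RNG seed.
#' @return A [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(pdTrue = 3.5e-5, seed = 1)
#' cfg
#' @export
simulationConfig <- function(pdTrue = 1e-5, dGel = 1e-6, cLumen = 1,
                             gelHalfWidth = 650, lumenWidth = 120,
                             nGaps = 3L, gapWidth = 120, postWidth = 26,
                             nMonolayers = 2L, gridDx = 2, pixelSize = 2,
                             frameInterval = 30, duration = 1800,
                             fillTime = 60, nPreFrames = 5L,
                             photonGain = 2000, readNoiseSd = 10,
                             offset = 100, gapPdCv = 0, leak = NULL,
                             seed = 1L) {
  new("SimulationConfig",
      pdTrue = pdTrue, dGel = dGel, cLumen = cLumen,
      gelHalfWidth = gelHalfWidth, lumenWidth = lumenWidth,
      nGaps = as.integer(nGaps), gapWidth = gapWidth, postWidth = postWidth,
      nMonolayers = as.integer(nMonolayers), gridDx = gridDx,
      pixelSize = pixelSize, frameInterval = frameInterval,
      duration = duration, fillTime = fillTime,
      nPreFrames = as.integer(nPreFrames), photonGain = photonGain,
      readNoiseSd = readNoiseSd, offset = offset, gapPdCv = gapPdCv,
      leak = leak, seed = as.integer(seed))
}

#' Read a simulation configuration from YAML
#'
#' Keys mirror the arguments of [simulationConfig()] in snake_case
#' (e.g. \code{pd_true}, \code{d_gel}, \code{frame_interval}).
#'
#' @param path YAML file path.
#' @return A [SimulationConfig-class].
#' @export
readSimulationConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  toCamel <- function(x) gsub("_(\\w)", "\\U\\1", x, perl = TRUE)
  names(cfg) <- toCamel(names(cfg))
  known <- names(formals(simulationConfig))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(simulationConfig, cfg)
}

#' Stokes-Einstein diffusivity of a spherical particle
#'
#' \eqn{D = k_B T / (3 \pi \eta d_H)}, converted to cm^2/s. Used to
#' parameterise simulations of nanoparticles of different hydrodynamic
#' diameters; defaults are cell-culture conditions (37 C, water).
#'
#' @param dH hydrodynamic diameter, nm.
#' @param temperature absolute temperature, K (default 310).
#' @param viscosity solvent dynamic viscosity, Pa s (default 6.9e-4,
#'   water at 37 C).
#' @return Diffusivity in cm^2/s.
#' @examples
#' stokesEinsteinD(1, temperature = 298, viscosity = 8.9e-4)  # ~4.9e-6
#' stokesEinsteinD(c(20, 40, 100, 200))
#' @export
stokesEinsteinD <- function(dH, temperature = 310, viscosity = 6.9e-4) {
  if (any(dH <= 0) || temperature <= 0 || viscosity <= 0)
    stop("all Stokes-Einstein inputs must be positive")
  kB <- 1.380649e-23  # J/K
  dM <- dH * 1e-9
  dM2s <- kB * temperature / (3 * pi * viscosity * dM)  # m^2/s
  dM2s * 1e4                                            # cm^2/s
}

#' Closed-form Robin-boundary diffusion profile (analytic oracle)
#'
#' Concentration in a semi-infinite gel behind a membrane of permeability
#' \code{pd} when the lumen steps to \code{c0} at t = 0 (surface-resistance
#' solution):
#' \deqn{C(y,t) = c_0\,[\mathrm{erfc}(\frac{y}{2\sqrt{Dt}})
#'   - e^{hy + h^2 D t}\,\mathrm{erfc}(\frac{y}{2\sqrt{Dt}} + h\sqrt{Dt})]}
#' with \eqn{h = P_d / D}. Evaluated with the scaled complementary error
#' function for numerical stability at large arguments. This is the
#' independent reference the finite-difference solver is validated against.
#'
#' @param y depth into the gel, um (vector).
#' @param t time since the concentration step, s.
#' @param pd membrane permeability, cm/s.
#' @param dGel gel diffusivity, cm^2/s.
#' @param c0 lumen concentration.
#' @return Concentrations at \code{y}.
#' @export
robinConcentration <- function(y, t, pd, dGel, c0 = 1) {
  if (t <= 0) return(rep(0, length(y)))
  D <- dGel * 1e8                       # um^2/s
  h <- (pd * 1e4) / D                   # 1/um
  s <- 2 * sqrt(D * t)
  z1 <- y / s
  z2 <- z1 + h * sqrt(D * t)
  term2 <- exp(h * y + h^2 * D * t - z2^2) * pracma::erfcx(z2)
  c0 * (pracma::erfc(z1) - term2)
}

# frame times (s from acquisition start) and solver schedule for a config
.simSchedule <- function(config) {
  dtF <- config@frameInterval
  nPre <- config@nPreFrames
  nPost <- as.integer(round(config@duration / dtF)) + 1L
  nFrames <- nPre + nPost
  times <- (seq_len(nFrames) - 1L) * dtF
  tInject <- nPre * dtF
  list(times = times, tInject = tInject, nFrames = nFrames,
       t0Frame = nPre + as.integer(ceiling(config@fillTime / dtF)) + 1L)
}

# lumen concentration at acquisition time t (vectorised)
.lumenConc <- function(config, times) {
  sch <- .simSchedule(config)
  tp <- times - sch$tInject
  out <- ifelse(tp <= 0, 0,
                ifelse(config@fillTime <= 0 | tp >= config@fillTime,
                       config@cLumen, config@cLumen * tp / config@fillTime))
  as.numeric(out)
}

#' Solve the membrane-gel diffusion problem for one gap
#'
#' Finite-volume solution of 1-D diffusion across the full gel width, with a
#' Robin membrane-flux condition \eqn{J = P_d (C_{lumen}(t) - C)} at each
#' seeded end (zero-flux at an unseeded end). The explicit scheme sub-steps
#' internally to satisfy the stability bound \eqn{D\,\Delta t / \Delta x^2
#' \le 0.45}. The lumen ramps linearly over \code{fillTime} and is otherwise
#' a fixed-concentration reservoir.
#'
#' @param config a [SimulationConfig-class].
#' @param pdLeft,pdRight membrane permeabilities (cm/s) at the two gel ends;
#'   defaults come from \code{config}; \code{NA} marks an unseeded (zero-flux)
#'   end.
#' @return A list: \code{field} (frames x cells concentration matrix),
#'   \code{y} (cell-centre depths, um), \code{times} (frame times, s),
#'   \code{lumen} (lumen concentration per frame), \code{influx} (cumulative
#'   membrane influx per frame, per unit monolayer area, um x conc) and
#'   \code{dx}.
#' @examples
#' cfg <- simulationConfig(duration = 300, gelHalfWidth = 200, gridDx = 5)
#' sol <- solveDiffusion(cfg)
#' dim(sol$field)
#' @export
solveDiffusion <- function(config,
                           pdLeft = config@pdTrue,
                           pdRight = if (config@nMonolayers == 2L)
                             config@pdTrue else NA) {
  stopifnot(is(config, "SimulationConfig"))
  D <- config@dGel * 1e8                       # um^2/s
  dx <- config@gridDx
  n <- as.integer(round(2 * config@gelHalfWidth / dx))
  if (n < 3L) stop("grid too coarse: fewer than 3 cells across the gel")
  sch <- .simSchedule(config)
  dtStab <- 0.45 * dx^2 / D
  nsub <- max(1L, as.integer(ceiling(config@frameInterval / dtStab)))
  dt <- config@frameInterval / nsub
  pL <- if (is.na(pdLeft)) -1 else pdLeft * 1e4     # um/s
  pR <- if (is.na(pdRight)) -1 else pdRight * 1e4
  field <- matrix(0, sch$nFrames, n)
  influx <- numeric(sch$nFrames)
  C <- numeric(n)
  flx <- 0
  for (f in 2:sch$nFrames) {
    st <- .diffusionAdvance(C, D, dx, dt, nsub,
                            sch$times[f - 1L] - sch$tInject,
                            pL, pR, config@cLumen, config@fillTime, flx)
    C <- st$C
    flx <- st$influx
    field[f, ] <- C
    influx[f] <- flx
  }
  list(field = field, y = (seq_len(n) - 0.5) * dx, times = sch$times,
       lumen = .lumenConc(config, sch$times), influx = influx, dx = dx)
}

#' Add a focal leak to a simulation configuration
#'
#' Returns a configuration whose membrane permeability is
#' \code{pdTrue * multiplier} over a sub-segment of one post gap (on the
#' left/first monolayer) and unchanged elsewhere. The simulator then solves
#' the leak rows as independent 1-D columns (quasi-2-D, valid at early
#' times).
#'
#' @param config a [SimulationConfig-class].
#' @param gap 1-based index of the affected post gap.
#' @param position fractional position of the leak start within the gap.
#' @param widthFraction leaking fraction of the gap width, in (0, 1).
#' @param multiplier permeability multiplier (>= 1).
#' @return The modified [SimulationConfig-class].
#' @export
injectFocalLeak <- function(config, gap = 1L, position = 0.45,
                            widthFraction = 0.1, multiplier = 10) {
  stopifnot(is(config, "SimulationConfig"))
  config@leak <- list(gap = as.integer(gap), position = position,
                      widthFraction = widthFraction, multiplier = multiplier)
  validObject(config)
  config
}

# pixel-level layout of the rendered device
.deviceLayout <- function(config) {
  px <- config@pixelSize
  lumenPx <- max(1L, as.integer(round(config@lumenWidth / px)))
  gelPx <- as.integer(round(2 * config@gelHalfWidth / px))
  gapPx <- max(1L, as.integer(round(config@gapWidth / px)))
  postPx <- as.integer(round(config@postWidth / px))
  nG <- config@nGaps
  H <- nG * gapPx + (nG + 1L) * postPx
  gaps <- lapply(seq_len(nG), function(g) {
    r0 <- postPx * g + gapPx * (g - 1L)
    c(r0, r0 + gapPx)                              # 0-based half-open rows
  })
  if (config@nMonolayers == 2L) {
    mono <- c(lumenPx, lumenPx + 1L + gelPx)
    gelCols <- c(lumenPx + 1L, lumenPx + 1L + gelPx)
    lumen <- list(c(0L, lumenPx),
                  c(lumenPx + 2L + gelPx, lumenPx + 2L + gelPx + lumenPx))
    W <- 2L * lumenPx + 2L + gelPx
  } else {
    mono <- lumenPx
    gelCols <- c(lumenPx + 1L, lumenPx + 1L + gelPx)
    lumen <- list(c(0L, lumenPx))
    W <- lumenPx + 1L + gelPx
  }
  list(H = H, W = W, gaps = gaps, gapPx = gapPx, postPx = postPx,
       gelCols = gelCols, mono = mono, lumen = lumen, gelPx = gelPx)
}

# realised per-gap-per-side true permeabilities (lognormal heterogeneity,
# mean preserved); uses the current RNG stream
.drawGapPd <- function(config) {
  nS <- config@nMonolayers
  m <- matrix(config@pdTrue, config@nGaps, nS,
              dimnames = list(NULL, c("left", "right")[seq_len(nS)]))
  if (config@gapPdCv > 0) {
    sdlog <- sqrt(log(1 + config@gapPdCv^2))
    m[] <- rlnorm(length(m), log(config@pdTrue) - sdlog^2 / 2, sdlog)
  }
  m
}

#' Render a synthetic acquisition from solved concentration fields
#'
#' Broadcasts per-gap 1-D concentration profiles across the device layout
#' (background concentration 0 behind posts and in the monolayer line),
#' converts concentration to expected counts
#' \eqn{E = \mathrm{gain}\,C + \mathrm{offset}}, and draws observed counts as
#' \eqn{\mathrm{Pois}(E - \mathrm{offset}) + \mathrm{offset} +
#' \mathcal{N}(0, \sigma_{read})}, rounded to integer ADU and clipped at 0.
#' Seed-reproducible via \code{config@seed}.
#'
#' Most users call [simulateDevice()], which solves and renders in one step.
#'
#' @param fields list of solution lists (one per gap, see [solveDiffusion()]);
#'   optionally with an extra \code{leak} element for the leak rows.
#' @param config the generating [SimulationConfig-class].
#' @param gapPd realised per-gap permeability matrix (for the truth record).
#' @param reseed seed the RNG with \code{config@seed} before drawing noise
#'   (default TRUE; [simulateDevice()] disables it to keep one seeded stream
#'   across the heterogeneity draw and the render).
#' @return A [SyntheticTruth-class].
#' @export
renderStack <- function(fields, config, gapPd, reseed = TRUE) {
  lay <- .deviceLayout(config)
  sch <- .simSchedule(config)
  lum <- .lumenConc(config, sch$times)
  px <- config@pixelSize
  pixCentres <- (seq_len(lay$gelPx) - 0.5) * px
  # frames x gel-pixel concentration matrix for one solution
  fieldPx <- function(sol) {
    if (isTRUE(all.equal(sol$y, pixCentres, tolerance = 1e-9)))
      sol$field
    else t(apply(sol$field, 1L, function(row)
      approx(sol$y, row, xout = pixCentres, rule = 2)$y))
  }
  leakRows <- .leakRows(config, lay)
  nf <- sch$nFrames
  conc <- array(0, c(nf, lay$H, lay$W))
  gelIdx <- (lay$gelCols[1L] + 1L):lay$gelCols[2L]
  for (lu in lay$lumen)
    conc[, , (lu[1L] + 1L):lu[2L]] <- lum      # recycles over the frame dim
  for (g in seq_along(lay$gaps)) {
    rows <- (lay$gaps[[g]][1L] + 1L):lay$gaps[[g]][2L]
    fp <- fieldPx(fields[[g]])
    conc[, rows, gelIdx] <- fp[, rep(seq_len(lay$gelPx), each = length(rows))]
  }
  if (!is.null(leakRows)) {
    fp <- fieldPx(fields$leak)
    conc[, leakRows, gelIdx] <-
      fp[, rep(seq_len(lay$gelPx), each = length(leakRows))]
  }
  gain <- config@photonGain
  expected <- gain * conc + config@offset
  if (reseed) set.seed(config@seed)
  noisy <- array(.cameraNoise(as.numeric(conc), gain, config@offset,
                              config@readNoiseSd), dim(conc))
  lab <- sprintf("synthetic Pd=%.3g cm/s seed=%d", config@pdTrue, config@seed)
  geom <- deviceGeometry(monolayerCols = lay$mono, gelCols = lay$gelCols,
                         lumenCols = lay$lumen, postGaps = lay$gaps)
  new("SyntheticTruth",
      config = config,
      stack = ImageStack(noisy, px, config@frameInterval, lab),
      noiseFreeStack = ImageStack(expected, px, config@frameInterval,
                                  paste(lab, "(noise-free)")),
      geometry = geom,
      truePd = config@pdTrue,
      gapPd = gapPd,
      trueT0Frame = sch$t0Frame)
}

# 1-based leak row indices, or NULL
.leakRows <- function(config, lay) {
  lk <- config@leak
  if (is.null(lk)) return(NULL)
  gap <- lay$gaps[[lk$gap]]
  gapPx <- gap[2L] - gap[1L]
  wid <- max(1L, as.integer(round(lk$widthFraction * gapPx)))
  r0 <- gap[1L] + as.integer(round(lk$position * gapPx))
  r0 <- min(r0, gap[2L] - wid)
  (r0 + 1L):(r0 + wid)
}

#' Simulate a complete synthetic experiment
#'
#' Draws per-gap true permeabilities (if \code{gapPdCv > 0}), solves the
#' membrane-gel diffusion problem per gap (plus the leak sub-segment when a
#' focal leak is configured), and renders the noisy and noise-free stacks.
#'
#' @param config a [SimulationConfig-class].
#' @param fields optional pre-solved fields from a previous call with the
#'   same physics (skips the solver; used by recovery harnesses that vary
#'   only the noise seed).
#' @return A [SyntheticTruth-class].
#' @examples
#' cfg <- simulationConfig(duration = 300, gelHalfWidth = 200,
#'                         lumenWidth = 40, gapWidth = 40, nGaps = 2L,
#'                         gridDx = 5, pixelSize = 5, seed = 7)
#' tr <- simulateDevice(cfg)
#' tr
#' @export
simulateDevice <- function(config, fields = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(config@seed)
  gapPd <- .drawGapPd(config)
  if (is.null(fields)) fields <- .solveFields(config, gapPd)
  renderStack(fields, config, gapPd, reseed = FALSE)
}

# solve every distinct gap (and the leak segment); returns list indexable by
# gap number plus optional $leak
.solveFields <- function(config, gapPd) {
  pdR <- function(g) if (config@nMonolayers == 2L) gapPd[g, 2L] else NA
  fields <- vector("list", config@nGaps)
  solved <- list()
  for (g in seq_len(config@nGaps)) {
    key <- sprintf("%.12g|%.12g", gapPd[g, 1L],
                   if (is.na(pdR(g))) -1 else pdR(g))
    if (is.null(solved[[key]]))
      solved[[key]] <- solveDiffusion(config, pdLeft = gapPd[g, 1L],
                                      pdRight = pdR(g))
    fields[[g]] <- solved[[key]]
  }
  if (!is.null(config@leak)) {
    g <- config@leak$gap
    fields$leak <- solveDiffusion(config,
                                  pdLeft = gapPd[g, 1L] *
                                    config@leak$multiplier,
                                  pdRight = pdR(g))
  }
  fields
}

#' Simulate several devices under one condition
#'
#' Runs [simulateDevice()] and [measureDevice()] for \code{nDevices}
#' independent devices (seeds \code{seed, seed+1, ...}) and stacks the
#' per-triple measurements, labelled with condition and probe.
#'
#' @param config a [SimulationConfig-class]; its \code{gapPdCv} supplies the
#'   biological between-gap spread.
#' @param nDevices number of devices.
#' @param condition,probe labels carried into the output.
#' @param seed base seed; device i uses \code{seed + i - 1}.
#' @param ... passed to [measureDevice()].
#' @return data.frame of measurements with \code{device}, \code{condition}
#'   and \code{probe} columns.
#' @export
simulateCondition <- function(config, nDevices, condition = "condition",
                              probe = "probe", seed = config@seed, ...) {
  out <- vector("list", nDevices)
  for (i in seq_len(nDevices)) {
    cfg <- config
    cfg@seed <- as.integer(seed + i - 1L)
    tr <- simulateDevice(cfg)
    m <- measureDevice(tr@stack, geometry = tr@geometry,
                       nPreFrames = cfg@nPreFrames, ...)
    m$device <- i
    m$condition <- condition
    m$probe <- probe
    out[[i]] <- m
  }
  do.call(rbind, out)
}

#' Parameter-recovery harness
#'
#' Repeatedly simulates a device at known true permeability with fresh noise
#' seeds, runs the full measurement pipeline, and summarises how well the
#' estimator recovers the truth.
#'
#' @param config a [SimulationConfig-class] (its \code{pdTrue} is the truth).
#' @param reps number of independent noise realisations.
#' @param seed base seed.
#' @param ... passed to [measureDevice()].
#' @return A list: \code{perRep} data.frame (seed, median recovered Pd),
#'   \code{medianPd}, \code{relBias} (signed, of the median),
#'   \code{rmse} over per-rep medians, and \code{truePd}.
#' @export
recoverPd <- function(config, reps = 20L, seed = config@seed, ...) {
  fields <- NULL
  if (config@gapPdCv == 0)       # physics identical across reps: solve once
    fields <- .solveFields(config, .drawGapPd(config))
  med <- numeric(reps)
  for (i in seq_len(reps)) {
    cfg <- config
    cfg@seed <- as.integer(seed + i - 1L)
    tr <- simulateDevice(cfg, fields = fields)
    m <- measureDevice(tr@stack, geometry = tr@geometry,
                       nPreFrames = cfg@nPreFrames, ...)
    ok <- !m$focal_leak & is.na(m$error)
    med[i] <- median(m$Pd_cm_s[ok])
  }
  mp <- median(med)
  list(perRep = data.frame(seed = seed + seq_len(reps) - 1L, medianPd = med),
       medianPd = mp,
       relBias = (mp - config@pdTrue) / config@pdTrue,
       rmse = sqrt(mean((med - config@pdTrue)^2)),
       truePd = config@pdTrue)
}
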