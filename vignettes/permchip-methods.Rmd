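---
title: "Measuring endothelial permeability on a chip: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring endothelial permeability on a chip: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permchip)
```

# The measurement

A two-channel microfluidic device holds a central fibrin gel between one or
two endothelialised media channels. The endothelial monolayer sits at the
gel–lumen interface, exposed between supporting posts. After a fluorescent
tracer fills the lumen, it crosses the monolayer and diffuses into the gel;
the fluorescence intensity $I$ is proportional to tracer concentration, so
the rising gel signal encodes the barrier's diffusional permeability
coefficient $P_d$ (cm/s).

Three regions of interest yield one data point per post gap per monolayer:

* a **lumen box** inside the channel, mean intensity $I_{lumen}$;
* a one-pixel **interface line** in the gel, flush against the monolayer,
  mean intensity $I_{y=0}$ — a proxy for the gel-side boundary
  concentration;
* a **gel box** whose monolayer-side edge is the interface line, mean
  intensity $I_{ave,gel}$, physical area $A_{gel}$, spanning monolayer width
  $w$.

Mass balance over the gel box (channel height cancels between flux area and
box volume) gives the working identity

$$P_d \;=\; \frac{A_{gel}\,\dfrac{dI_{ave,gel}}{dt}}
                 {w\,\bigl(I_{lumen}-I_{y=0}\bigr)_{t=0}},$$

with $t=0$ the frame at which the lumen has completely filled. The identity
holds *exactly at* $t=0$; any practical estimator must average over a finite
window of frames, and two effects then matter:

1. **Interface build-up.** The gel-side boundary concentration rises during
   the window, so the instantaneous influx
   $J(t) \propto \Delta I(t) = I_{lumen}(t)-I_{y=0}(t)$ falls below its
   $t=0$ value. For a leaky barrier probed with a slow diffuser the boundary
   layer saturates within minutes, and a plain OLS slope divided by
   $\Delta I(t_0)$ underestimates $P_d$ substantially.
2. **Out-flux through the far edge.** Whatever tracer diffuses past the far
   edge of the gel box leaves the control volume uncounted. With a
   dextran-like diffusivity of $10^{-6}\,\mathrm{cm^2/s}$ the diffusion
   front travels $\sqrt{Dt}\approx170$ µm in five minutes, so shallow boxes
   leak measurable mass within a standard fit window.

`permchip` addresses both structurally:

* **Flux-matched fit (default).** Since
  $dI_{ave,gel}/dt = (w/A_{gel})\,P_d\,\Delta I(t)$ frame by frame while the
  box balance is closed, the package regresses $I_{ave,gel}(t_k)$ on the
  cumulative trapezoid integral $\int_{t_0}^{t_k}\Delta I\,dt$ of the
  *measured* intensity difference; the slope times $A_{gel}/w$ is $P_d$.
  When $\Delta I$ is constant this reduces algebraically to the identity
  above, so it is a strict generalisation, not a different estimator.
  The literal early-window OLS form remains available
  (`fitPd(..., method = "linear")`) and agrees with the default whenever the
  early-time premise actually holds (dilute interface, contained front).
* **Closed control volume (default ROI depth).** `buildRoiTriples()` extends
  the gel box to the gel midline, where the net diffusive flux vanishes by
  symmetry when both channels are seeded (or to the far gel wall with one
  channel). The box then captures *all* tracer that crossed the monolayer,
  and the estimator stays correct at any permeability and any diffusivity —
  which is also why the box must include the interface line: slow diffusers
  pile up right behind the membrane, and a box that excluded that
  accumulation would miss their mass. For shallower, user-set boxes a
  **front guard** truncates the fit window at the first frame where the far
  edge of the box carries signal above $2\%$ of the interface intensity (or
  above three standard deviations of its pre-injection noise floor),
  keeping at least three frames and reporting the truncation
  (`front_reached`).

$t=0$ is detected from the lumen trace: the plateau level is the median of
the top quartile of $I_{lumen}$, and $t_0$ is the first frame reaching 95%
of it (`plateauFraction`, overridable by an explicit frame). A
non-positive $\Delta I(t_0)$ — saturated interface or mis-detected filling —
is an error for that data point, never silently clipped; `measureDevice()`
records the error and continues with the remaining triples.

## Background subtraction

The camera background is estimated from frames acquired before injection
(`estimateBackground()`; default 5 frames, scalar mode; a per-pixel mode is
offered for structured offsets, as it is unknown which variant a given lab
uses). The subtraction acts on the ROI **mean**, and the mean is clipped at
zero. Clipping individual pixels instead would rectify camera noise: wherever
per-pixel SNR is below one — routine in the gel box at low permeability —
$E[\max(X,0)]$ compresses intensity increments and systematically shrinks the
fitted slope (we measured roughly a 20% loss of recovered $P_d$ at
$10^{-6}$ cm/s before adopting the mean-level rule).

## Focal-leak QC

A focal leak — a localized defect in the monolayer — produces a bright plume
at the interface. For each data point the spatial intensity profile along
the interface line is averaged over the fit window after $t_0$; the leak
score is $(\max-\mathrm{median})/\mathrm{median}$ and a measurement is
flagged above a threshold of 1.0. A non-positive median yields an infinite
score and a flag. Flagged points stay in the per-measurement output but are
excluded from aggregation by default. The rule is an operational criterion
validated on simulated leaks (10× local permeability over 10% of a gap is
flagged essentially always at reference noise, with false positives at or
near zero); it is deliberately simple and tunable rather than a replica of
any particular published leak definition. Fits with $r^2$ below 0.9 raise a
QC *warning* flag but are not auto-excluded — only leaks exclude.

# The synthetic-data generator

The generator is the ground-truth engine for every recovery test: it
forward-simulates the physics, then renders camera frames.

**Transport model.** One dimension per post gap, along the diffusion axis:
the lumen is a fixed-concentration reservoir (microlitre feed versus
nanolitre gel volume justifies ignoring depletion) that ramps linearly to
$C_{lumen}$ over `fillTime`; the membrane imposes the Robin flux
$J = P_d\,(C_{lumen}(t) - C(0^+,t))$; the gel interior is pure diffusion
with coefficient $D_{gel}$; the opposite end is a second membrane (two
seeded channels) or a zero-flux wall. Rows behind posts carry no tracer, and
each gap is solved independently (quasi-2-D), which is accurate at the early
times the estimator uses. Lateral diffusion along the gap, convection and
photobleaching are not modelled.

**Solver.** Cell-centred finite volumes with an explicit update, sub-stepped
internally to the stability bound $D\,\Delta t/\Delta x^2 \le 0.45$; the
inner loop is compiled (Rcpp). The solver tracks the cumulative membrane
influx so mass conservation is checkable exactly; negative concentrations
are clipped at zero (they cannot arise beyond round-off under the stability
bound). The independent correctness reference is the closed-form
surface-resistance solution for a semi-infinite gel,

$$C(y,t) = C_0\Bigl[\operatorname{erfc}\tfrac{y}{2\sqrt{Dt}}
  - e^{hy+h^2Dt}\operatorname{erfc}\bigl(\tfrac{y}{2\sqrt{Dt}}+h\sqrt{Dt}\bigr)\Bigr],
  \qquad h = P_d/D,$$

exposed as `robinConcentration()` and evaluated with the scaled
complementary error function so the exponentially growing factor never
overflows.

**Camera model.** Expected counts are $\mathrm{gain}\cdot C +
\mathrm{offset}$; observed counts are
$\mathrm{Pois}(\mathrm{gain}\cdot C) + \mathrm{offset} +
\mathcal{N}(0,\sigma_{read})$, rounded to integer ADU and clipped at zero,
drawn in one compiled pass from R's seeded RNG. The EMCCD excess-noise
factor is not modelled separately; raising `readNoiseSd` emulates it. This
is sufficient for SNR-dependent recovery behaviour, which is what the tests
exercise.

**Biological heterogeneity.** Real devices show large spread between data
points. `gapPdCv` draws each gap-and-side's true permeability from a
lognormal centred on `pdTrue` (mean-preserving). The base configuration uses
0; condition-level simulations (treatment comparisons, TNR, size series) use
0.25, chosen once as the point-to-point coefficient of variation consistent
with the SEM bars typical of such assays at plausible $n$.

## Reference study conditions (defaults) and why

| parameter | default | rationale |
|---|---|---|
| `gelHalfWidth` | 650 µm | half of a ~1.3-mm central gel typical of two-channel devices; no dimensions are published for the reference device, so this is a declared choice |
| `gapWidth` / `postWidth` / `nGaps` | 120 / 26 / 3 | post-gap scale of such devices; three gaps × two monolayers = six data points per device |
| `lumenWidth` | 120 µm | rendered channel band; only its ROI-margin strip enters the analysis |
| `dGel` | 1e-6 cm²/s | free-solution diffusivity of ~10-kDa dextran; fibrin pores are micrometres wide, so gel hindrance is negligible for the probes considered |
| `frameInterval` / `duration` | 30 s / 1800 s | 30-min acquisition at 30-s intervals (nanoparticle runs use 2700 s) |
| `fillTime` | 60 s | lumen filling ramp; puts $t_0$ two frames after injection |
| `nPreFrames` | 5 | background frames before injection |
| `photonGain` / `readNoiseSd` / `offset` | 2000 / 10 / 100 counts | EMCCD-like: a filled lumen sits near 2100 ADU with shot-noise-dominated statistics |
| `gridDx` = `pixelSize` | 2 µm | solver cells coincide with rendered pixels, avoiding interpolation in the default path |
| `pdTrue` | 1e-5 cm/s | mid-range of the experimentally relevant $10^{-6}$–$10^{-4}$ cm/s |
| `fitWindow` | 10 frames | 5 min: long enough to average noise, still early-time for the default geometry |
| `gelDepth` | to midline | closes the ROI mass balance (see above); a 100-µm-deep box loses the diffusion front within one frame interval at dextran-like $D$ |
| `leakThreshold` | 1.0 | interface profiles are flat to a few percent without a leak and reach scores of several with one |

Stokes–Einstein ($D = k_BT/3\pi\eta d_H$, `stokesEinsteinD()`) parameterises
nanoparticle size series; its defaults are culture conditions (310 K, water
at 37 °C, $\eta = 6.9\times10^{-4}$ Pa·s).

# Numerical and design choices

* **Coordinates.** Pixel coordinates are 0-based with half-open rectangles
  `c(row0, row1, col0, col1)` in all configs and classes, so lengths and
  areas are plain differences; 1-based indexing is confined to internal R
  subsetting. Frame indices (e.g. `t0_index`) are 1-based, as R users
  expect.
* **Calibration** (µm/px, s/frame) comes from arguments or config files,
  never from TIFF metadata, to stay independent of TIFF dialects.
* **TIFF round-trips.** Integer stacks are written as 16-bit and round-trip
  bit-exactly; non-integer stacks (e.g. noise-free expectations) are written
  as 32-bit float normalised by a power-of-two scale carried in a JSON
  sidecar, exact to single precision.
* **ΔI is per-triple**, taken from the same data point's lumen box and
  interface line rather than channel-wide averages, so local barrier
  heterogeneity stays local to its data point.
* **Student's t-test** means the classic pooled-variance two-tailed form
  (Welch available via `welch = TRUE`); no multiple-testing correction is
  applied, matching per-pair testing at $\alpha = 0.05$. Two groups with
  zero variance and equal values return $t=0,\,p=1$ rather than erroring.
* **$n=1$ groups** report SEM 0 with a warning instead of failing, to keep
  batch summaries alive.
* **TNR uncertainty** is propagated from the two SEMs,
  $\sigma_{TNR} = TNR\sqrt{(s_t/\mu_t)^2+(s_n/\mu_n)^2}$ — an addition of
  this package, reported alongside the ratio.
* **Determinism.** Every stochastic component flows from one integer seed;
  the heterogeneity draw and the render consume a single seeded stream, so a
  simulated device is reproducible end to end and a leak with multiplier 1
  renders bit-identically to the leak-free device.
* **Degenerate inputs.** $P_d = 0$ yields an identically zero gel; an
  all-zero or background-equal stack fails lumen-fill detection with a clear
  error recorded per data point; regions outside the frame, empty gap lists,
  overlapping gaps and over-deep gel boxes are rejected at validity-check
  time.

# Problem sizes in the tests and acceptance script

Unit tests run on shrunken devices (400-µm gel, 5-µm grid, 10-min
acquisitions) so one solve takes ~0.1 s; the physics is unchanged. The
acceptance script and the end-to-end test file use the reference conditions:
solver-versus-oracle on a 2-mm semi-infinite gel; recovery with 20 noise
seeds at each of $10^{-6}$, $2.47\times10^{-5}$, $3.5\times10^{-5}$ and
$10^{-4}$ cm/s; leak QC on 50 leak and 50 intact single-gap devices; a TNR
pair with 10 devices per arm (120 gap draws keep the lognormal sampling
error of the ratio near 5%); and ten repetitions of a four-size,
10-points-per-size nanoparticle series at constant true permeability
(900-s acquisitions — the fit uses only the first five minutes, so the
tail adds nothing but runtime).

# What passing tests do and do not show

The generator emulates diffusion physics, filling dynamics, camera noise,
post geometry, focal leaks and between-point biological spread. It does
**not** emulate convective flow, photobleaching, flat-field structure,
monolayer thickness, lateral diffusion behind posts, fibrin-pore hindrance
of very large particles, or protein-corona kinetics (corona growth enters
only through the hydrodynamic diameter handed to Stokes–Einstein). Recovery
within a few percent on synthetic data therefore validates the *estimator
and its implementation* — ROI arithmetic, filling detection, windowing,
units — under the stated transport model, not the model's fidelity to any
particular device. On real images, pressure imbalances between channels
(convection), bleaching, and ROI misplacement remain the user's
responsibility; the per-measurement QC columns (`r2`, `leak_score`,
`front_reached`, `t0_index`) are the designed entry points for catching
them.
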