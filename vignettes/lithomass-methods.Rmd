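---
title: "Measuring coccolith CaCO3 content by opto-electrochemical dissolution: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring coccolith CaCO3 content by opto-electrochemical dissolution: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lithomass)
```

## The measurement principle

A coccolith is a micron-scale plate of biogenic calcite, typically 2--10 um
long and 0.2--2 um thick, carrying picograms of CaCO3 -- far too little to
weigh. `lithomass` implements an image-based "acid titration": a fibre
microelectrode (7 um diameter carbon fibre) oxidises a dissolved acid
precursor (hydroquinone, H2BQ -- 2e- -> BQ + 2H+), creating a locally acidic
micro-environment; a nearby coccolith dissolves while being imaged by
dark-field microscopy, where light-scattering calcite is bright on a dark
background.

Two facts make the movie quantitative:

1. **The dissolution is surface-reaction limited.** For calcite,
   flux = $k_1 [\mathrm{H^+}]$ with $k_1 \approx 0.043$ cm/s. Whether the
   rate of an isolated particle is set by this interfacial reaction or by
   proton transport depends on particle size; the crossover radius is
   $D_{\mathrm{H^+}}/k_1 \approx 22$ um. Coccoliths (effective radius about
   5 um) sit well inside the surface-limited regime even with a surface
   roughness factor of 4--8, so the proton concentration at the lith equals
   the local solution value and the linear retreat rate $v$ is *constant in
   time* for a given position and electrolyte.
2. **Dissolution time encodes thickness.** Because the surface retreats at
   constant speed $v$ everywhere, the time $t(i,j)$ a pixel takes to clear is
   $h(i,j)/v$, with $h$ the local calcite thickness. Measuring $v$ on the
   same lith (from the initial decay of its effective radius) internally
   calibrates every rate-affecting factor -- roughness, electrode distance,
   inhibitors -- and converting $t(i,j) \cdot v$ pixel-by-pixel gives a 3D
   thickness map, hence volume and (at calcite density 2.71 pg/um^3) mass.

The pipeline is: segment the movie into per-frame masks, track
$r_\mathrm{eff}(t) = \sqrt{A(t)/\pi}$, fit its two-regime decay, build the
per-pixel dissolution-time map, multiply by $v$, integrate.

## Segmentation choices

**Frozen background-referenced threshold.** The threshold is estimated once
on the pre-dissolution frame and frozen: re-estimating per frame becomes
ill-posed as the foreground vanishes, and the dissolution end point (first
empty mask) must be well defined. Rather than Otsu's mid-way split, the
frozen threshold is set just above the dark background --
`mean(bg) + max(2.5 sd(bg), 0.02 (mean(fg) - mean(bg)))`, with the
background/foreground split initialized by Otsu. In dark field, *any* signal
above the background noise is calcite; a mid-way threshold would classify
thin (dim) calcite as background and systematically truncate the last
fraction of every pixel's dissolution time, biasing volumes low. A 3x3
median filter is applied before thresholding to suppress shot noise (and
hence lower the detection threshold); it can be disabled or widened via
`median_radius`.

**Cleaning.** Objects below 5 px are removed and only *small* (< 5 px)
interior holes are filled: a genuine hole -- a thin placolith centre
clearing before its rim -- is signal, not noise, and filling it would
overcount the centre's dissolution time. The lith is tracked across frames
by maximal overlap with the previous mask, discarding noise satellites.

**Onset (lag) refinement.** Acid arrival is diffusive, so distant liths
start dissolving late; this lag must be subtracted or it is converted into
spurious thickness ($v \cdot \mathrm{lag}$ per pixel). Threshold-crossing
detection alone (first 2% drop of $r_\mathrm{eff}$) is systematically late
by $0.02\, r_0 / v$, so the onset is refined by back-extrapolating an OLS
line through the first post-detection samples to the pre-onset level. On
noiseless fixtures this recovers the true onset to within a frame.

## The two-regime rate fit

Disk-like liths show a shallow initial $r_\mathrm{eff}$ decay (lateral
retreat at $v$, with the thickness intact) followed by a rapid collapse once
the thinnest region reaches zero. `fit_two_regimes()` fits a continuous
two-segment piecewise-linear model with the knot found by exhaustive search
over interior samples plus continuous refinement (`optimize`, tol 1e-9);
exact two-slope data are recovered exactly.

The initial rate $v$ used for reconstruction is re-estimated on an early
window after onset. The window defaults to 50% of the fitted breakpoint
offset rather than a fixed number of seconds, for two reasons: (i) on
rim-thick placoliths the decay has a *middle* phase (central hole growth)
that a two-segment fit partially absorbs into segment 1, so a window well
inside the first regime is needed; (ii) a proportional window makes the
whole analysis covariant under a joint rescaling of rate and frame interval,
which is exactly the "internal calibration" property the method claims --
our rate-independence test recovers identical volumes at $v$ = 0.05 and
0.2 um/s. An absolute window (e.g. the first 3 s, over which the decay of
typical liths is reliably linear) can be forced via `initial_window`.

## Per-pixel timing conventions

`dissolution_time_map()` assigns each frame-0 pixel
`(last foreground frame - onset frame + 1) * dt`. The +1 counts the frame
interval during which the pixel actually cleared. A pixel that has been
background for two consecutive frames is final; later flickers are noise.
Pixels already gone at onset get one frame interval, the minimum resolvable
time ($h_{\min} = v\,\Delta t$), and are counted in an `early_pixels`
attribute. Lag subtraction is on by default (`subtract_lag = TRUE`); both
behaviours are available and recorded in the provenance sidecar.

## What the synthetic generator emulates -- and what it does not

`render_movie()` erodes a parametric lith at constant surface-normal speed:
the top face loses $v\,\Delta t$ per frame and the lateral support retreats
by the same normal distance (Euclidean-distance-transform front
propagation, with a half-pixel correction so the discrete front tracks the
continuum boundary). Intensity is a saturating function of thickness,
$I = 1 - e^{-h/h_0}$ with $h_0 = 0.5$ um -- thick calcite saturates, thin
calcite is dim but present, mimicking the radially varying scatter of real
placoliths. Gaussian PSF blur and additive Gaussian noise are optional; one
RNG seed per movie, recorded in the ground truth. Since the reconstruction
uses only thresholded masks, the transfer curve affects realism, not the
method's logic; it *does* control how much thin calcite sits below any
noise-limited threshold, which is the dominant error source under noise.

The default placolith profile is thin at the centre
(`centre_fraction = 0.3`), rises as $u^2$ to a rim peak at normalized radius
0.75, and tapers to 15% of the peak at the margin. The taper matters: a
profile whose full rim thickness extends to the outline edge would be a
vertical calcite cliff, and lateral ("side") attack would remove most of the
rim volume before its top face cleared -- real placolith margins close
smoothly.

Not emulated: physical dark-field optics (Mie scattering), birefringence,
stage drift, multi-lith occlusion, and lateral erosion of interior holes
(the generator's side attack acts only from the initial outline). Passing
the recovery suite therefore demonstrates the correctness of the
time-to-event logic and its noise robustness, not photometric realism.

### Known, quantified biases

* **Rim attack.** Pixels within $h$ of the outline are removed by side
  attack before their top face clears, so rim thickness is underestimated;
  the deficit scales like $h/r$ (about $0.95\,h/r$ for a uniform disk). The
  test suite measures it rather than hiding it; no correction is applied.
* **Minimum measurable thickness.** Liths whose thin centre clears within a
  few frames of onset have no measurable initial lateral phase, and the
  fitted "initial" rate is then dominated by collapse -- volumes of very
  thin liths (centre thickness $\lesssim 5 v \Delta t$) are unreliable.
* **Threshold truncation.** Under noise, calcite dimmer than the detection
  threshold is invisible; with the background-referenced threshold and
  median pre-filter this costs a few percent of volume at 10% noise.
* **Compensating biases on rim-thick placoliths.** The early-window rate on
  a three-phase decay overlaps the beginning of central hole growth and
  overestimates $v$ by roughly 10--20%, while rim attack and truncation
  remove a comparable volume fraction; the net placolith volume error is
  smaller than either effect alone. Both contributions are visible
  individually in the benchmark suite (the dissolution-time map against
  ground truth isolates the geometric deficit from the rate estimate), and
  neither is corrected post hoc.

Typical accuracies on the default benchmark geometries (one CPU, seconds to
tens of seconds): noiseless thin disks ~1%, noiseless placoliths ~7%, noisy
(10%) placoliths ~3--4% median over 50 seeds (worst seed ~11%), rate
independence exact by construction.

## The acid transport model

`simulate_protons()` solves axisymmetric (1D radial) finite-volume
reaction-diffusion around the fibre: H2BQ (D = 7.4e-6 cm^2/s) is held at
zero at the electrode surface (transport-limited oxidation at the applied
potential), protons (D = 9.31e-5 cm^2/s) are released there at twice the
H2BQ flux, and the outer boundary (3 mm; the diffusion length at 30 s is
only ~1 mm) is held at bulk composition. Bicarbonate, when present, is a
third diffusing species consumed together with protons by a fast
irreversible bimolecular reaction (rate constant 1e6 L/mol/s, effectively
instantaneous against transport; justified because the generated acid is
far below carbonic acid's pKa of 6.3). Time integration is stiff-stable
(`deSolve::ode.1D`, lsoda, banded Jacobian), so there is no CFL restriction;
the grid is geometrically stretched (200 cells by default). Mass balance --
protons generated = in solution + scavenged -- closes to better than 0.01%.
An optional `layer_height` caps the radial face areas to emulate the
cylindrical-to-planar transition of a thin-layer cell; prototypes showed
confinement *slows* the approach to steady state, so the open geometry is
the default and the conservative choice for time-scale claims.

Validation: the simulated quasi-steady surface concentration matches the
cylindrical product-accumulation closed form
$2 c_b (D_S/D_H)\,\ln(\sqrt{4 D_H t}/r_e)/\ln(\sqrt{4 D_S t}/r_e)$ to ~1%,
and the 10 mM default yields surface pH ~2.7 (< 3, i.e. millimolar acid).

**Steady-state timing.** `steady_state_time(x, tol, t_ref)` reports the
first time the concentration at distance $x$ is within `tol` (default 10%)
of its value at `t_ref` (default 30 s). This is a strict criterion: a
cylindrical source's far field keeps growing logarithmically, so at
$x = 50$ um the 10% band is only entered after ~7 s, although the profile
is visually flat (within ~30%) after 1--2 s. The tolerance is a genuine
dial: conclusions phrased as "steady within about a second" correspond to
the looser band.

**Kinetic regimes.** For a smooth sphere consuming protons at first order,
the steady surface-to-bulk ratio is $m_T/(m_T + k_1)$ with $m_T = D/r$;
`surface_ratio_sphere_fd()` re-derives it by a steady finite-volume radial
solve (Robin inner boundary, Thomas algorithm, log-spaced cells out to
4000 radii) agreeing to 3 significant figures. The half-way radius
$D/k_1 = 21.7$ um separates surface- from transport-limited dissolution and
drops with roughness as $D/(k_1 \cdot \mathrm{roughness})$.

**Electrolyte modifiers.** Mg2+ (surface adsorption) and HCO3- (solution
scavenging) reduce rates through independent saturating factors
$1/(1+\alpha c)$, calibrated once so that seawater-level Mg2+ (54.6 mM)
yields 4.5/6.5 and bicarbonate (2.4 mM) yields 3.8/6.5 of the
roughness-only relative rate (6.5); the full K/2-like medium then predicts
2.6, within the measured 2.9 +/- 1.0 and preserving the observed ordering.
These are empirical factors -- no adsorption isotherm is fitted, because no
isotherm data exist at these compositions.

## Allometry

`loglog_fit()` pools all liths and regresses $\log_{10}$ mass on
$\log_{10}$ length by OLS; the slope (allometric exponent, ~3 for
geometrically similar liths), its normal-theory standard error, and
Pearson's r of the log pairs are returned. Species summaries use the sample
(n-1) standard deviation. The classical shape-factor estimate
$m = 2.7 k_s L^3$ (pg, um; $k_s$ = 0.06, range 0.04--0.07) is provided as
the literature baseline the per-lith measurements are compared against.

## Problem sizes and defaults

The bundled benchmarks use 96--224 px grids at 0.05--0.1 um/px, frame
intervals 0.125--2 s, retreat rates 0.0125--0.2 um/s and 50-seed Monte
Carlo batches -- large enough that discretization is not the limiting error,
small enough that the full suite runs in under a minute on one CPU. The
transport solver's 200-cell grid resolves the surface concentration to
better than 1%; doubling the cells changes headline numbers in the fourth
digit.

## Reproducibility

Every CLI run writes a JSON provenance sidecar (configuration, thresholds,
seed, package version, storage scales) sufficient to re-run bit-identically.
Thickness maps are written as 32-bit float TIFF; samples are stored scaled
by 1e-3 (the `tiff` writer preserves float samples only inside [0, 1]) and
the scale is recorded in the sidecar and undone by `read_thickness_tiff()`.
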