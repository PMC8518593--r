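# lithomass

Coccoliths — the micron-scale calcite plates shed by calcifying marine
phytoplankton — carry picograms of CaCO₃ each, yet collectively export more
than a billion tonnes of calcite to the deep ocean every year. Their
per-lith mass is a key biogeochemical quantity, and far too small to weigh.

`lithomass` implements an **opto-electrochemical acid titration** of
individual coccoliths. A fibre microelectrode oxidises a dissolved acid
precursor (hydroquinone, H₂BQ − 2e⁻ → BQ + 2H⁺), acidifying its
surroundings; a nearby coccolith dissolves while being watched in
dark-field microscopy. Because calcite dissolution at these particle sizes
is *surface-reaction limited* (flux = k₁[H⁺], k₁ ≈ 0.043 cm/s; the
surface/transport crossover lies at radius D/k₁ ≈ 22 μm, far above coccolith
sizes), the surface retreats at a constant speed *v*. The time *t(i,j)* each
pixel needs to clear then encodes the local calcite thickness:

    h(i,j) = v · t(i,j),   V = Σ h·ΔA,   m = ρ_calcite · V   (ρ = 2.71 pg/μm³)

with *v* measured on the same lith from the initial slope of its effective
radius, r_eff(t) = √(A(t)/π) — which internally calibrates surface
roughness, electrode distance and dissolution inhibitors.

The package provides, as both an R API and a small CLI:

* **segmentation** of dissolution movies (frozen background-referenced
  threshold, overlap tracking) and r_eff(t) extraction;
* **reconstruction**: continuous two-segment (breakpoint) fit of the
  two-regime decay, per-pixel dissolution-time map, 3D thickness map,
  volume and mass;
* **kinetics**: finite-volume reaction–diffusion simulation of the
  electro-generated proton field (with optional bicarbonate scavenging),
  surface pH, steady-state timing, the sphere surface/transport regime
  analysis, and electrolyte rate modifiers;
* **allometry**: shape-factor mass (m = 2.7·k_s·L³), pooled log–log
  mass–length regression, thickness–length correlation, species summaries;
* **synthetic data**: a ground-truth movie generator (parametric placolith
  geometry eroded at constant normal speed, dark-field-like rendering with
  PSF and noise) that makes every stage testable without experimental data.

## Worked example

Simulate a noisy dissolution movie of a placolith with known geometry, then
reconstruct it:

```r
library(lithomass)

model    <- lith_model(a = 4, b = 3, max_thickness = 1)   # semi-axes um, rim peak 1 um
scenario <- dissolution_scenario(v = 0.056, frame_interval = 0.5,
                                 noise_sigma = 0.1, lag_time = 2, seed = 42)
movie <- render_movie(model, scenario, pixel_size = 0.1, dim = c(128, 128))

rec <- reconstruct(movie$stack)
rec
#> lith_reconstruction [ok]: length 8.2 um, volume 26.3 um^3, mass 71.28 pg
#>   v_initial 0.07553 um/s, v_terminal 0.4135 um/s, 9.05 um from electrode
movie$truth$volume
#> [1] 25.26
```

The reconstructed volume (26.3 μm³) agrees with the generator's ground
truth (25.3 μm³) to 4% despite 10% intensity noise and a 2 s diffusive
onset lag; the fitted terminal slope (0.41 μm/s) is much steeper than the
initial one (0.076 μm/s) — the characteristic two-regime decay of a thin
disk that loses its last calcite almost at once. The mass, 71.3 pg, is
exactly 2.71 × volume.

The kinetic side of the method:

```r
regime_switch_radius()            # surface/transport crossover for smooth calcite
#> [1] 21.65                      # um — coccoliths are far below this
surface_ph(simulate_protons(proton_field()))
#> [1] 2.69                       # 10 mM H2BQ acidifies the electrode below pH 3
```

And the population-level mass–length scaling on a simulated cohort with a
true exponent of 2.8:

```r
f <- loglog_fit(simulate_lith_table(150, exponent = 2.8, scatter_dex = 0.2, seed = 1))
sprintf("slope %.2f +/- %.2f, r %.3f", f$slope, f$stderr, f$pearson_r)
#> "slope 2.76 +/- 0.09, r 0.928"
```

A command-line interface with the same functionality ships in
`inst/cli/lithomass` (subcommands `reconstruct`, `simulate-movie`,
`simulate-acid`, `allometry`); every run writes a JSON provenance sidecar
sufficient to reproduce it bit-identically.

See `vignettes/lithomass-methods.Rmd` for the models, parameter choices,
numerical conventions and known biases.

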