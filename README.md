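# protoacoustics

Desk-scale simulator of ionoacoustic (protoacoustic) Bragg-peak monitoring
for proton therapy of the brain.

A pulsed proton beam deposits most of its energy at the end of its range —
the Bragg peak — and the quasi-instantaneous heating launches a pressure
wave whose dominant source is the peak itself. Piezoelectric sensors on the
skull record that wave; time differences of arrival (TDOA) across the sensor
set locate the source, and therefore the peak, inside the head. This package
implements the full chain as testable R functions:

* **Dose** — Bragg-Kleeman depth-dose ($R = aE^p$, $a = 0.022$, $p = 1.77$)
  with Gaussian range straggling and a configurable nuclear-loss fraction,
  deposited on a voxel grid with an exact lateral Gaussian; optional bone
  layer as a water-equivalent range shift (`deposit_3d()`).
* **Thermoacoustics** — retarded-time discretization of
  $p(\mathbf r,t) = \frac{\alpha}{4\pi C_p}\int \frac{dV'}{|\mathbf r-\mathbf r'|}
  \,\partial_t^2\,\epsilon(\mathbf r',t-|\mathbf r-\mathbf r'|/c_s)$
  (`thermoacoustic_pressure()`), ray amplitude propagation
  $P = P_{ref}(d_{ref}/d)e^{-\alpha'(d-d_{ref})}$
  (`attenuated_amplitude()`), spectral characterization
  (`central_frequency()`).
* **Skull interface** — Snell refraction with longitudinal/shear branches,
  energy-flux transmission/reflection coefficients, and the arrival-time
  correction for the faster path through the bone layer
  (`toa_correction()`, 1.08 μs at normal incidence for the defaults).
* **Wave-propagation validation** — a small 2-D finite-difference solver for
  the heterogeneous acoustic wave equation (`fdtd_run()`), used to check
  arrival times against the ray model.
* **Receiver design** — analytic radial-mode resonance/anti-resonance model
  of a PZT disc and the feasibility-band + $k_1/k_2$ grid-search geometry
  optimization (`optimize_geometry()`).
* **Localization** — cross-correlation TOA estimation with sub-sample
  parabolic refinement (`estimate_toa()`) and damped Gauss-Newton TDOA
  multilateration with multistart (`solve_position()`).

## Worked example

The default scene is the published six-sensor head geometry: a 100 MeV beam
of 5×10⁶ protons per 10 μs pulse whose Bragg peak lands at
(−70, 20, 171.9) mm inside a spherical 3.5 mm skull shell.

```r
library(protoacoustics)

scene <- build_default_scene()
report <- run_full_chain(scene)
print(report)
#> <run_report>
#>   true source: (-70.00, 20.00, 171.90) mm
#>   reconstructed: (-69.93, 20.00, 171.90) mm
#>   localization error: 0.069 mm (correction: per_sensor)

# disable the skull-layer time correction: the sub-microsecond arrival
# biases degrade the fix to millimetre scale
print(run_full_chain(scene, correction = "none")$error_mm)
#> [1] 1.048097

# reference amplitude 2 mm beyond the peak, and at the 20 mm sensor distance
grid <- deposit_3d(scene$beam, spacing = 1)
pk <- peak_region(grid)
tr <- thermoacoustic_pressure(grid, c(0, 0, pk$peak_depth + 2))
max(abs(tr$p))
#> [1] 2.91875
attenuated_amplitude(max(abs(tr$p)), d_ref = 2, d = 20, alpha_atten = 0.95)
#> [1] 0.2869264

# central frequency of the signal received 20 mm from the peak
central_frequency(report$template)$f_central
#> [1] 99750.62
```

Read: with the per-sensor layer correction the peak is recovered to
0.07 mm; without it the error grows to ~1 mm. The pressure 2 mm beyond the
peak is ~2.9 Pa, which spherical spreading plus water absorption
(0.95 Np/m) reduces to ~0.29 Pa at a 20 mm sensor; the received pulse is
centred near 100 kHz, which is what the receiver-design module optimizes
the PZT disc for:

```r
optimize_geometry(110e3, pic255())$geometry
#> d = 18 mm, th = 8 mm
```

A thin command-line front end over the same functions ships in
`inst/cli/protoacoustic.R` (subcommands `full-chain`, `simulate-dose`,
`simulate-signal`, `transmission-table`, `design-sensor`, `localize`).

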