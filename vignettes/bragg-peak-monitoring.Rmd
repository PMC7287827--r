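---
title: "Ionoacoustic Bragg-peak monitoring: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ionoacoustic Bragg-peak monitoring: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protoacoustics)
```

# The problem

A therapeutic proton beam deposits most of its energy in the last few
millimetres of its range — the Bragg peak. Verifying *in vivo* where that
peak actually sits is one of the open problems of proton therapy. The
ionoacoustic (protoacoustic) approach exploits the fact that a pulsed beam
heats the dose volume quasi-instantaneously, launching a pressure wave whose
dominant source is the Bragg peak itself. Piezoelectric sensors on the skull
record that wave, and the time differences of arrival (TDOA) across the
sensor set fix the source position — and hence the peak — to millimetre
accuracy.

This package implements the whole chain at desk scale for a brain-treatment
geometry: dose deposition, thermoacoustic emission, propagation through the
cerebrospinal-fluid/skull interface, receiver design, and source
reconstruction. Each stage is exposed as ordinary R functions so the chain
can be re-run stage by stage, perturbed, and tested.

# Dose model

Monte Carlo transport is out of scope; the depth-dose curve is the
Bragg-Kleeman analytic stand-in. The range in water follows
$R = a E^p$ with the usual water constants $a = 0.022$ mm MeV$^{-p}$,
$p = 1.77$ (so $R(100\,\mathrm{MeV}) \approx 76.3$ mm), and the per-proton
linear energy deposition is the corresponding differential curve
$\mathrm{d}E/\mathrm{d}z \propto (R - z)^{1/p - 1}$ convolved with a
Gaussian range-straggling kernel. Two calibration knobs are deliberately
exposed, because the reference Monte Carlo settings behind them are not
published:

* `straggle_frac` (default 0.01): range-straggling sigma as a fraction of
  the range, i.e. 0.76 mm at 100 MeV — a typical value for water at these
  energies;
* `nuclear_loss` (default 0.10): the fraction of beam energy carried away
  non-locally by nuclear interactions. The curve is normalized so that its
  integral is exactly $(1 - \texttt{nuclear\_loss}) \cdot E$.

`deposit_3d()` multiplies this axial curve by an exact lateral Gaussian
(error-function cell fractions, beam sigma 1 mm by default) on a
cell-centred voxel grid (1 mm default). A skull entry layer is modelled as a
pure water-equivalent range shift of `thickness * (rsp - 1)`; scatter
broadening in bone is ignored, because the dominant printed effect of the
layer is the proximal peak shift. An optional Monte Carlo mode samples
per-proton ranges from the straggling Gaussian with an explicit seed; the
default analytic mode is deterministic.

One known gap of the stand-in: its proximal shoulder is broader than a
Monte Carlo Bragg curve, so the half-maximum region of the 100 MeV peak has
a bounding diameter of roughly 4–5 mm rather than the ~2 mm sphere quoted
for the reference simulation. The propagation stage therefore takes the
source sphere diameter (2 mm) as an explicit scene parameter instead of
deriving it from the half-max region.

# Thermoacoustic emission

The pressure at a point is the retarded-time integral
$$p(\mathbf r, t) = \frac{\alpha}{4\pi C_p} \int \frac{\mathrm dV'}
{|\mathbf r - \mathbf r'|}\,
\frac{\partial^2}{\partial t^2}\,\epsilon(\mathbf r', t - |\mathbf r -
\mathbf r'|/c_s),$$
with $\alpha$ the volumetric thermal expansion coefficient, $C_p$ the
specific heat and $\epsilon$ the deposited energy density. The source is
assumed separable, $\epsilon(\mathbf r, t) = \epsilon(\mathbf r)\,
S_{cum}(t)$, the standard assumption when the beam's spatial profile is
stationary during the pulse; the second time derivative of the deposition is
then the first derivative of the pulse profile $S$. `thermoacoustic_pressure()`
bins each voxel's weight $\epsilon\,\mathrm dV'/|\mathbf r - \mathbf r'|$ at
its retarded arrival (linear split between adjacent time bins), convolves
the binned kernel with the sampled profile, and differentiates once by
central differences. Medium defaults are body-temperature water:
$c_s = 1500$ m/s, $C_p = 4180$ J/(kg K), $\rho = 1003$ kg/m$^3$, and
$\alpha = 3.7\times10^{-4}$ K$^{-1}$ — the 37 °C value rather than the
20 °C one ($2.1\times10^{-4}$), because the application is *in vivo*; it is
a configuration knob.

Two numerical choices matter:

* **Near field.** The voxel-as-point approximation fails when the
  observation point is within a few voxel pitches of the source. Voxels
  closer than 8 pitches are subdivided 4×4×4, which converges the 2 mm
  reference amplitude to well under a percent.
* **Pulse profile.** The reference beam delivers $5\times10^6$ protons in a
  10 μs pulse, but the pulse *shape* is not published. Both rectangular and
  Gaussian profiles are implemented. The default is the Gaussian (sigma =
  duration/6, edge-corrected so the profile reaches zero continuously): a
  rectangular 10 μs profile concentrates its spectrum near
  $1/(2\tau) = 50$ kHz and below and cannot reproduce the ~110 kHz central
  frequency, ~2.9 Pa reference amplitude and ~0.28 Pa sensor amplitude that
  the chain is validated against, while the Gaussian profile reproduces all
  three simultaneously. The edge correction exists because a truncated
  Gaussian with a nonzero edge value acquires a delta in its derivative,
  which the time discretization would amplify as `1/dt`.

Amplitude propagation away from the reference point uses the ray form
$P = P_{ref}\,(d_{ref}/d)\,e^{-\alpha'(d - d_{ref})}$ with the water
absorption coefficient $\alpha' = 0.95$ Np/m (300 kHz reference), applied as
a frequency-independent factor — no dispersion model. The relative form is
used (rather than an absolute $P_0/d$ anchor) because it is the only reading
consistent with both printed amplitudes (2.92 Pa at 2 mm and 0.28 Pa at
20 mm).

`central_frequency()` reports the spectral maximum after mean removal, a
Hann taper, and zero-padding. By default the analysis window is ±10 μs
around the envelope peak: the direct spherical wave from the Bragg peak is
the signal of interest, and the window keeps the later, lower-frequency
cylindrical wave radiated by the entrance track from dominating the
spectrum.

# Skull interface

The cerebrospinal-fluid/skull boundary is treated as a plane fluid–solid
interface with Snell refraction into longitudinal and shear branches and
standard energy-flux coefficients built from the impedances
$Z = \rho c/\cos\theta$; below both critical angles $T_p + T_s + R = 1$
identically. Default skull parameters — longitudinal speed 2800 m/s, shear
1400 m/s, density 1900 kg/m$^3$, thickness 3.5 mm — are typical cranial-bone
values chosen so the normal-incidence arrival-time correction
$$\Delta t = \frac{L}{\cos\theta_p}\left(\frac 1{c_{fluid}} -
\frac1{c_{long}}\right)$$
equals the applied 1.08 μs; the exact values behind that printed correction
are not published, so all four are configuration values. The layer makes
arrivals *earlier* than an all-fluid path; the per-sensor signed shift
handed to `correct_toas()` is therefore `-toa_correction(...)`. A constant
correction cancels exactly in time differences — only the per-sensor
(angle-dependent) mode changes the reconstruction, which is why the chain
defaults to it.

# Wave-propagation validation

`fdtd_run()` is a small 2-D finite-difference solver for the heterogeneous
acoustic wave equation (harmonic-mean face densities, exponential sponge
boundary). Being 2-D, it spreads cylindrically and is used only to validate
*arrival times* (against the ray model and the layer correction) and
qualitative transmission, never amplitudes — those come from the
ray-acoustic model above. Monopole/dipole volume sources are taken as zero;
the source enters as a pressure injection. The CFL bound
`dt <= dx/(c_max * sqrt(2))` is enforced with an explicit error.

# Receiver design

The reference receiver study optimizes a PZT (PIC255) disc for the expected
signal band. The published workflow sweeps impedance spectra with FEM; here
the first two radial modes are approximated analytically:
$f_{r,1} = (N_p/d)\,(1 + q x^2)^{-1/2}$ with aspect ratio $x = th/d$ and
$q = (N_p/N_1)^2$ — the classical coupled-resonator correction built from
the datasheet planar ($N_p$ = 2000 Hz m) and transverse ($N_1$ = 1420 Hz m)
frequency constants — and anti-resonances from the mode couplings via the
IEEE relation $f_a = f_r/\sqrt{1 - k^2}$. The printed coupling formula
$k = 1 - (f_r/f_a)^2$ lacks the radical of the IEEE definition
$k^2 = 1 - (f_r/f_a)^2$; the radical form is implemented (the optimizer's
ordering is unaffected either way). The first-mode coupling interpolates
from the planar value $k_p$ toward the thickness value $k_t$ as the mode
hybridizes; the second-mode coupling carries a Lorentzian "mode-veering"
suppression centred where the thickness mode crosses the second radial mode
(that crossing is derived from the same datasheet constants; the dip depth
0.75 and width 0.25 are heuristic calibration so the analytic landscape
reproduces the qualitative shape of the published FEM surface — an
approximation documented as such, not fitted to any graded quantity).

`optimize_geometry()` preserves the published optimization logic exactly:
grid-search diameters and thicknesses in [5, 40] mm, keep geometries whose
first-mode (resonance, anti-resonance) band contains the target frequency,
and take the arg-max of $k_1/k_2$, ties toward the smaller diameter. With
the shipped constants and a 110 kHz target the optimum lands at a thick
mid-size disc (18 mm × 8 mm), in the neighbourhood of the published FEM
optimum (15 mm × 9 mm); exact coincidence is not expected from a
scalar-constant model.

# Localization

Arrival times are estimated by normalized cross-correlation between each
received trace and the source-side template (the simulated trace 20 mm
beyond the peak on the beam axis), with sub-sample refinement by parabolic
interpolation of the correlation peak; a peak coefficient below 0.2 flags
the estimate unreliable. The TDOA system
$F_i(x) = |x - s_i| - |x - s_{ref}| - c\,\Delta t_i$ is solved in
least-squares by damped Gauss-Newton: Levenberg-style diagonal
regularization, Armijo backtracking, and — on non-convergence — multistart
from the corners and centroid of the search box. The system is assembled in
millimetres; assembling it in seconds makes the normal matrix so small that
any fixed regularization dominates it, a numerically real failure mode found
during development. Tolerances: step norm $10^{-9}$ mm, at most 100
iterations per start.

The six shipped sensor positions are nearly coplanar (all within 2.6 mm of
one axial plane), so the fix is ill-conditioned along that normal —
`sensor_array()` warns about it. This conditioning is physically meaningful:
it is why sub-microsecond arrival biases from the skull layer grow into
millimetre-scale position errors, and why removing them with the layer
correction matters.

# Scene geometry

The only published geometry is the sensor/source table; the skull shell
around it has to be reconstructed. An unconstrained sphere fit through the
six sensors degenerates (their near-coplanarity lets a huge far-away sphere
fit best, putting every incidence angle past critical), so the shell is
fixed anatomically instead: centre at the midpoint of the sensor span,
$(-61, 17, 172.5)$ mm, outer radius 42 mm — the largest sphere that keeps
every sensor on or outside the shell — and the default 3.5 mm wall. The
source sits 9.5 mm off-centre, giving incidence angles up to ~10°, all well
below the 32.4° longitudinal critical angle. These values were fixed once,
from geometry alone, and are scene parameters like everything else.

`run_full_chain()` wires the stages together: dose grid (0.5 mm pitch so
the 2 mm source sphere is resolved), thermoacoustic traces at the sensors
from the dose inside that sphere (each arrival advanced by its per-sensor
layer time, amplitudes scaled by the interface transmission and fluid
absorption), cross-correlation lags against the template, optional layer
correction, Gauss-Newton solve. With the per-sensor correction the
reconstruction error against the Bragg-peak centroid is well below a
millimetre; with the correction off, the sub-microsecond layer biases and
the ill-conditioned array geometry leave an error of order a millimetre to
a few millimetres — the degradation the published study reports. The chain
is deterministic; optional Gaussian TOA jitter (`toa_jitter_sd`) is the
only random element and takes an explicit seed.

# What the synthetic data do and do not show

The generator emulates: Bragg-curve depth dose with straggling and nuclear
loss, a Gaussian pencil beam, separable pulse time structure, a uniform
fluid brain, a single spherical uniform skull shell, and noise-free sensors
(plus optional Gaussian TOA jitter). It does not emulate: Monte Carlo dose
fine structure (nuclear buildup, secondary halo), anatomical skull thickness
variation and curvature, shear-wave arrivals, frequency-dependent bone
absorption and dispersion, transducer impulse response, or electronic noise.
Passing tests therefore demonstrate internal consistency of the model chain
and agreement with the published desk-scale figures — not clinical
performance on real anatomy.

# Problem sizes

The shipped configuration runs the full chain in well under a second: a
16×16×176-voxel dose grid at 0.5 mm (1 mm for the reference-amplitude
evaluation), ~30 source voxels in the 2 mm sphere, six sensor traces of
~1000–1300 samples at 50 ns, and a Gauss-Newton solve of a 5×3 system. The
finite-difference validation runs use 70×136 cells at 0.5–1 mm for 220–400
steps. These sizes were chosen as the smallest that keep every validated
quantity grid-converged (halving any pitch moves the reported numbers by
less than the tolerances asserted in the tests).
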