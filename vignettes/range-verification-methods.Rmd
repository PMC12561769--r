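---
title: "Protoacoustic range verification: models, phantoms and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protoacoustic range verification: models, phantoms and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protorange)
```

## The problem

A therapeutic proton beam stops at the Bragg peak, where it deposits most
of its energy. Because nothing is transmitted beyond the stopping point,
the beam range cannot be imaged directly during treatment. The pulsed
energy deposition, however, heats the tissue at the Bragg peak by a tiny
amount, and the resulting thermoelastic expansion launches a pressure
wave — the protoacoustic (ionoacoustic) signal. If a detector records
that wave, the Bragg-peak-to-detector distance can be estimated by
time-of-flight (TOF):

\[ D_\mathrm{TOF} = T_\mathrm{peak} \cdot \bar c, \qquad
   \Delta D = |D_\mathrm{real} - D_\mathrm{TOF}|, \qquad
   \varepsilon_D = 100\,\Delta D / D_\mathrm{real}, \]

where \(T_\mathrm{peak}\) is the arrival time of the global maximum of
the detected waveform and \(\bar c\) the straight-line path-averaged
speed of sound between the Bragg peak and the detector. The question this
package quantifies is how *acoustic heterogeneity* — voxel-to-voxel
variation of sound speed and density inside nominally homogeneous
tissue — biases that estimate.

## Source model

The initial pressure generated by a dose deposition is
\(P_0(\mathbf r) = \Gamma(\mathbf r)\,\rho(\mathbf r)\,\mathrm{Dose}(\mathbf r)\)
with the Grüneisen coefficient \(\Gamma = c^2\beta/C_p\)
(`gruneisen()`, `initial_pressure()`). The shipped thermoacoustic
defaults (\(\beta = 2.24\times10^{-4}\,\mathrm{K^{-1}}\),
\(C_p = 4178\,\mathrm{J\,K^{-1}kg^{-1}}\), water \(c\) and \(\rho\)) are
calibrated once so that 1.0 cGy in water-equivalent tissue yields
\(\approx 1.2\) Pa, the conversion the study states; per-tissue values
are configurable because published tissue compilations vary.

The proton pulse is temporally Gaussian with a **total width of 10 µs
interpreted as a 6σ support** (σ ≈ 1.67 µs, peak at 5 µs). Two details
matter numerically:

* **Pedestal subtraction.** A Gaussian truncated at ±3σ retains a 1.1%
  pedestal; the discontinuities at the support edges inject a broadband
  click whose band-limited far field can rival the physical signal. The
  sampled pulse (`gaussian_pulse()`) is therefore pedestal-subtracted and
  renormalised — an exact Gaussian in shape, identically zero at the
  edges.
* **Drive convention.** The solver's default `"pressure"` drive imposes
  the waveform on the source voxel incrementally, so the local pressure
  follows \(P_0 G(t)\) — the literal reading of a time-convolved initial
  pressure. The corresponding 3-D far field is \(\propto G''(t - r/c)\):
  a symmetric tri-lobed wavelet whose leading compression peaks
  \(\sqrt3\,\sigma \approx 2.89\,\mu s\) *before* the pulse centre, i.e.
  \(2.11\,\mu s\) after the geometric arrival \(r/c\). For the reference
  geometry (100 mm of 25 °C water, 1498 m/s) this predicts an arrival of
  68.87 µs, matching the reference measurement of 68.74 µs to within
  0.15 µs. The alternative `"pressure_rate"` drive (mass-rate source,
  classic N-shaped far field \(\propto G'\), offset \(2\sigma\) later)
  is available; the arrival-time *offset* is a pulse-shape convention
  either way, which is why the studies compare arrival times and range
  gaps between media rather than leaning on the absolute offset.

A study source can include the entrance path: `build_study_sources()`
places a 12 mPa source at the Bragg peak and 2 mPa sources at every voxel
along the beam entrance. The study drivers default to the Bragg source
alone, since the printed baseline arrival is governed by it and the
contribution of the entrance path to the global maximum is a modelling
unknown.

Detected amplitudes scale with the source footprint (a single voxel by
default) and are far below the 12 mPa injected at the source — of order
10 nPa–0.1 mPa at 100 mm depending on dimensionality and absorption — so
the 0.2 mPa peak-to-valley validity gate (`signal_is_valid()`) generally
flags desk-scale single-voxel-source traces as invalid. The flag is
reported as computed; all range quantities are amplitude-scale-invariant
(the solver is linear, which the test suite verifies to machine
precision).

## Media models

* **Water.** Marczak's fifth-order polynomial for speed and Kell's
  formula for density, each anchored so that 25 °C maps exactly to the
  reference values 1498 m/s and 997 kg/m³.
* **CT numbers.** All CT numbers use the offset scale (water ≈ 1000,
  air ≈ 0), the only scale consistent with the built-in tissue
  statistics; `hu_from_conventional()` converts from the scanner scale.
  `hu_to_speed()` / `hu_to_density()` interpolate piecewise-linearly
  through air, lung, water, soft-tissue and bone anchors, exactly at the
  anchors, clamped outside.
* **Tissues.** `tissue_table()` carries the per-tissue mean and SD of CT
  number, density and speed. Nonuniform phantoms draw **one standard
  normal per voxel** and drive all three properties through linear
  relations calibrated to those (mean, SD) pairs. This reproduces every
  tabulated statistic exactly in expectation. The alternative — drawing
  CT noise and pushing it through the global anchor map — is *not*
  equivalent: the anchor map's local slope at lung (~1.3 m/s per CT
  number) would inflate the lung speed SD to ~87 m/s against the
  tabulated 47.8 m/s, so the calibrated per-tissue relations are the
  faithful generator.
* **Absorption.** Frequency power-law \(\alpha = \alpha_0\omega^d\) with
  a global \(d = 1.05\). Per-tissue prefactors default to representative
  tabulated values (soft tissue 0.54, cortical bone 6.9, inflated lung
  40 dB MHz\(^{-d}\) cm\(^{-1}\)). Absorption is not cosmetic here: in a
  lossless nonuniform lung phantom the multiply-scattered coda can
  occasionally exceed the direct compression peak, and the global-maximum
  arrival rule then fails in a way the physical, strongly absorbing lung
  does not permit. Water is treated as lossless (its quadratic-law
  absorption is negligible at the ~0.1 MHz pulse band).

## Phantoms

`make_thermal_water_phantom()` draws i.i.d. voxel temperatures
N(25, sd²) °C. Draws are winsorised symmetrically to [0.5, 49.5] °C
(preserving the 25 °C mean exactly; at sd = 15 °C about 94% of the
nominal variance survives) so every voxel stays inside the property
models' validity range. Because the temperature-to-speed curve is
concave, zero-mean temperature noise would *lower the bulk mean speed*
(by ~7.7 m/s at sd = 15 °C, i.e. a spurious ~0.4 µs delay); since the
study isolates heterogeneity from bulk changes, the converted fields are
re-centred on the 25 °C reference values, leaving pure spatial
heterogeneity.

`make_tissue_phantom()` and `make_bimaterial_phantom()` build uniform
(means everywhere) and nonuniform (per-voxel draws) single- and
two-material phantoms; the bimaterial interface is perpendicular to the
source–detector axis at its midpoint, so the 100 mm path crosses ~50 mm
of each material. Properties are floored at 1% of the lung means (clamp
events are messaged). All generators are seed-deterministic:
identical configurations give bit-identical grids.

The noise model is i.i.d. per voxel with no spatial correlation — the
minimal assumption consistent with specifying only means and SDs. Real
tissue heterogeneity is spatially correlated and anisotropic; passing
these tests therefore shows correct behaviour under the stated
statistical model, not under real anatomy.

`load_ct_volume()` ingests NIfTI or a plain-text voxel format (the
CT-number scale must be declared explicitly), and
`make_ct_like_phantom()` builds synthetic labelled volumes (e.g. an air
pocket between Bragg peak and detector) for detector-placement studies.

## Wave solver

`propagate()` integrates the first-order coupled pressure–velocity
system on a staggered grid: 8th-order spatial stencils, leapfrog time
stepping, split-field PML on all boundaries, single (default) or double
precision, 2-D and 3-D. Design notes:

* **Why 8th order.** At the pulse's centre frequency (~0.135 MHz) the
  wavelength is 11 mm in water but only 4.8 mm in lung. The 8th-order
  staggered stencil keeps the phase-velocity error at 1.2×10⁻⁶ (water,
  1 mm grid) and 7.4×10⁻⁴ (lung, 1 mm). Low-order schemes are not just
  inaccurate here — their dispersion delays the high-frequency content
  enough to hand the global maximum to the trailing lobe of the wavelet,
  a qualitative failure of the arrival rule.
* **PML.** Quartic absorption profile with the toolbox-style
  dimensionless coefficient 2.0 (σ_max = 2 c_max/Δx), thickness ≥ 10
  points, positioned outside the user grid (properties edge-replicated
  into it). The profile ramps over the *updated* part of the layer (the
  outermost 4 cells lie beyond the stencil and stay frozen). Measured
  normal-incidence reflection is below 1% of the incident amplitude; the
  test suite checks this. Grazing incidence absorbs less — which is why
  the transverse domain must not be too narrow (below).
* **Absorption operator.** The power law is realised as a viscous
  (diffusive) loss matched to \(\alpha_0\omega^d\) at a reference
  frequency (default 0.135 MHz, the pulse's spectral peak); the run
  metadata flags the approximation. Over the two-octave band of the
  pulse this mismatches the exact power law by the difference between
  \(\omega^{1.05}\) and \(\omega^2\) scaling — acceptable for arrival
  times, not for broadband amplitude spectroscopy.
* **Time step.** The CFL number is checked before every run (default
  limit 0.3; the limiting voxel is reported on violation). Arrival-time
  studies sample traces at 10–40 ns, far below the stability limit,
  because thermal delays are resolved at the 0.01 µs level.
* **Flush-to-zero.** Strong absorption drives residual fields into the
  denormal range, where hardware arithmetic slows by orders of
  magnitude; the kernel enables flush-to-zero (physically harmless at
  these amplitudes).

`check_stability()` reports the CFL state; `convergence_probe()` re-runs
a configuration across a ladder of grid spacings (dt rescaled to keep
CFL constant) and reports the detected arrival at each level.

## Peak picking

`detect_peak_time()` returns the time of the global maximum, with ties
broken to the earliest. Ties are assessed on *local maxima within a 2%
relative band* of the global maximum: the 3-D far field of a symmetric
pulse has two analytically equal compression lobes 5.8 µs apart, and
with a near-dispersion-free solver their numerical order is meaningless.
The earliest-local-maximum rule resolves this deterministically in
favour of the physical first arrival. Setting `tie_tol = 0` recovers the
plain global-maximum rule. Traces that are identically zero raise an
error ("no signal"); no filtering, denoising or pulse-width correction
is applied anywhere.

`path_average_speed()` samples the straight Bragg-peak-to-detector
segment at one-voxel intervals using **midpoint (cell-centred)
sampling** — N = round(L/Δx) samples at sub-segment midpoints with
nearest-voxel lookup — so each traversed voxel carries equal weight and
a half-and-half bimaterial path weighs its two materials exactly 50:50.
Endpoint-inclusive sampling would weigh one material 51:50 and shift the
mixed-path mean by ~7 m/s.

Averaging order matters in mixed media: the default converts per sample
and averages the *speeds* (arithmetic mean), which reproduces the
reference uniform-phantom ranges exactly — e.g. bone+lung gives
(2153.9 + 652.8)/2 = 1403.35 m/s. Averaging the *CT numbers* first and
converting the mean (`method = "hu_mean"`) lands near the soft-tissue
anchor (~1567 m/s) because the anchor map is nonlinear; both are
available, the speed average is the default.

## Study protocol and problem sizes

The reference-scale setting — a 200 mm cube at 1 mm and 10 ns in 3-D —
is supported (`scale = "reference"`) but slow on a workstation. The studies
default to a desk-scale protocol chosen so that every quantity compared
against the reference values is insensitive to the reduction:

* **2-D plane** through the source–detector axis for the stochastic
  studies (heterogeneity delays and range gaps are differences between
  media, cancelling the dimension-dependent pulse offset), and coarse
  3-D (1 mm, dt = 0.1 µs, 60 mm transverse aperture) for the water
  baseline, whose absolute arrival *does* depend on dimensionality.
* **1 mm phantom voxels** — the reference voxel size — so the
  heterogeneity correlation length matches; 2 mm would also put only
  2.4 grid points per lung wavelength, unresolvable by any scheme.
* **Solver-side refinement.** Where the slowest involved tissue gives
  fewer than 8 points per wavelength (lung at 1 mm: 4.8), the solver
  grid is a nearest-neighbour refinement (to 0.5 mm) of the phantom;
  the phantom keeps its native 1 mm noise blocks, so the physics of the
  heterogeneity is unchanged and only the numerics improve.
* **Transverse aperture 180 mm** (2-D studies). With a 60 mm aperture,
  off-axis energy re-radiated by heterogeneities grazes the lateral PMLs
  and can return a spurious late peak comparable to the direct arrival
  (grazing incidence is where PMLs absorb worst); at 120 mm occasional
  realisations in slow lung still produced such peaks, and at 180 mm
  they fall clearly below the direct arrival across the tested seeds.
  Uniform media are insensitive to the aperture.
* **Five replicate seeds** for every stochastic configuration (the
  reference reports single realisations without a stated seed policy),
  except the thermal delay, which is reported as a **20-seed mean**: its
  per-realisation spread (~0.06 µs) exceeds the delay itself, so the
  5-seed mean would be dominated by realisation noise. Reports carry
  per-replicate rows plus mean/SD summaries, and double-precision
  arithmetic because 0.01 µs arrival shifts sit near single-precision
  trace granularity.
* **Time steps**: 10 ns for the thermal study (delays of 0.01–0.06 µs),
  40 ns for the tissue studies (gaps of millimetres; 0.04 µs quantises
  to < 0.03 mm).

With these defaults the full acceptance recomputation (water baseline in
3-D, thermal study, homogeneous and 12-configuration bimaterial studies)
takes on the order of ten minutes on one CPU core.

## Known limitations

* 2-D scattering is stronger than 3-D at equal contrast (scatterers are
  effectively rods), so desk-scale heterogeneity-induced gaps carry a
  dimensional bias that the replicate tolerance absorbs but does not
  remove.
* The viscous absorption operator matches the power law at one frequency
  only, and lung's absorption prefactor at 0.1 MHz is an extrapolation
  of MHz-range tabulations.
* The i.i.d. voxel noise model has no spatial correlation; real CT-derived
  property maps do.
* Proton transport is out of scope: the Bragg-peak position (and
  optionally a dose map) is an input, not a computed quantity.
* Clinical whole-body CT propagation is out of scope; the clinical
  evaluation ships as tabulated range pairs
  (`clinical_tof_cases()`), on which the package reproduces the error
  arithmetic, and synthetic CT-like fixtures
  (`make_ct_like_phantom()`) stand in for detector-placement studies.
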