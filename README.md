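# protorange

Simulation pipeline for **protoacoustic proton-range verification in
acoustically heterogeneous media**.

When a pulsed proton beam stops in tissue, the energy deposited at the
Bragg peak launches a pressure wave (the protoacoustic or ionoacoustic
signal). A detector at distance `D_real` sees the wave arrive at
`T_peak`, and the beam range can be estimated by time of flight,

    D_TOF = T_peak · c̄ ,   ΔD = |D_real − D_TOF| ,   ε_D = 100 · ΔD / D_real ,

with `c̄` the straight-line path-averaged speed of sound between the
Bragg peak and the detector. Real tissue is not acoustically uniform:
CT-derived sound speed and density vary voxel to voxel, and that
heterogeneity delays and distorts the wavefront. This package is built
for medical-physics researchers who want to quantify that effect. It
provides:

* **Media models** — temperature-dependent water properties (anchored to
  1498 m/s and 997 kg/m³ at 25 °C), CT-number-to-property maps, tissue
  statistics (soft tissue, bone, lung), Grüneisen coefficient
  `Γ = c²β/C_p`, and power-law absorption `α(ω) = α₀ ω^d` with `d = 1.05`.
* **Phantom generators** — thermal water with Gaussian spatial
  temperature fluctuation; uniform vs nonuniform single-tissue phantoms;
  two-material phantoms split at the path midpoint; synthetic CT-like
  labelled volumes; NIfTI/plain-text CT ingestion.
* **A wave solver** — staggered-grid pressure–velocity FDTD (8th-order
  spatial stencils, split-field PML, heterogeneous speed/density,
  power-law viscous absorption, 2-D and 3-D, single/double precision),
  with CFL checking and a grid-convergence probe.
* **TOF analysis** — global-maximum arrival picking with an
  earliest-tie rule, the 0.2 mPa peak-to-valley validity gate,
  path-averaged sound speed, and the range-error arithmetic above.
* **Study drivers** — `run_thermal_water_study()`,
  `run_homogeneous_study()`, `run_bimaterial_study()`,
  `run_ct_detector_study()` reproduce the three heterogeneity analyses
  end to end at desk scale, and `clinical_range_report()` evaluates the
  shipped five-case clinical TOF table (25 detector positions).

## Worked example

Uniform two-material phantoms, 100 mm Bragg-peak-to-detector path with
50 mm of each material. The path-averaged speed of the bone–lung pair is
the arithmetic mean of the tissue speeds, and multiplying a 101.05 µs
arrival time by it gives the TOF range:

```r
library(protorange)

g <- make_bimaterial_phantom(
  phantom_config("bimaterial", tissues = c("bone", "lung"), shape = c(130, 60)))
pa <- path_average_speed(g, c(15.5, 29.5), c(115.5, 29.5))
pa
#> <path_average> 1403.35 m/s over 100 mm (100 samples, speed_mean)

tof_to_distance(101.05e-6, pa$c_avg)   # mm
#> [1] 141.8085
```

A 141.81 mm estimate for a 100 mm geometric distance: in a bone–lung
phantom the naive path-average TOF overestimates the range by more than
40%, which is why detector placement relative to slow media matters.

Simulating rather than tabulating: the thermal-water study propagates
the wave through water phantoms whose voxel temperatures fluctuate
around 25 °C and compares arrival times with the homogeneous baseline:

```r
rep <- run_thermal_water_study(
  study_config("thermal_water", temperature_sds = c(0, 15), replicates = 5))
attr(rep, "summary")
#>   config n tof_us_mean  tof_us_sd delay_us_mean delay_us_sd
#> 1    sd0 1      69.460         NA         0.000          NA
#> 2   sd15 5      69.514 0.06580274         0.054  0.06580274
```

A ±15 °C spatial temperature spread delays the arrival by only ~0.05 µs
(≈0.08 mm of range) — thermal heterogeneity is negligible, in contrast
to tissue heterogeneity: the same comparison for lung
(`run_homogeneous_study()`) lengthens the estimated range by ~3 mm.

The numbered scripts under `analysis/` run the full study sequence
(3-D water baseline, thermal water, homogeneous tissues, 12-configuration
bimaterial study, clinical detector table) and write their tables under
`results/`.

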