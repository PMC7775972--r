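# pmqsm — quantitative susceptibility and R2\* mapping for whole post-mortem brains

Whole, fixed post-mortem brains imaged with a multi-echo gradient-echo
(GRE) sequence at ultra-high field pose processing problems that in-vivo
QSM pipelines do not handle well: per-coil phase offsets that produce
open-ended fringe lines in vendor reconstructions, B0 drift from
passive-shim heating that translates echoes and repeats along the
phase-encode axis and shifts the whole-brain frequency between repeats,
air bubbles that create strong dipole fields and streaking, and the
absence of any pathology-free reference region. `pmqsm` is an R
implementation of a processing chain built for exactly this setting,
aimed at researchers relating susceptibility (χ) and R2\* maps to
histology in neurodegeneration cohorts.

The chain: coil combination by first-echo phase subtraction (offsets
cancel exactly) with sum-of-squares magnitudes; translation-only
alignment of echoes and repeats; voxel-wise nonlinear complex field
fitting

&nbsp;&nbsp;argmin<sub>φ₀, Δf</sub> ‖ S(TE′) − |S(TE′)| · e^{i(φ₀ + 2πΔf·TE′)} ‖²

initialized from a spatially unwrapped two-echo phase difference so that
local offsets beyond the 75.76 Hz per-spacing aliasing limit stay on the
correct branch; φ₀-based mask refinement; readout phase-gradient removal;
per-repeat field estimation with map averaging and drift diagnostics;
v-SHARP background removal (12 mm maximal kernel, regularization 0.02);
thresholded k-space division (TKD, δ = 0.2, with point-spread-function
amplitude correction) and a two-pass streak-reduced dipole inversion;
whole-brain mean-zero referencing; R2\* fitting with a noise-floor term,
M(TE) = M₀·e^(−TE·R2\*) + noise, with bounds and inter-repeat T2\* drift
assessment; and an ROI/statistics layer (scaled-MAD outlier rejection,
per-batch standardization of stained-area fractions, Pearson and partial
correlation, Welch's t with Hedges's g, covariate regression).

A physics-based phantom simulator (`phantom_spec()`, `build_phantom()`,
`simulate_acquisition()`) forward-models the acquisition — dipole
convolution with D(k) = 1/3 − (k·b̂)²/|k|², coil sensitivities with
constant phase offsets, complex noise, per-repeat drift, phase-encode
translations, air bubbles — so every stage is testable by parameter
recovery. See the methods vignette
(`vignettes/pmqsm-methods.Rmd`) for models, parameters and design
decisions.

## Worked example

Simulate a four-repeat acquisition with the default drift schedule
({0, 5, 8, 9} Hz) and inter-repeat phase-encode shifts, then run the full
pipeline:

```r
library(pmqsm)
res <- run_pipeline(pipeline_config(
  seed = 7,
  acquisition = list(voxel_size_mm = c(2, 2, 2), n_repeats = 4),
  simulate = list(grid_shape = c(32, 32, 32), container_radius_mm = 28,
                  brain_semiaxes_mm = c(24, 20, 18),
                  ribbon_center_mm = c(0, 0, 15), ribbon_radius_mm = 6,
                  n_coils = 2, coil_phase_offsets_rad = c(0.5, -1.2),
                  bubbles = list())))
res$field$drift
#>   repeat_index mean_delta_f_hz increment_hz
#> 1            1       -0.148044           NA
#> 2            2        4.891742    5.0397858
#> 3            3        7.860465    2.9687229
#> 4            4        8.837994    0.9775292
```

The drift diagnostic recovers the injected per-repeat offsets: the
whole-brain mean frequency rises by ≈5, 3 and 1 Hz between successive
repeats — the decreasing-increment signature of a scanner whose
passive-shim temperature settles during the session.

```r
mask <- res$chi$mask
mean(res$chi$chi_ppb[mask])        # 0 (whole-brain referenced)
range(res$chi$chi_ppb[mask])       # -58.6 .. 87.0 ppb
roi_summary(res$chi$chi_ppb, res$truth$labels == 3 & mask)
#> ribbon ROI: mean chi 25.0 ppb over 64 voxels (1 outlier removed)
```

The referenced susceptibility map averages exactly zero over the brain;
the simulated cortical-ribbon hyperintensity (truth +50 ppb against a
+20 ppb grey shell) is recovered as a clearly positive ROI mean — v-SHARP
attenuates part of a patch this small, which is why group analyses on
desk-scale phantoms are interpreted directionally. The per-repeat T2\*
drift report (`res$t2star_drift`) stays within a few percent, so no
temperature correction is applied.

A thin command-line wrapper with `simulate`, `run`, `combine` and `qsm`
subcommands ships in `inst/cli/pmqsm.R`.

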