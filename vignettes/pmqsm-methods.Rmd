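---
title: "Post-mortem QSM and R2* mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-mortem QSM and R2* mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`pmqsm` implements a complete processing chain for quantitative
susceptibility mapping (QSM) and R2\* relaxometry of whole, fixed
post-mortem brains acquired with a multi-coil, multi-echo 3D gradient-echo
(GRE) sequence at ultra-high field, together with a physics-based phantom
simulator so that every stage can be validated by parameter recovery
without any real data. This vignette explains the models behind each
stage, the tunable parameters and their defaults, what the simulator does
and does not emulate, and the design decisions that were genuinely open.

# The signal model

For receive coil $c$ and echo time $TE_n$, the complex GRE signal at voxel
$\vec r$ is modelled as

$$ S_c(\vec r, TE_n) = C_c(\vec r)\, M_0(\vec r)\, e^{-TE_n R_2^*(\vec r)}
   \, e^{i\left[\phi_{0,c}(\vec r) + 2\pi \Delta f(\vec r)\, TE_n\right]}
   + \varepsilon, $$

with $C_c$ a smooth complex coil sensitivity, $\phi_{0,c}$ a
time-independent coil phase offset, $\Delta f = \gamma/2\pi \cdot \Delta
B_z$ the frequency offset induced by the susceptibility distribution, and
$\varepsilon$ complex Gaussian noise. The frequency offset is the dipole
convolution of the susceptibility $\chi$; in k-space

$$ \Delta f = f_0\, \mathcal F^{-1}\!\left[ D(\vec k)\, \mathcal F \chi
   \right], \qquad D(\vec k) = \tfrac13 - \frac{(\vec k \cdot \hat
   b)^2}{|\vec k|^2}, \quad D(0) := 0, $$

where $f_0 = \gamma/2\pi \cdot B_0$ converts ppm of field change to Hz
(298.04 Hz/ppm at 7 T). Setting $D(0)=0$ makes the spatial mean of $\chi$
unobservable, which is why susceptibility maps are *relative* and are
referenced to the whole-brain mean at the end of the chain.

Units convention: frequency offsets are carried in Hz throughout; $\chi$
is carried in ppb. The single conversion constant `hz_per_ppm()` is
$\gamma/2\pi \cdot B_0$ with $\gamma/2\pi = 42.577$ MHz/T.

# Pre-processing: coil combination and alignment

Per-coil phase offsets are removed by conjugate-multiplying the first
(short-TE) echo into every later echo, which cancels $\phi_{0,c}$ exactly
and moves the time base to effective echo times $TE'_n = TE_n - TE_1$
(6.6, 13.2, 19.8, 26.4, 33 ms for the default protocol). The
offset-corrected signals are complex-summed over coils; magnitudes are
combined by sum of squares. Whether the complex sum should carry the
natural first-echo magnitude weighting is not determined by the method
description it follows, so `combine_coils(weighting =)` exposes both; the
default keeps the weights (they maximize SNR and cannot reintroduce
offsets, which cancel per coil before the sum).

Scanner frequency drift during the long acquisition translates images
along the phase-encode axis, by an amount growing with echo time, and
misaligns repeats. Two translation-only alignment steps deal with this:

* `align_echoes_first_to_rest()` estimates the phase-encode displacement
  of each later echo relative to the first and resamples the *first* echo
  into each later echo's frame before offset subtraction — the later
  echoes, which feed all downstream stages, are never interpolated.
* `align_repeats()` registers every repeat to the second echo of repeat 1
  with a full 3-vector translation.

Both use cross-correlation of magnitudes; the integer peak is refined by
maximizing the continuous correlation through the Fourier shift theorem
(coordinate-wise golden-section search), and shifts are applied as Fourier
phase ramps, so subvoxel translations are both estimable and exactly
applicable. Rotations are out of scope by design: the brain is held in a
rigid sphere-in-sphere holder, and the drift mechanism produces pure
translations.

High-resolution acquisitions are matched to the rest of a cohort by
`truncate_kspace_slice()`, which center-crops k-space along the slice
axis (e.g. 208 slices at 0.55 mm to 104 at 1.1 mm with factor 2),
preserving the values of band-limited content exactly.

# Field estimation

The frequency offset is estimated per voxel by minimizing the squared
complex residual

$$ \left\| S(TE') - |S(TE')|\, e^{i(\phi_0 + 2\pi \Delta f\, TE')}
   \right\|^2 $$

over the five effective echoes, with the magnitude taken from the data.
The residual offset $\phi_0$ should be near zero after coil combination;
it is retained as a goodness-of-fit channel — large focal $|\phi_0|$
marks voxels (vessels, bubble rims) whose phase cannot be trusted, and
`refine_mask_phi0()` removes them (default threshold 1.0 rad,
config-exposed; no canonical value exists).

The solver is a Levenberg–Marquardt iteration written directly on the
2-parameter normal equations and vectorized across all masked voxels,
which makes the 64³ problem a few seconds of work. For this model the
Gauss–Newton matrix is independent of the parameters, so the iteration is
extremely well behaved; voxels that still fail to converge keep their
initialization and are flagged (they are exactly the $\phi_0$-removal
candidates). `minpack.lm::nls.lm` on single voxels serves as an
independent oracle in the tests.

**Initialization and aliasing.** A frequency offset of
$1/(2 \cdot 6.6\,\mathrm{ms}) = 75.76$ Hz accrues $\pi$ per effective
echo spacing; beyond it, per-echo-pair estimates alias. The fit is
therefore initialized from the *least*-wrapped data available: the phase
difference between the first two effective echoes is spatially unwrapped
(`unwrap_phase_3d()`, quality-guided region growing; quality is the
negative local wrapped-gradient energy) and scaled to Hz, and the
unwrapped first effective echo supplies $\phi_0$. Smooth *local*
excursions beyond the aliasing limit are recovered because region growing
walks into them from sub-limit territory. A *global* super-limit offset
is unobservable from a single spatial snapshot — each connected region's
$2\pi k$ branch is anchored at its seed — and wraps, exactly as
whole-brain mean drift values do.

A linear phase gradient along the readout direction, the image-domain
signature of eddy currents or accumulated readout mistiming, is estimated
per echo from the increment of each echo's phase over the linear
prediction from the first effective echo (per-readout-slab circular means,
then a weighted line fit) and subtracted. Only the *slope* is removed:
removing the intercept would alter the per-echo mean phase and bias the
field estimate. The fit is restricted to the mask.

**Repeats.** The field is fitted per repeat and the maps averaged
(intersection of masks). Averaging maps rather than phase data needs no
drift correction and attenuates any single-repeat artefact by $1/R$. The
per-repeat whole-brain mean offsets and their increments are reported as
the drift diagnostic; with the simulator's default drift of {0, 5, 8, 9}
Hz the increments {5, 3, 1} Hz decrease, emulating a scanner whose
passive-shim temperature settles over the session.

# Background removal and dipole inversion

`vsharp_background_removal()` implements variable-kernel
spherical-mean-value (SMV) filtering: fields harmonic inside the mask —
anything generated by sources outside it — are annihilated by $(1 -
\mathrm{SMV}_\rho)$; sphere radii descend from `max_kernel_mm` (default
12 mm) to one voxel in one-voxel steps, each voxel using the largest
sphere that fits inside the mask, and the filtered field is deconvolved
by the largest kernel's response with Fourier components below
`reg_param` (default 0.02) truncated. Two numerical points matter:

* The sphere kernels are rasterized with a one-voxel partial-volume ramp.
  A hard-thresholded sphere violates the mean-value property at the
  $10^{-1}$ level on typical grids, and the deconvolution amplifies that
  error by up to `1/reg_param`.
* The input to recovery tests must be *harmonic*: the FFT-forward field
  of a hard-edged source carries percent-level Gibbs ringing that is not
  harmonic and that no background-removal method should be expected to
  remove. Validation therefore uses closed-form external sphere fields.

Two properties of v-SHARP shape the test geometry. Sources closer to the
mask edge than the largest kernel radius are distorted by the
variable-kernel scheme, and a mask only a couple of kernel radii across
loses genuine tissue structure along with the background. Both effects
are intrinsic to the method, so recovery tests use phantoms whose
brain-to-kernel size ratio resembles the whole-brain setting.

`tkd_inversion()` divides the field by $D(\vec k)$, replacing
$|D| < \delta$ by $\delta\,\mathrm{sign}(D)$ (threshold $\delta = 0.2$,
the common choice; $\mathrm{sign}(0) := +1$), and by default rescales the
result by the central value of the inversion's point-spread function,
$\overline{D/D_\delta}$ — the standard correction for TKD's systematic
underestimation (about 24% at $\delta = 0.2$; without it a 100 ppb sphere
comes back at ~81 ppb, with it at ~106 ppb).

`streak_reduced_inversion()` is a two-level scheme in the spirit of
streak-artifact-reducing QSM: a first-pass TKD flags strong sources
(|χ| above the 99.5th percentile — air bubbles, vessels), the strong
component is re-estimated with weak regularization (threshold 0.05), its
forward field is subtracted, the residual is inverted with stronger
regularization (threshold 0.25), and the components are summed. The
residual-pass threshold was chosen as the strongest regularization that
keeps the no-strong-source limit within 10% of plain TKD while roughly
an order of magnitude below TKD's tissue error next to a 9.4 ppm bubble.
The contract is this paired inequality, not bit-compatibility with any
reference binary. All inversion parameters are recorded in a JSON
sidecar.

`reference_susceptibility()` subtracts the mean over the (eroded) brain
mask. Lacking any region that can be confidently called pathology-free in
end-stage disease, the whole brain is the least-bad reference; the
operation is idempotent and shift-invariant.

# R2\* mapping

`fit_r2star()` fits $M(TE) = M_0 e^{-TE\,R_2^*} + \mathrm{noise}$ to all
six echo magnitudes per voxel by bounded nonlinear least squares
(non-negativity on all three parameters — the physical choice, since the
method description does not state whether bounds were used). The noise
floor matters when the decay runs into the magnitude background of
multi-channel sum-of-squares data. Two regimes are worth distinguishing,
because they behave differently:

* Magnitudes with a genuine additive floor (as SoS combination of many
  channels produces, floor $\approx \sigma\sqrt{2N_c}$): the floor model
  is clearly less biased (measured at SNR 50, $R_2^* = 40\,$s⁻¹, floor
  50: |bias| ≈ 1.8 vs 3.5 s⁻¹ for the 2-parameter fit).
* Pure single-channel Rician magnitudes at SNR 50 and $R_2^* = 40$ s⁻¹
  never reach the floor within a 35 ms echo train; there the 2-parameter
  fit is nearly unbiased while the 3-parameter estimator pays its
  intrinsic small-sample bias (~+3 s⁻¹, confirmed with a global
  variable-projection optimizer). The floor model is the right default
  for the multi-channel data this pipeline targets, not a universal win.

`assess_t2star_drift()` fits each repeat separately, averages
$T_2^* = 1000/R_2^*$ ms over the mask (voxels with $R_2^* > 1$ s⁻¹, to
avoid dividing by zero), and reports percent change against repeat 1; no
correction is applied below 1% drift, consistent with treating
sub-percent temperature effects as negligible.

# ROI statistics

ROI means are computed after scaled-MAD outlier rejection
(`mad_outlier_filter()`: scaled MAD $= 1.4826 \times$ MAD, exclusion
beyond 3 scaled MADs; an all-equal sample has zero MAD and nothing is
excluded). Stained-area fractions from different staining batches are
standardized within batch (sample SD by default, switchable) before
pooling. The correlation layer provides Pearson $r$ with two-tailed $p$
and first-order partial correlation by double OLS residualization (equal
to the closed-form formula; $p$ on $n-3$ degrees of freedom). Group
contrasts use Welch's $t$ with Satterthwaite degrees of freedom and
Hedges's $g$ (pooled-SD Cohen's $d$ times $J = 1 - 3/(4\nu - 1)$,
$\nu = n_a + n_b - 2$). All $p$-values are two-tailed with $\alpha =
0.05$ and no multiple-testing correction is applied — a deliberate
mirror of the analysis style this package supports, stated here so no
one mistakes the omission for an accident. Fixative composition is
handled as an indicator covariate via `regress_out_covariate()`, which
restores the grand mean so residualized values keep their units.

# The simulator: what it emulates, and what it does not

`phantom_spec()` + `build_phantom()` + `simulate_acquisition()` produce a
brain-shaped two-compartment ellipsoid (white core, grey shell) with a
cortical-ribbon patch emulating a focal M1 hyperintensity, immersed in a
susceptibility-matched signal-free surround inside a spherical container,
with optional air bubbles (9.4 ppm, signal voids). Artefact knobs: smooth
complex coil sensitivities with constant per-coil offsets, additive
complex Gaussian noise (Rician magnitudes arise naturally), per-repeat
frequency drift, and phase-encode translations of echoes and repeats
applied by Fourier phase ramps (subvoxel).

Defaults are the study conditions where those are stated — TEs 2–35 ms at
6.6 ms effective spacing, 7 T, four repeats, drift {0, 5, 8, 9} Hz with
decreasing increments and correspondingly decreasing inter-repeat
translations — and desk-scale choices where they are not: grid 48³ at
2 mm with 4 coils (the real acquisition is 384×310×208 at 0.5 mm with 32
channels, far beyond a laptop-sized test), SNR ≈ 50, tissue values
(surround 0, white −30, grey +20, ribbon +50 ppb; R2\* 50/40/50 s⁻¹)
that are plausible for fixed tissue at 7 T but deliberately
config-exposed rather than canonical, since no ground-truth post-mortem
values exist to copy.

Not emulated: k-space undersampling/GRAPPA (simulated data are fully
sampled per coil; the reconstruction problem is out of scope), gradient
nonlinearity, physical temperature modelling (drift is prescribed, not
simulated thermally), partial-volume tissue interfaces (labels are
crisp), susceptibility anisotropy, and microstructure-induced non-linear
phase evolution. Passing recovery tests therefore demonstrates the
correctness of the processing chain under its own forward model, not
robustness to every failure mode of real tissue data.

# Problem sizes and determinism

The bundled tests and the acceptance script run phantoms between 24³ and
80³ voxels: large enough that the brain is several v-SHARP kernel radii
across (the regime the method is designed for), small enough for a
single-CPU desk run. The cohort-direction study uses 9 diseased vs 3
control subjects at 32³ and 20 replicates — enough to check the *sign*
of the ribbon effect; cohort-level magnitudes would need the real data.
Every stochastic step is seeded; simulation and pipeline are bit-
reproducible for a fixed seed, and the pipeline writes a JSON provenance
sidecar (parameters, package version, seed) next to its artifacts.

# Known limitations

* Inter-region $2\pi$ branch selection in unwrapping is unconstrained by
  construction; disconnected mask islands may carry different global
  offsets (they are excluded from a single brain mask in practice by the
  largest-component rule).
* v-SHARP distorts sources within one kernel radius of the mask edge and
  high-passes tissue structure on masks comparable to the kernel size;
  both are properties of the method, inherited faithfully.
* The additive noise-floor model is an approximation to the quadrature
  floor of sum-of-squares magnitudes; see the R2\* section.
* Translation-only registration cannot absorb rotations or deformations;
  it matches the rigid-holder acquisition it models.
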