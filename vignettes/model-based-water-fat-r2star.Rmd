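---
title: "Model-based water-fat, R2* and B0 mapping from multi-echo radial k-space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based water-fat, R2* and B0 mapping from multi-echo radial k-space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wfr2star)
```

## The problem

Quantitative R2* mapping estimates the effective transverse relaxation rate
(R2* = 1/T2*) from images acquired at several echo times. In moving subjects
— the motivating application is fetal brain imaging at 3 T — Cartesian
multi-echo protocols are impractical and EPI readouts suffer geometric
distortion, so the acquisition of interest is a single-slice multi-echo
radial FLASH shot lasting about two seconds, in which every echo samples only
a small number of radial spokes. Surrounding maternal tissue contains fat,
whose multi-resonance spectrum modulates the signal across echoes, and the
main field is never perfectly homogeneous, so a faithful signal model needs
four voxelwise unknowns: complex water `W`, complex fat `F`, the relaxation
rate `R2*`, and the off-resonance field `fB0`:

`M(TE) = (W + F z(TE)) exp(i 2 pi fB0 TE) exp(-TE R2*)`

with `z(TE)` the six-peak fat spectral weight (`fat_modulation()`). Because
each echo is massively undersampled, the maps cannot be estimated echo by
echo; instead the package solves the joint nonlinear inverse problem that
maps all parameter maps and the (unknown) coil sensitivity profiles directly
to the measured multi-coil k-space, a calibrationless model-based
reconstruction.

## Sampling scheme

`build_trajectory()` implements the blip-gradient multi-echo radial scheme:
within one frame of `NS` shots and `NE` echoes the spoke of shot `l`, echo
`m` sits at angle `2 pi ((l-1) NE + m - 1) / (NE NS)`, so the union of all
shots and echoes covers the circle uniformly while consecutive echoes within
a shot advance by a single elementary increment. Consecutive frames are
rotated by the second-order golden angle `180 / phi^2 = 68.75` degrees
(`frame_angle_offset()`). The reference protocol uses 30 shots and 35 echoes
(1050 spokes per slice) with TE1 = 2.37 ms and 1.88 ms echo spacing; the
echo times are the arithmetic sequence `TE1 + (m-1) dTE` throughout (the
implied 35th echo time is 66.29 ms). Echo trains are arithmetic by
construction, which has one modelling consequence worth noting: the signal
model is then exactly periodic in `fB0` with period `1/dTE`, a degeneracy
the voxelwise fitter resolves by reporting the in-band equivalent (see
below).

## Objective and solver

`irgnm_fista()` estimates `x = (W, F, R2*, fB0, c_1..c_K)` by minimizing

`1/2 sum_TE || P F ( C . M_TE(x_p) ) - Y_TE ||^2 + alpha R(x)`   subject to `R2* >= 0`,

where `P` is the radial sampling pattern, `F` the Fourier transform and `C`
the coil profiles. The regularizer combines a joint l1-wavelet penalty on
`(W, F, R2*)` (group soft-thresholding of Daubechies-4 coefficients across
the three maps, `joint_l1_prox()`; the coarsest approximation band is not
penalized) with quadratic Sobolev smoothness on `fB0` and on each coil map,
`w(k) = (1 + s ||k||^2)^(l/2)` with `s = 22 mm^2`, `l = 4` for the field
map and the much harsher classical weight `(1 + 220 ||k||^2)^16` (k in
cycles/pixel) for the coils. Field and coil maps are parameterized in the
preconditioned domain `x = F^-1 { w^-1 F x_hat }`, which turns the Sobolev
terms into plain l2 penalties on `x_hat`.

The outer loop is an iteratively regularized Gauss-Newton method: at step
`n` the forward operator is linearized and the subproblem solved with FISTA
(step size from a warm-started power iteration on the normal operator,
proximal maps as above, R2* clamped to `[0, r2s_max]` every iteration). The
regularization weight follows `alpha_n = max(alpha_min, alpha0 / 3^n)` with
`alpha0 = 1` and `alpha_min = 0.002`; the early heavily-regularized steps
mostly establish the coil profiles and a low-resolution object, and the
maps sharpen as alpha decays. The same `alpha` also weights an adaptive
Levenberg-Marquardt damping term `alpha ||x - x_n||^2` on the map channels
inside each subproblem; a step that still increases the data misfit is
rejected and re-solved with boosted damping. The damping vanishes with the
schedule and does not bias the converged solution, but keeps each
Gauss-Newton update inside the validity region of the linearized
exponentials — without it the strongly nonlinear field and relaxation
channels overshoot in the middle of the schedule.

### Off-resonance: pre-estimation and swap correction

The field map is the one unknown with a genuinely multi-modal landscape:
beyond roughly `1/(2 te_max)` of field error the late echoes wrap, and the
dominant fat resonance, aliased into the band of the echo spacing, mimics
a shifted water line (the classical fat-water swap). Three measures make
the estimate robust across the full `+/- 1/(2 dTE)` band:

1. **Calibrationless field pre-estimation.** The ramp-weighted adjoint
   images of the data are quick-look gridded echo images; the
   coil-phase-free combination `J_m = sum_k q_km conj(q_k1)` follows the
   voxel signal model with all constant factors absorbed into W and F, so
   the multi-start voxelwise fitter (`fit_voxel_complex()`) recovers the
   off-resonance and R2* per coarse block before the first Gauss-Newton
   step. The estimates, mildly smoothed, initialize the field and
   relaxation channels.
2. **Reference-centred field penalty.** The quadratic penalty on the
   preconditioned field channel is centred at that initial estimate (the
   classical IRGNM reference choice); centring it at zero would erase the
   pre-estimate during the strongly regularized early steps.
3. **Model-subtracted swap polish.** Gridded pre-fits cannot decide the
   water/fat hypothesis where point-spread leakage from slowly-decaying
   neighbours dominates a rapidly-decaying voxel. Near the end of the
   schedule, voxels whose coil-combined model residual remains comparable
   to their own modelled signal energy are re-fitted voxelwise on
   leakage-cleaned signals (data residual plus the voxel's modelled
   self-term); a changed field hypothesis is written back and refined by
   the remaining outer steps.

An optional echo-time continuation (`echo_ladder`) that grows the active
echo set over the outer iterations is available as an alternative
coarse-to-fine strategy, but is off by default: the pre-estimated field
makes it unnecessary.

### Numerical design choices

Several choices matter for convergence and are worth recording:

- **Toeplitz embedding.** All inner iterations apply the normal operator
  `A^H A` of each echo's sampling pattern as an FFT convolution on the
  2x-padded grid (`toeplitz_plan()`); for full radial spokes with integer
  sample radii the point-spread kernel is a sum of Dirichlet kernels,
  evaluated in closed form to machine precision. No gridding happens inside
  the iteration; the gridding NUFFT (Kaiser-Bessel, 2x oversampling,
  accuracy ~1e-7) is used once to form the adjoint images of the data.
- **Density-preconditioned data term.** The inner solves use a ramp
  density-compensated metric `||D^(1/2)(A x - y)||` (weights `max(|k|, 0.5)`
  along each spoke). The weighted radial normal operator is approximately
  the identity, which conditions the FISTA subproblems; for consistent data
  the minimizer is unchanged, and the added noise-weighting is immaterial
  at the noise levels and ROI-mean statistics of interest. The public
  `toeplitz_normal()` operator remains the plain (unweighted) normal
  operator.
- **Normalization and channel scales.** The weighted data norm is scaled to
  100 and the full linearized operator at the initial state to unit
  spectral norm, so the alpha schedule acts on a fixed scale. The water/fat
  channels are anchored to the measured image amplitude (the 95th
  percentile of the coil-combined adjoint image), which also pins the
  otherwise gauge-free split of magnitude between object and coils at
  initialization; R2* and fB0 channels are scaled by `1/te_rms` and
  `1/(2 pi te_rms)` respectively, so all Jacobian channels present
  comparable curvature to the inner solver. These are the defaults of
  `recon_config()`; explicit values can be supplied.
- **Initialization.** `W = 1` (constant), everything else zero. A fully
  zero start is a fixed point of the bilinear object-coil system — no
  channel has a nonzero Jacobian there — so the water channel must carry
  the initial signal. With zero data the converged object signal, fat,
  field and coil maps are all zero while `W` retains its unpenalized
  constant component; the physically meaningful outputs vanish.
- **Iteration counts.** Defaults are `n_gn = 20` outer steps with
  `n_fista = 50` inner iterations (the last five steps anneal the data
  metric as described above); with the field pre-estimation the
  alpha-floor steps refine rather than search, and the budget is set by
  the slowest (relaxation-rate) channel.
- **Degenerate inputs.** Divergence (weighted misfit growing in two
  consecutive outer steps) raises an error with diagnostics; `r2s_max`
  (500 1/s) bounds the feasible-set projection.

## The analytic phantom

`make_numerical_phantom()` reproduces the validation object: ten circular
tubes (radius 9 mm on a 33 mm ring) in a 50 mm background disk, 128 mm FOV.
Tube fat fractions run 5-95 % in 10 % steps, T2* values 10-190 ms in 20 ms
steps (an alternative R2* grid 10-190 1/s is selectable), and off-resonance
covers -50..50 Hz in 10 Hz steps, with 0 Hz carried by the water-only
background (R2* = 20 1/s, W = 1) and the ten remaining values assigned to
the tubes monotonically along x — B0 inhomogeneity is a smooth, shim-like
function of space, so neighbouring tubes differ by at most 20 Hz rather
than jumping across the full range.
`simulate_kspace()` computes the k-space of this piecewise-elliptical
object analytically — `ellipse_ft()` is the closed-form Bessel-function
Fourier transform of an ellipse — so no rasterization enters the data
generation ("no inverse crime"): coil weighting is exact too, because the
simulated coils are truncated Fourier series (`simulate_coils()`) whose
products with the object are frequency shifts of the analytic transform.
Tubes fully inside the background replace it by signal differencing;
disjoint regions add. Complex Gaussian noise (sd 0.1 per real and
imaginary component) is added per coil and sample; the data stays in
natural analytic units (the background disk's DC value is its area,
about 7.9e3 mm^2), the scale at which that noise level corresponds to the
near-noiseless regime of the reference validation.

What the phantom does not emulate: motion, gradient-delay/eddy-current
errors, slice profiles, coil noise correlation, and the smooth anatomy of
real tissue — passing the phantom validation demonstrates correctness of
the forward model, operators and solver, not robustness to those effects.

## Validation pipeline

`run_acceptance_phantom()` chains simulation, reconstruction and analysis:
per-tube means over central ROIs (half the tube radius,
`tube_roi_masks()`) are compared against ground truth with Bland-Altman
statistics (`bland_altman()`), and the reported biases are required to stay
within 0.5 % (fat fraction), 1.0 1/s (R2*) and 0.5 Hz (B0). The default
problem size of the validation run is a 96-pixel grid with the full
30-shot, 35-echo protocol and 8 coils. The voxelwise reference fitters
(`fit_voxel_complex()`, multi-started over the off-resonance alias band;
`fit_magnitude_exp()` for magnitude-only EPI-style fitting) and the
agreement statistics (`icc_agreement()`, ICC(A,1) — two-way,
absolute-agreement, single measurement, chosen because the comparisons are
between absolute quantitative values) support the same kinds of comparisons
on user data.

The validation is deliberately free of inverse crime: the simulated data
are samples of the continuous object's Fourier transform, while the
reconstruction models a discrete grid. At the default 96-pixel validation
scale the resulting model mismatch (a few percent of signal energy,
concentrated at tissue boundaries) leaves visible traces in the ROI
statistics: the water/fat split carries anticorrelated voxel jitter whose
magnitude rectification biases high fat fractions low by several percent
(the complex-mean fat fraction stays accurate), and mid-range R2* values
absorb one to a few 1/s of apparent decay. The off-resonance map is
robust to all of this. These effects shrink with grid size; the original
validation scale of 192 pixels is several times more expensive than the
default configuration.

## Known limitations

- 2D single-slice only; no stack-of-stars or simultaneous multi-slice.
- A single R2* per voxel (no separate water/fat relaxation), and no T1 or
  flip-angle dependence (the FLASH steady-state amplitude is absorbed into
  W and F).
- Off-resonance beyond +/-1/(2 dTE) aliases irreducibly for arithmetic
  echo trains; within the band, robustness rests on the field
  pre-estimation and swap polish described above.
- Gradient-delay estimation for measured scanner data is out of scope; the
  pipeline expects trajectory-consistent k-space.
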