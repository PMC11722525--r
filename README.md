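# wfr2star

Calibrationless model-based reconstruction of **water, fat, R2\* and B0
maps** (plus coil sensitivities) directly from undersampled multi-echo
**radial FLASH** k-space, together with the blip-gradient radial trajectory
design and an analytic numerical-phantom simulator that makes the whole
method verifiable without scanner data.

The intended users are MRI reconstruction researchers working on
quantitative parameter mapping in moving subjects (the motivating
application is distortion-free R2\* mapping of the fetal brain at 3 T from
a 2-second single-slice acquisition), and anyone who needs a reproducible,
fully synthetic test bed for water-fat-R2\*-B0 estimation.

## The model

Each voxel follows the multi-peak water-fat signal model

```
M(TE) = (W + F z(TE)) exp(i 2 pi fB0 TE) exp(-TE R2*)
```

where `W`, `F` are complex water/fat components, `z(TE)` the six-peak fat
spectral weight, `fB0` the off-resonance (Hz) and `R2*` the effective
relaxation rate (1/s). The acquisition samples each echo on a few radial
spokes (angle `2 pi ((l-1) NE + m - 1) / (NE NS)` for shot `l`, echo `m`;
frames rotate by the small golden angle 68.75°). All maps and the coil
profiles `c_k` are estimated jointly from the k-space data `y` by
an iteratively regularized Gauss-Newton method (IRGNM) with a FISTA inner
solver:

```
min_x  1/2 sum_TE || P F ( C . M_TE(x) ) - Y_TE ||^2
       + alpha ( joint-l1-wavelet(W, F, R2*) + Sobolev(fB0) + Sobolev(C) ),
       R2* >= 0,  alpha_n = max(0.002, 3^-n)
```

See the vignette (`vignettes/model-based-water-fat-r2star.Rmd`) for the
solver's numerical design (Toeplitz point-spread-function embedding,
density-preconditioned inner metric, echo-time continuation for the
phase-wrap-prone field map, adaptive Levenberg-Marquardt damping).

## Worked example

Simulate the ten-tube numerical phantom (fat fractions 5-95 %, T2*
10-190 ms, off-resonance -50..50 Hz, 8 coils, complex noise sd 0.1),
reconstruct it, and compare tube ROI means against ground truth:

```r
library(wfr2star)
rep <- run_acceptance_phantom(base_resolution = 96, seed = 1)
round(rep$per_tube, 2)
rep$bias
```

```
#>        tube     ff  r2star     fb0 ff_true r2star_true fb0_true
#> tube01    1 20.491 100.066  47.216       5     100.000       50
#> tube02    2 14.834  35.064  39.742      15      33.333       40
#> tube03    3 25.398  23.370  19.783      25      20.000       20
#> tube04    4 35.481  16.766 -10.118      35      14.286      -10
#> tube05    5 43.662  15.993 -30.005      45      11.111      -30
#> tube06    6 56.674  10.877 -49.916      55       9.091      -50
#> tube07    7 63.658  10.175 -39.699      65       7.692      -40
#> tube08    8 70.212   6.652 -20.074      75       6.667      -20
#> tube09    9 77.940   5.346  10.043      85       5.882      10
#> tube10   10 85.380   7.197  30.094      95       5.263      30
#>         ff     r2star        fb0
#> -0.6269917  1.8182432 -0.2934175
```

(column `ff` is the reconstructed ROI-mean fat fraction in percent,
`r2star` in 1/s, `fb0` in Hz; `rep$bias` holds the mean differences over
the ten tubes, `rep$sd` their SDs, `rep$pass` the check against the
0.5 % / 1.0 s^-1 / 0.5 Hz limits). At this reduced 96-pixel scale the
off-resonance bias meets its limit; the fat-fraction and R2* biases
remain above their strictest limits, dominated by the discretization
mismatch between the continuous-object simulation and the reduced
reconstruction grid — see the vignette's limitations section.

A command-line interface wrapping the same functions (subcommands
`simulate`, `recon`, `fit`, `analyze`, `accept`, YAML-configured) ships at
`inst/cli/wfr2star`; file formats are documented in `inst/FORMATS.md`.

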