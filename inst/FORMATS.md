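# File formats

## K-space container (`write_kspace` / `read_kspace`)

A single self-describing file (R serialization) with a format-version tag
`wfr2star-kspace-1` and four groups, mirroring the layout of common raw-data
containers so that data and sampling pattern never separate:

| group    | content |
|----------|---------|
| `data`   | complex array `[coil, echo, spoke, sample]` |
| `traj`   | the radial trajectory: `n_shots`, `n_echoes`, `samples_per_spoke`, `n_frames`, `angles` (shot x echo x frame, radians), `frame_offsets` (degrees), `coords` (per echo: spoke x sample x 2, cycles/FOV) |
| `echoes` | `te_first`, `delta_te` (ms), `n_echoes` |
| `meta`   | named list; required: `fov_mm`; typical: `noise_sd`, `seed`, `scale`, `provenance`, `coil_compression_energy` |

Reading validates the version tag and the presence and dimensional
consistency of every group.

## Trajectory export (`write_trajectory`)

Tab-separated plain text with columns `echo`, `spoke`, `sample`, `kx`, `ky`;
coordinates in cycles/FOV, range `[-N/2, N/2]`, centre sample of every spoke
at `(0, 0)`.

## Parameter maps (`write_maps` / `read_maps`)

One NIfTI volume per map, suffixes:

- `_water_real`, `_water_imag`, `_fat_real`, `_fat_imag` — complex water and
  fat components as real/imaginary pairs (arbitrary signal units)
- `_r2star` — effective relaxation rate, 1/s, non-negative
- `_fb0` — off-resonance field, Hz
- `_fatfrac` — fat fraction `|F|/(|W|+|F|) * 100` in percent (0/0 voxels are 0)

The NIfTI `pixdim` encodes the in-plane voxel size `fov_mm / n`.

## Statistics output (CLI `analyze`)

- `*_roi_stats.csv`: per-ROI `mean`/`sd` of both input maps
- `*_agreement.csv`: Bland-Altman `mean_diff`, `sd_diff`, limits of
  agreement, and ICC(A,1)
- `*_bland_altman_points.csv`: the per-ROI paired means for plotting

## CLI configuration (YAML)

Common keys: `seed`, `base_resolution`, `n_shots`, `n_echoes`, `te_first`,
`delta_te`, `n_coils`, `noise_sd`, `fat_spectrum` (`shifts_ppm`,
`amplitudes`, `hz_per_ppm`). Reconstruction keys mirror `recon_config()`:
`alpha0`, `alpha_min`, `reduction_factor`, `n_gn`, `n_fista`, `sobolev_s`,
`sobolev_l`, `wavelet_levels`, `r2s_max`, `with_fat`, plus
`n_virtual_coils` for coil compression and `input` (k-space container
path). `fit` takes `input_prefix` of per-echo NIfTI pairs
(`_echoNN_{real,imag}.nii.gz`); `analyze` takes `map_x`, `map_y`, `labels`
(NIfTI label image, 0 = background).
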