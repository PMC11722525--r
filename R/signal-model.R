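#' Multi-peak fat spectrum
#'
#' Chemical-shift spectrum of fat relative to water. The default is the
#' standard six-peak liver fat model (methyl/methylene and olefinic
#' resonances); amplitudes are normalized to sum to one at construction.
#'
#' @param peak_shifts_ppm Chemical shifts in ppm relative to water
#'   (negative = lower frequency than water).
#' @param peak_amplitudes Relative amplitudes (non-negative); normalized
#'   internally.
#' @param hz_per_ppm Resonance-frequency scale in Hz/ppm. The default
#'   127.73 Hz/ppm corresponds to a nominal 3.0 T field.
#' @return Object of class `fat_spectrum`.
#' @export
fat_spectrum <- function(peak_shifts_ppm = c(-3.80, -3.40, -2.60, -1.94, -0.39, 0.60),
                         peak_amplitudes = c(0.087, 0.693, 0.128, 0.004, 0.039, 0.048),
                         hz_per_ppm = 127.73) {
  stopifnot(length(peak_shifts_ppm) == length(peak_amplitudes),
            all(is.finite(peak_shifts_ppm)),
            all(peak_amplitudes >= 0), sum(peak_amplitudes) > 0,
            hz_per_ppm > 0)
  structure(
    list(peak_shifts_ppm = as.numeric(peak_shifts_ppm),
         peak_amplitudes = as.numeric(peak_amplitudes) / sum(peak_amplitudes),
         hz_per_ppm = hz_per_ppm),
    class = "fat_spectrum"
  )
}

#' Fat spectral modulation at an echo time
#'
#' The complex weight `z(TE) = sum_p a_p * exp(i*2*pi*f_p*TE)` with
#' `f_p = shift_p * hz_per_ppm`. Because the amplitudes sum to one,
#' `|z| <= 1` and `z(0) = 1`.
#'
#' @param spectrum A [fat_spectrum()].
#' @param te_ms Echo time(s) in ms (>= 0). Vectorized.
#' @return Complex vector, one value per echo time.
#' @export
fat_modulation <- function(spectrum, te_ms) {
  stopifnot(inherits(spectrum, "fat_spectrum"), all(te_ms >= 0))
  f_hz <- spectrum$peak_shifts_ppm * spectrum$hz_per_ppm
  te_s <- te_ms / 1000
  # outer sum over peaks for each echo time
  drop(exp(1i * 2 * pi * outer(te_s, f_hz)) %*% spectrum$peak_amplitudes)
}

#' Parameter maps of the water-fat signal model
#'
#' Container for the voxelwise unknowns: complex water and fat components,
#' the effective relaxation rate R2* (1/s, non-negative) and the B0
#' off-resonance field (Hz). All maps share one grid.
#'
#' @param water Complex matrix (arbitrary signal units).
#' @param fat Complex matrix, same shape; default all-zero (water only).
#' @param r2star Real matrix in 1/s (>= 0); scalar recycled. Default 0.
#' @param fb0 Real matrix in Hz; scalar recycled. Default 0.
#' @return Object of class `parameter_maps`.
#' @export
parameter_maps <- function(water, fat = NULL, r2star = 0, fb0 = 0) {
  water <- as.matrix(water)
  storage.mode(water) <- "complex"
  dm <- dim(water)
  expand <- function(x, complex = FALSE) {
    if (is.null(x)) x <- 0
    if (length(x) == 1L) x <- matrix(x, dm[1], dm[2])
    x <- as.matrix(x)
    stopifnot(identical(dim(x), dm))
    storage.mode(x) <- if (complex) "complex" else "double"
    x
  }
  fat <- expand(fat, complex = TRUE)
  r2star <- expand(r2star)
  fb0 <- expand(fb0)
  if (any(r2star < 0)) stop("r2star must be non-negative everywhere")
  structure(list(water = water, fat = fat, r2star = r2star, fb0 = fb0),
            class = "parameter_maps")
}

#' Evaluate the multi-echo water-fat signal model
#'
#' Voxelwise model `M(TE) = (W + F*z(TE)) * exp(i*2*pi*fB0*TE) *
#' exp(-TE*R2*)`, with `z` the fat spectral modulation. Off-resonance
#' phase accrues with a positive sign; fat peaks have negative ppm shifts
#' so fat precesses at lower frequency. Echo times are in ms at the
#' interface and converted to seconds internally (R2* in 1/s, fB0 in Hz).
#'
#' @param maps A [parameter_maps()] object.
#' @param te_ms Echo time in ms (scalar).
#' @param spectrum A [fat_spectrum()]; default the six-peak model.
#' @return Complex matrix, the modelled echo image.
#' @export
echo_image <- function(maps, te_ms, spectrum = fat_spectrum()) {
  stopifnot(inherits(maps, "parameter_maps"), length(te_ms) == 1L, te_ms >= 0)
  if (any(maps$r2star < 0)) stop("r2star must be non-negative")
  z <- fat_modulation(spectrum, te_ms)
  te_s <- te_ms / 1000
  (maps$water + maps$fat * z) *
    exp((1i * 2 * pi * maps$fb0 - maps$r2star) * te_s)
}

#' Analytic derivatives of the signal model
#'
#' Partial derivatives of `echo_image()` with respect to the four unknowns,
#' needed by the Gauss-Newton linearization:
#' `dM/dW = E`, `dM/dF = z*E`, `dM/dR2* = -TE*(W+F*z)*E`,
#' `dM/dfB0 = i*2*pi*TE*(W+F*z)*E`, with
#' `E = exp(i*2*pi*fB0*TE) * exp(-TE*R2*)` and TE in seconds.
#'
#' @inheritParams echo_image
#' @return List of four complex matrices `dW`, `dF`, `dR2star`, `dFb0`
#'   (per 1/s and per Hz respectively).
#' @export
signal_jacobian <- function(maps, te_ms, spectrum = fat_spectrum()) {
  stopifnot(inherits(maps, "parameter_maps"), length(te_ms) == 1L, te_ms >= 0)
  if (any(maps$r2star < 0)) stop("r2star must be non-negative")
  z <- fat_modulation(spectrum, te_ms)
  te_s <- te_ms / 1000
  E <- exp((1i * 2 * pi * maps$fb0 - maps$r2star) * te_s)
  B <- (maps$water + maps$fat * z) * E
  list(dW = E, dF = z * E, dR2star = -te_s * B, dFb0 = 1i * 2 * pi * te_s * B)
}

#' Fat fraction of parameter maps
#'
#' `|F| / (|W| + |F|) * 100` in percent, with the 0/0 convention mapping
#' empty voxels to 0.
#'
#' @param maps A [parameter_maps()] object.
#' @return Real matrix of fat fractions in percent.
#' @export
fat_fraction <- function(maps) {
  stopifnot(inherits(maps, "parameter_maps"))
  aw <- Mod(maps$water); af <- Mod(maps$fat)
  den <- aw + af
  ff <- ifelse(den > 0, af / den, 0)
  100 * ff
}
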