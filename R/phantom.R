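#' Analytic Fourier transform of an ellipse
#'
#' Closed-form continuous 2D Fourier transform of the indicator function of
#' an ellipse: `a*b*J1(2*pi*rho)/rho * exp(-i*2*pi*k.c)` with
#' `rho = sqrt((a*kx)^2 + (b*ky)^2)` and J1 the first-order Bessel
#' function; the DC value is the area `pi*a*b`.
#'
#' @param semi_axes Length-2 vector (a, b) in mm, positive.
#' @param center Length-2 vector (x, y) in mm.
#' @param k m x 2 matrix of spatial frequencies in cycles/mm.
#' @return Complex vector of length m.
#' @export
ellipse_ft <- function(semi_axes, center, k) {
  stopifnot(length(semi_axes) == 2L, all(semi_axes > 0), length(center) == 2L)
  if (!is.matrix(k)) k <- matrix(k, ncol = 2L)
  a <- semi_axes[1]; b <- semi_axes[2]
  rho <- sqrt((a * k[, 1])^2 + (b * k[, 2])^2)
  amp <- numeric(length(rho))
  small <- rho < 1e-12
  amp[!small] <- a * b * besselJ(2 * pi * rho[!small], 1) / rho[!small]
  amp[small] <- pi * a * b
  amp * exp(-1i * 2 * pi * (k[, 1] * center[1] + k[, 2] * center[2]))
}

#' Numerical water-fat phantom specification
#'
#' Ten circular tubes inside a circular background, spanning fat fractions
#' 5-95 % (step 10 %), off-resonance -50..50 Hz (step 10 Hz; 0 Hz is
#' carried by the background so that the eleven regions cover the full
#' grid), and a T2* grid of 10-190 ms in 20 ms steps (equivalently R2*
#' 100 down to 5.26 1/s). The background is water-only with R2* = 20 1/s.
#' An alternative R2* grid (10-190 1/s, step 20) is selectable.
#'
#' @param base_resolution Nominal acquisition matrix (pixels); default 192.
#' @param fov_mm Field of view in mm; default 128.
#' @param relaxation_grid `"t2star"` (default: T2* 10-190 ms step 20 ms) or
#'   `"r2star"` (R2* 10-190 1/s step 20 1/s).
#' @return Object of class `phantom_spec`: list with `fov_mm`,
#'   `base_resolution` and `regions` (first region is the background; each
#'   region has `center`, `semi_axes`, `water` and `fat` amplitudes,
#'   `r2star`, `fb0`).
#' @export
make_numerical_phantom <- function(base_resolution = 192L, fov_mm = 128,
                                   relaxation_grid = c("t2star", "r2star")) {
  relaxation_grid <- match.arg(relaxation_grid)
  n_tubes <- 10L
  ff <- seq(5, 95, by = 10)
  r2s <- switch(relaxation_grid,
                t2star = 1000 / seq(10, 190, by = 20),
                r2star = seq(10, 190, by = 20))
  fb0_pool <- c(seq(-50, -10, by = 10), seq(10, 50, by = 10))
  ring_r <- 33; tube_r <- 9; bg_r <- 50
  ang <- 2 * pi * (seq_len(n_tubes) - 1) / n_tubes
  centers <- cbind(ring_r * cos(ang), ring_r * sin(ang))
  # B0 inhomogeneity is a smooth function of space (shim-like); the grid
  # values are assigned monotonically along x so the phantom field is
  # spatially coherent rather than jumping 100 Hz between neighbours
  ord <- order(round(centers[, 1], 9), centers[, 2])
  fb0 <- numeric(n_tubes)
  fb0[ord] <- fb0_pool
  regions <- vector("list", n_tubes + 1L)
  regions[[1]] <- list(center = c(0, 0), semi_axes = c(bg_r, bg_r),
                       water = 1, fat = 0, r2star = 20, fb0 = 0)
  for (j in seq_len(n_tubes)) {
    regions[[j + 1L]] <- list(
      center = centers[j, ],
      semi_axes = c(tube_r, tube_r),
      water = 1 - ff[j] / 100,
      fat = ff[j] / 100,
      r2star = r2s[j],
      fb0 = fb0[j]
    )
  }
  structure(list(fov_mm = fov_mm, base_resolution = as.integer(base_resolution),
                 regions = regions),
            class = "phantom_spec")
}

# complex tissue signal of one region at the given echo times (ms)
.region_signal <- function(region, te_ms, spectrum) {
  z <- fat_modulation(spectrum, te_ms)
  te_s <- te_ms / 1000
  amp <- region$water + region$fat * z
  amp * exp((1i * 2 * pi * region$fb0 - region$r2star) * te_s)
}

#' Pixel coordinates of the reconstruction grid
#'
#' Pixel i (1-based) sits at `(i - 1 - n/2) * fov/n` mm, so the grid origin
#' coincides with the k-space phase origin of the NUFFT convention.
#'
#' @param n Grid size.
#' @param fov_mm Field of view in mm.
#' @return Vector of n coordinates in mm.
#' @export
grid_coords <- function(n, fov_mm) {
  (seq_len(n) - 1 - n %/% 2) * fov_mm / n
}

# area-weighted coverage fraction of an ellipse on the pixel grid
.ellipse_coverage <- function(region, n, fov_mm, supersample = 4L) {
  dx <- fov_mm / n
  x0 <- grid_coords(n, fov_mm)
  off <- ((seq_len(supersample) - 0.5) / supersample - 0.5) * dx
  xs <- as.vector(outer(off, x0, `+`))   # subpixel centres, pixel-major
  a <- region$semi_axes[1]; b <- region$semi_axes[2]
  u <- (xs - region$center[1]) / a
  v <- (xs - region$center[2]) / b
  inside <- outer(u^2, v^2, `+`) <= 1
  idx <- rep(seq_len(n), each = supersample)
  m <- t(rowsum(t(rowsum(inside + 0, idx, reorder = FALSE)), idx, reorder = FALSE))
  m / supersample^2
}

#' Rasterize phantom ground truth onto a pixel grid
#'
#' Region coverage fractions are computed with subpixel area weighting;
#' tubes override the background. Returns both per-region coverage maps
#' and piecewise-constant parameter maps (partial-volume voxels carry the
#' area-weighted mix, which is the physically correct signal mixing for
#' the linear components).
#'
#' @param phantom A [make_numerical_phantom()]-style `phantom_spec`.
#' @param n Grid size.
#' @param supersample Subpixel sampling factor per axis (default 4).
#' @return List with `coverage` (list of matrices, one per region, tubes
#'   already subtracted from the background) and `maps`, a
#'   [parameter_maps()] object of the dominant-region parameters.
#' @export
rasterize_phantom <- function(phantom, n, supersample = 4L) {
  stopifnot(inherits(phantom, "phantom_spec"))
  fov <- phantom$fov_mm
  regs <- phantom$regions
  cov <- lapply(regs, .ellipse_coverage, n = n, fov_mm = fov,
                supersample = supersample)
  if (length(regs) > 1L) {
    tube_sum <- Reduce(`+`, cov[-1])
    cov[[1]] <- pmax(cov[[1]] - tube_sum, 0)
  }
  W <- matrix(0, n, n); Fm <- matrix(0, n, n)
  R2 <- matrix(0, n, n); B0 <- matrix(0, n, n); tot <- matrix(0, n, n)
  for (j in seq_along(regs)) {
    r <- regs[[j]]
    W <- W + cov[[j]] * r$water
    Fm <- Fm + cov[[j]] * r$fat
    R2 <- R2 + cov[[j]] * r$r2star
    B0 <- B0 + cov[[j]] * r$fb0
    tot <- tot + cov[[j]]
  }
  nz <- tot > 1e-6
  R2[nz] <- R2[nz] / tot[nz]
  B0[nz] <- B0[nz] / tot[nz]
  list(coverage = cov,
       maps = parameter_maps(W, Fm, R2, B0))
}

#' Central-disk ROI masks for the phantom tubes
#'
#' One mask per tube, a disk of half the tube radius at the tube centre
#' (placed centrally to avoid partial-volume voxels at the rim).
#'
#' @param phantom A `phantom_spec`.
#' @param n Grid size of the maps.
#' @param fraction Fraction of the tube radius to keep (default 0.5).
#' @return Named list of logical n x n masks, `tube01` ... `tube10`.
#' @export
tube_roi_masks <- function(phantom, n, fraction = 0.5) {
  stopifnot(inherits(phantom, "phantom_spec"))
  x <- grid_coords(n, phantom$fov_mm)
  tubes <- phantom$regions[-1]
  out <- lapply(seq_along(tubes), function(j) {
    r <- tubes[[j]]
    rad <- fraction * min(r$semi_axes)
    outer((x - r$center[1])^2, (x - r$center[2])^2, `+`) <= rad^2
  })
  names(out) <- sprintf("tube%02d", seq_along(tubes))
  out
}

#' Ground-truth tube values of a phantom
#'
#' @param phantom A `phantom_spec`.
#' @return data.frame with columns tube, fat_fraction (%), r2star (1/s),
#'   fb0 (Hz).
#' @export
phantom_ground_truth <- function(phantom) {
  tubes <- phantom$regions[-1]
  w <- vapply(tubes, `[[`, numeric(1), "water")
  f <- vapply(tubes, `[[`, numeric(1), "fat")
  data.frame(
    tube = seq_along(tubes),
    fat_fraction = 100 * f / (w + f),
    r2star = vapply(tubes, `[[`, numeric(1), "r2star"),
    fb0 = vapply(tubes, `[[`, numeric(1), "fb0")
  )
}
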