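#' Circular receive-coil array model
#'
#' Describes an array of smooth complex coil sensitivity profiles placed
#' on a circle around the object. Each profile is represented exactly as a
#' truncated Fourier series over a small set of low spatial frequencies
#' shared by all coils, so that coil-weighted analytic k-space can be
#' computed as exact frequency shifts of the object's Fourier transform.
#'
#' @param n_coils Number of coils (default 8).
#' @param placement_radius_mm Radius of the coil circle in mm; default
#'   1.1x half the FOV at simulation time.
#' @param width_mm Gaussian width (sigma) of each coil lobe in mm.
#' @param seed Integer seed for the small deterministic jitter of coil
#'   positions (breaks exact symmetries).
#' @param flat If `TRUE`, a single all-ones sensitivity (ignores the
#'   other profile parameters).
#' @return Object of class `coil_model`.
#' @export
coil_model <- function(n_coils = 8L, placement_radius_mm = NULL,
                       width_mm = NULL, seed = 1L, flat = FALSE) {
  n_coils <- as.integer(n_coils)
  stopifnot(n_coils >= 1L)
  structure(list(n_coils = n_coils, placement_radius_mm = placement_radius_mm,
                 width_mm = width_mm, seed = as.integer(seed), flat = isTRUE(flat)),
            class = "coil_model")
}

# shared low-frequency basis: (p, q)/(2*fov) cycles/mm for p,q in -2..2
.coil_basis <- function(fov_mm, order = 2L) {
  p <- seq(-order, order)
  g <- expand.grid(p = p, q = p)
  cbind(g$p, g$q) / (2 * fov_mm)
}

#' Simulate smooth complex coil sensitivity maps
#'
#' Gaussian lobes with a gentle linear phase, one per coil, placed evenly
#' (with a small seeded jitter) on a circle, are projected onto the shared
#' truncated Fourier basis by least squares on the pixel grid. The fitted
#' series *is* the coil: both the gridded maps returned here and the
#' analytic k-space simulation evaluate the same series, so the two
#' representations agree exactly.
#'
#' @param model A [coil_model()].
#' @param n Grid size.
#' @param fov_mm Field of view in mm.
#' @return Object of class `coil_set`: list with `maps` (n x n x K complex
#'   array), `freqs` (T x 2 basis frequencies in cycles/mm) and `coeffs`
#'   (T x K complex coefficients).
#' @export
simulate_coils <- function(model, n, fov_mm) {
  stopifnot(inherits(model, "coil_model"))
  K <- model$n_coils
  if (model$flat) {
    maps <- array(1 + 0i, dim = c(n, n, K))
    return(structure(list(maps = maps,
                          freqs = matrix(0, 1, 2),
                          coeffs = matrix(1 + 0i, 1, K)),
                     class = "coil_set"))
  }
  rad <- if (is.null(model$placement_radius_mm)) 0.55 * fov_mm else model$placement_radius_mm
  sig <- if (is.null(model$width_mm)) 0.45 * fov_mm else model$width_mm
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(model$seed)
  ang <- 2 * pi * (seq_len(K) - 1) / K + stats::rnorm(K, sd = 0.03)
  x <- grid_coords(n, fov_mm)
  X <- matrix(rep(x, n), n, n)       # varies along rows
  Y <- t(X)
  freqs <- .coil_basis(fov_mm)
  basis <- exp(1i * 2 * pi * (outer(as.vector(X), freqs[, 1]) +
                              outer(as.vector(Y), freqs[, 2])))
  coeffs <- matrix(0i, nrow(freqs), K)
  maps <- array(0i, dim = c(n, n, K))
  gram <- crossprod(Conj(basis), basis)
  for (k in seq_len(K)) {
    cx <- rad * cos(ang[k]); cy <- rad * sin(ang[k])
    prof <- exp(-((X - cx)^2 + (Y - cy)^2) / (2 * sig^2)) *
      exp(1i * pi * (X * cos(ang[k]) + Y * sin(ang[k])) / fov_mm)
    co <- solve(gram, crossprod(Conj(basis), as.vector(prof)))
    coeffs[, k] <- co
    maps[, , k] <- matrix(basis %*% co, n, n)
  }
  structure(list(maps = maps, freqs = freqs, coeffs = coeffs),
            class = "coil_set")
}
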