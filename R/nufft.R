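# Gridding NUFFT on a square grid: 2x oversampling, Kaiser-Bessel kernel.
# Image pixels live on the centred integer grid n = -N/2 .. N/2-1 (matrix
# row/column i maps to n = i - 1 - N/2); k-space coordinates are in
# cycles/FOV in [-N/2, N/2]. Forward transform (type 2):
#   s_j = sum_n x(n) * exp(-i*2*pi * k_j . n / N)

.nufft_os <- 2L
.nufft_J <- 8L
.nufft_beta <- pi * sqrt((.nufft_J / .nufft_os * (.nufft_os - 0.5))^2 - 0.8)

# Fourier transform of the Kaiser-Bessel kernel, for deapodization.
.kb_ft <- function(nu, J = .nufft_J, beta = .nufft_beta) {
  z <- beta^2 - (pi * J * nu)^2
  out <- numeric(length(z))
  pos <- z > 0
  out[pos] <- sinh(sqrt(z[pos])) / sqrt(z[pos])
  zz <- sqrt(-z[!pos])
  out[!pos] <- ifelse(zz < 1e-12, 1, sin(zz) / zz)
  J * out
}

.deapod_matrix <- function(n) {
  G <- .nufft_os * n
  ctr <- seq_len(n) - 1 - n %/% 2
  d <- .kb_ft(ctr / G)
  outer(d, d)
}

.check_coords <- function(coords, n) {
  if (!is.matrix(coords) || ncol(coords) != 2L)
    stop("coords must be an m x 2 matrix of (kx, ky) in cycles/FOV")
  if (any(abs(coords) > n / 2 + 1e-9))
    stop("k-space coordinates outside the Nyquist box [-N/2, N/2]")
  invisible(TRUE)
}

# ifftshift-style embedding of a centred N-grid into the G-grid (and back).
.embed_idx <- function(n, G) {
  c((G - n %/% 2 + 1):G, 1:(n - n %/% 2))
}

#' Non-uniform Fourier transform (forward, type 2)
#'
#' Evaluates `s_j = sum_n x(n) exp(-i 2 pi k_j . n / N)` over the centred
#' pixel grid, via 2x-oversampled FFT with Kaiser-Bessel interpolation
#' (relative accuracy about 1e-7 versus direct summation).
#'
#' @param image Complex N x N matrix (N even).
#' @param coords m x 2 matrix of k-space coordinates in cycles/FOV,
#'   within the Nyquist box `[-N/2, N/2]`.
#' @return Complex vector of m samples.
#' @export
nufft_forward <- function(image, coords) {
  image <- as.matrix(image)
  n <- nrow(image)
  stopifnot(ncol(image) == n, n %% 2L == 0L)
  .check_coords(coords, n)
  G <- .nufft_os * n
  y <- image / .deapod_matrix(n)
  emb <- matrix(0i, G, G)
  idx <- .embed_idx(n, G)
  emb[idx, idx] <- y
  X <- stats::fft(emb)
  g <- coords * .nufft_os   # per-pixel frequency k/N times G
  nufft_gather_cpp(X, g[, 1], g[, 2], .nufft_J, .nufft_beta)
}

#' Non-uniform Fourier transform (adjoint, type 1)
#'
#' Exact adjoint of [nufft_forward()]:
#' `x(n) = sum_j s_j exp(+i 2 pi k_j . n / N)`.
#'
#' @param samples Complex vector of m samples.
#' @param coords m x 2 matrix of coordinates in cycles/FOV.
#' @param n Output grid size (even).
#' @return Complex n x n matrix.
#' @export
nufft_adjoint <- function(samples, coords, n) {
  n <- as.integer(n)
  stopifnot(n %% 2L == 0L, length(samples) == nrow(coords))
  .check_coords(coords, n)
  G <- .nufft_os * n
  g <- coords * .nufft_os
  grid <- nufft_spread_cpp(as.complex(samples), g[, 1], g[, 2], G,
                           .nufft_J, .nufft_beta)
  Xb <- stats::fft(grid, inverse = TRUE)
  idx <- .embed_idx(n, G)
  Xb[idx, idx] / .deapod_matrix(n)
}

#' Toeplitz embedding of the NUFFT normal operator
#'
#' Precomputes, per echo, the 2N-periodic point-spread-function kernel so
#' that `adjoint(forward(x))` can be applied with two FFTs on the
#' 2x-padded grid. For full radial spokes with integer sample radii the
#' kernel is evaluated in closed form (a sum of Dirichlet kernels, exact
#' to machine precision); for arbitrary coordinates it is computed by an
#' adjoint NUFFT of unit samples on the doubled grid.
#'
#' @param traj_or_coords Either a [build_trajectory()] object (closed-form
#'   radial kernels, one per echo) or a single m x 2 coordinate matrix.
#' @param n Image grid size (even).
#' @param weights Optional non-negative per-sample weights, giving the
#'   kernel of the weighted normal operator `A^H diag(w) A` (used e.g. as
#'   a density preconditioner). For a trajectory: a vector over the
#'   samples of one spoke (recycled over spokes and echoes). Default
#'   `NULL`: plain normal operator, closed-form radial kernels.
#' @return Object of class `toeplitz_plan` with the stacked Fourier-domain
#'   kernels.
#' @export
toeplitz_plan <- function(traj_or_coords, n, weights = NULL) {
  n <- as.integer(n)
  stopifnot(n %% 2L == 0L)
  M <- 2L * n
  circ <- ((seq_len(M) - 1 + n) %% M) + 1  # position of d(t) in centred matrix
  if (inherits(traj_or_coords, "radial_trajectory")) {
    traj <- traj_or_coords
    if (traj$samples_per_spoke != n)
      stop("trajectory samples_per_spoke must equal the grid size n")
    ne <- traj$n_echoes
    kern <- array(0i, dim = c(M, M, ne))
    if (is.null(weights)) {
      for (m in seq_len(ne)) {
        th <- as.vector(traj$angles[, m, ])
        kern[, , m] <- radial_psf_kernel_cpp(th, n)
      }
    } else {
      stopifnot(length(weights) == traj$samples_per_spoke, all(weights >= 0))
      for (m in seq_len(ne)) {
        co <- .echo_coords(traj, m)
        w <- rep(weights, each = nrow(co) / traj$samples_per_spoke)
        H <- nufft_adjoint(as.complex(w), 2 * co, M)
        kern[, , m] <- stats::fft(H[circ, circ])
      }
    }
  } else {
    coords <- traj_or_coords
    .check_coords(coords, n)
    w <- if (is.null(weights)) rep(1, nrow(coords)) else weights
    stopifnot(length(w) == nrow(coords), all(w >= 0))
    H <- nufft_adjoint(as.complex(w), 2 * coords, M)
    kern <- array(stats::fft(H[circ, circ]), dim = c(M, M, 1L))
    ne <- 1L
  }
  structure(list(kern = kern, n = n, n_echoes = ne), class = "toeplitz_plan")
}

#' Apply the Toeplitz normal operator
#'
#' Computes `nufft_adjoint(nufft_forward(image))` for the coordinates the
#' plan was built for, using FFT convolutions on the 2x-padded grid.
#'
#' @param plan A [toeplitz_plan()].
#' @param image Complex n x n matrix (or n x n x S stack).
#' @param echo Echo index (1-based) selecting the kernel; for a stack, a
#'   vector of per-slice echo indices.
#' @return Same shape as `image`.
#' @export
toeplitz_normal <- function(plan, image, echo = 1L) {
  stopifnot(inherits(plan, "toeplitz_plan"))
  single <- is.matrix(image)
  u <- if (single) array(image, dim = c(plan$n, plan$n, 1L)) else image
  stopifnot(dim(u)[1] == plan$n, dim(u)[2] == plan$n)
  eo <- as.integer(rep(echo, length.out = dim(u)[3])) - 1L
  stopifnot(all(eo >= 0L), all(eo < plan$n_echoes))
  v <- toeplitz_apply_stack_cpp(u, plan$kern, eo)
  if (single) v[, , 1] else v
}

#' Ramp density-compensation weights for quick-look gridding
#'
#' Simple |k| ramp filter (with a DC fraction keeping the centre finite)
#' for direct gridded previews of radial data. Not used by the iterative
#' model-based solver.
#'
#' @param coords m x 2 coordinate matrix in cycles/FOV.
#' @return Non-negative weight vector of length m.
#' @export
dcf_ramp <- function(coords) {
  r <- sqrt(coords[, 1]^2 + coords[, 2]^2)
  pmax(r, 0.5)
}
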