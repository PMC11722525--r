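#' Sobolev weighting of spatial frequencies
#'
#' `w(k) = (1 + s*||k||^2)^(l/2)`; the Sobolev penalty on a map x is
#' `||w * FT{x}||^2`, promoting smoothness by penalizing high spatial
#' frequencies.
#'
#' @param kx,ky Vectors of spatial frequencies per axis (cycles/mm).
#' @param s Sobolev constant in mm^2.
#' @param l Sobolev exponent.
#' @return `length(kx) x length(ky)` matrix of weights (>= 1).
#' @export
sobolev_weight <- function(kx, ky = kx, s, l) {
  stopifnot(s > 0, l > 0)
  (1 + s * outer(kx^2, ky^2, `+`))^(l / 2)
}

# Sobolev weights on the FFT-ordered n x n grid (unshifted frequency order)
.sobolev_fft <- function(n, s, l, fov_mm = NULL) {
  f <- c(0:(n %/% 2 - 1), (n %/% 2):(n - 1) - n)
  k <- if (is.null(fov_mm)) f / n else f / fov_mm   # cycles/pixel or cycles/mm
  sobolev_weight(k, k, s = s, l = l)
}

#' Regularization schedule of the Gauss-Newton iteration
#'
#' `alpha_n = max(alpha_min, alpha0 / reduction_factor^n)`: the weight
#' starts high to stabilize the strongly nonlinear early steps and is
#' reduced geometrically until it reaches the floor.
#'
#' @param n Outer (Gauss-Newton) iteration, 0-based. Vectorized.
#' @param cfg A [recon_config()].
#' @return Regularization weight(s).
#' @export
alpha_schedule <- function(n, cfg) {
  stopifnot(all(n >= 0))
  pmax(cfg$alpha_min, cfg$alpha0 / cfg$reduction_factor^n)
}

#' Reconstruction configuration
#'
#' @param alpha0 Initial regularization weight (default 1).
#' @param alpha_min Floor of the schedule (default 0.002).
#' @param reduction_factor Per-iteration reduction (default 3).
#' @param n_gn Outer Gauss-Newton iterations (default 20; the
#'   off-resonance map converges over the alpha-floor steps).
#' @param n_fista Inner FISTA iterations per outer step (default 50).
#' @param sobolev_s Sobolev constant for the B0 field map, mm^2 (default 22).
#' @param sobolev_l Sobolev exponent for the B0 field map (default 4).
#' @param coil_sobolev_a Dimensionless Sobolev constant for the coil maps
#'   (frequencies in cycles/pixel; default 220).
#' @param coil_sobolev_l Sobolev exponent for the coil maps (default 32).
#' @param wavelet_levels Decomposition levels of the joint l1-wavelet
#'   regularizer (default 4).
#' @param r2s_max Upper clamp of R2* in 1/s (default 500; the convex
#'   constraint set needs a bounded projection).
#' @param r2s_scale Internal scaling of the R2* channel, 1/s per internal
#'   unit. Default `NULL`: set automatically to the inverse r.m.s. echo
#'   time, which balances the R2* channel's curvature against the
#'   water/fat channels.
#' @param fb0_scale Internal scaling of the field channel, Hz per internal
#'   unit. Default `NULL`: `1/(2*pi*te_rms)`, balancing the field
#'   channel; this scale also sets how far the field map can move per
#'   Gauss-Newton step relative to the regularization, which controls the
#'   phase-wrap risk.
#' @param n_unweighted Number of final outer steps solved in the plain
#'   (unweighted) least-squares metric (default 5). The ramp-weighted
#'   metric that conditions the earlier steps slightly reweights model
#'   mismatch toward high spatial frequencies; the final unweighted
#'   steps restore the plain objective from a warm start.
#' @param with_fat If `FALSE`, the fat component is excluded
#'   (3-parameter model, e.g. for known fat-free objects).
#' @param seed Seed for the (deterministic) power-iteration start vectors.
#' @return Object of class `recon_config`.
#' @export
recon_config <- function(alpha0 = 1, alpha_min = 0.002, reduction_factor = 3,
                         n_gn = 20L, n_fista = 50L,
                         sobolev_s = 22, sobolev_l = 4,
                         coil_sobolev_a = 220, coil_sobolev_l = 32,
                         wavelet_levels = 4L, r2s_max = 500,
                         r2s_scale = NULL, fb0_scale = NULL,
                         n_unweighted = 5L, with_fat = TRUE, seed = 1L) {
  stopifnot(alpha0 >= alpha_min, alpha_min > 0, reduction_factor > 1,
            sobolev_s > 0, n_gn >= 1, n_fista >= 1, r2s_max > 0,
            is.null(r2s_scale) || r2s_scale > 0,
            is.null(fb0_scale) || fb0_scale > 0)
  structure(list(alpha0 = alpha0, alpha_min = alpha_min,
                 reduction_factor = reduction_factor,
                 n_gn = as.integer(n_gn), n_fista = as.integer(n_fista),
                 sobolev_s = sobolev_s, sobolev_l = sobolev_l,
                 coil_sobolev_a = coil_sobolev_a, coil_sobolev_l = coil_sobolev_l,
                 wavelet_levels = as.integer(wavelet_levels),
                 r2s_max = r2s_max, r2s_scale = r2s_scale,
                 fb0_scale = fb0_scale,
                 n_unweighted = as.integer(n_unweighted),
                 with_fat = isTRUE(with_fat),
                 seed = as.integer(seed)),
            class = "recon_config")
}

#' Reconstruction state
#'
#' @param maps A [parameter_maps()] object.
#' @param coils Complex `n x n x K` array of coil sensitivities.
#' @param alpha Regularization weight the state was produced at.
#' @param gn_iteration Outer iteration count.
#' @param log Optional per-iteration diagnostics data.frame.
#' @return Object of class `recon_state`.
#' @export
recon_state <- function(maps, coils, alpha = NA_real_, gn_iteration = 0L,
                        log = NULL) {
  stopifnot(inherits(maps, "parameter_maps"), is.array(coils))
  structure(list(maps = maps, coils = coils, alpha = alpha,
                 gn_iteration = as.integer(gn_iteration), log = log),
            class = "recon_state")
}

#' Project onto the feasible set
#'
#' Clamps R2* to `[0, r2s_max]`; all other components are unchanged.
#' Idempotent.
#'
#' @param state A [recon_state()].
#' @param cfg A [recon_config()].
#' @return The projected state.
#' @export
project_constraints <- function(state, cfg) {
  state$maps$r2star <- pmin(pmax(Re(state$maps$r2star), 0), cfg$r2s_max)
  state
}

#' Nonlinear forward operator: state to multi-echo k-space
#'
#' Eq.-of-model composition: for each echo the parameter maps are mapped
#' through the signal model, weighted by each coil sensitivity, and
#' sampled on that echo's radial spokes with the NUFFT.
#'
#' @param state A [recon_state()].
#' @param traj A [build_trajectory()].
#' @param echoes An [echo_train()].
#' @param spectrum A [fat_spectrum()].
#' @return Complex array `[coil, echo, spoke, sample]`.
#' @export
forward_operator <- function(state, traj, echoes, spectrum = fat_spectrum()) {
  n <- nrow(state$maps$water)
  if (traj$samples_per_spoke != n)
    stop("grid mismatch: trajectory samples_per_spoke != map grid")
  K <- dim(state$coils)[3]
  NE <- traj$n_echoes
  n_spokes <- traj$n_shots * traj$n_frames
  S <- traj$samples_per_spoke
  te <- echo_times(echoes)
  out <- array(0i, dim = c(K, NE, n_spokes, S))
  for (m in seq_len(NE)) {
    Mm <- echo_image(state$maps, te[m], spectrum)
    co <- .echo_coords(traj, m)
    for (k in seq_len(K)) {
      s <- nufft_forward(state$coils[, , k] * Mm, co)
      out[k, m, , ] <- matrix(s, n_spokes, S)
    }
  }
  out
}

#' Synthesize an R2*-weighted magnitude image from a reconstruction
#'
#' Evaluates the signal model at an arbitrary (virtual) echo time and
#' returns its magnitude, e.g. heavily R2*-weighted images at TE = 60 ms
#' from a 2-second acquisition.
#'
#' @param state A [recon_state()].
#' @param te_ms Virtual echo time in ms.
#' @param spectrum A [fat_spectrum()].
#' @return Real magnitude matrix.
#' @export
synthesize_weighted_image <- function(state, te_ms, spectrum = fat_spectrum()) {
  Mod(echo_image(state$maps, te_ms, spectrum))
}

# ---- internal solver machinery ---------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

# connected components (4-neighbour) of a logical matrix; returns integer
# labels, 0 = background
.label_components <- function(flag) {
  n <- nrow(flag)
  lab <- matrix(0L, n, ncol(flag))
  cur <- 0L
  for (s0 in which(flag)) {
    if (lab[s0] != 0L) next
    cur <- cur + 1L
    queue <- s0
    while (length(queue)) {
      i <- queue[[1]]
      queue <- queue[-1]
      if (lab[i] != 0L) next
      lab[i] <- cur
      r <- (i - 1L) %% n + 1L
      cc <- (i - 1L) %/% n + 1L
      for (j in c(if (r > 1L) i - 1L, if (r < n) i + 1L,
                  if (cc > 1L) i - n, if (cc < ncol(flag)) i + n)) {
        if (flag[j] && lab[j] == 0L) queue <- c(queue, j)
      }
    }
  }
  lab
}

.fft2u <- function(x) stats::fft(x)
.ifft2u <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# channel-list helpers (W, F complex; r2i, fbi real; chat complex cube)
.ch_zero <- function(n, K) {
  list(W = matrix(0i, n, n), F = matrix(0i, n, n),
       r2i = matrix(0, n, n), fbi = matrix(0, n, n),
       chat = array(0i, dim = c(n, n, K)))
}

.ch_axpby <- function(a, x, b, y) {
  list(W = a * x$W + b * y$W, F = a * x$F + b * y$F,
       r2i = a * x$r2i + b * y$r2i, fbi = a * x$fbi + b * y$fbi,
       chat = a * x$chat + b * y$chat)
}

.ch_norm <- function(x) {
  sqrt(sum(Mod(x$W)^2) + sum(Mod(x$F)^2) + sum(x$r2i^2) + sum(x$fbi^2) +
         sum(Mod(x$chat)^2))
}

#' Calibrationless model-based reconstruction (IRGNM-FISTA)
#'
#' Jointly estimates water, fat, R2*, B0 and coil sensitivity maps from
#' multi-echo radial k-space by an iteratively regularized Gauss-Newton
#' method. At each outer step the nonlinear forward operator is linearized
#' and the regularized linear subproblem is solved with FISTA: joint
#' l1-wavelet sparsity on (W, F, R2*), quadratic penalties on the
#' Sobolev-preconditioned B0 and coil channels, and projection of R2* onto
#' `[0, r2s_max]`. The field and coil maps are parameterized in the
#' preconditioned (inverse-Sobolev-weighted) domain, so their smoothness
#' penalty is a plain l2 norm. The regularization weight follows
#' [alpha_schedule()]. Data is normalized to unit scale internally and the
#' linear components are rescaled on output.
#'
#' All FFT-intensive inner steps use precomputed Toeplitz point-spread
#' kernels of the radial sampling pattern, so no gridding is performed
#' inside the iteration.
#'
#' @param y A [multi_echo_kspace()] object.
#' @param traj Trajectory; defaults to the one stored in `y`.
#' @param echoes Echo train; defaults to the one stored in `y`.
#' @param spectrum A [fat_spectrum()].
#' @param cfg A [recon_config()].
#' @param verbose Print per-iteration diagnostics.
#' @return A [recon_state()] with physical-unit maps, the estimated coil
#'   sensitivities and a per-iteration log (alpha, data misfit, step size).
#' @export
irgnm_fista <- function(y, traj = y$traj, echoes = y$echoes,
                        spectrum = fat_spectrum(), cfg = recon_config(),
                        coils = NULL, verbose = FALSE) {
  stopifnot(inherits(y, "multi_echo_kspace"), inherits(cfg, "recon_config"))
  n <- traj$samples_per_spoke
  K <- dim(y$data)[1]
  NE <- traj$n_echoes
  te_s <- echo_times(echoes) / 1000
  zm <- fat_modulation(spectrum, echo_times(echoes))
  nS <- n * n

  # The data term is preconditioned with ramp density-compensation
  # weights: the weighted normal operator A^H D A of a radial pattern is
  # close to the identity, which conditions the inner FISTA solves; the
  # noiseless minimizer is unchanged. The weighted data norm is scaled to
  # 100 and the operator to unit spectral norm, so the alpha schedule
  # acts on a fixed scale.
  nsp <- traj$n_shots * traj$n_frames
  radius <- abs(seq_len(n) - 1L - n %/% 2L)
  w_spoke <- pmax(radius, 0.5) / (n / 2)
  w_flat <- rep(w_spoke, each = nsp)          # sample-major flattening
  w_data <- aperm(array(w_spoke, dim = c(n, nsp, NE, K)), c(4, 3, 2, 1))
  ynorm <- sqrt(sum(w_data * Mod(y$data)^2))
  dscale <- if (ynorm > 0) 100 / ynorm else 1
  plan <- toeplitz_plan(traj, n, weights = w_spoke)
  set.seed(cfg$seed)
  v1 <- matrix(complex(real = stats::rnorm(n * n),
                       imaginary = stats::rnorm(n * n)), n, n)
  opn <- 1
  for (it in seq_len(10L)) {
    v1 <- toeplitz_apply_stack_cpp(array(v1 / sqrt(sum(Mod(v1)^2)),
                                         dim = c(n, n, 1L)),
                                   plan$kern, 0L)[, , 1]
    opn <- sqrt(sum(Mod(v1)^2))
  }
  s_op <- sqrt(opn)                 # ||D^(1/2) A|| of one echo's sampling
  plan$kern <- plan$kern / opn

  # weighted adjoint images of the measured data, one per (coil, echo)
  S <- K * NE
  qstack <- array(0i, dim = c(n, n, S))
  for (m in seq_len(NE)) {
    co <- .echo_coords(traj, m)
    for (k in seq_len(K)) {
      sv <- w_flat * as.vector(y$data[k, m, , ]) * (dscale / s_op)
      qstack[, , (m - 1L) * K + k] <- nufft_adjoint(sv, co, n)
    }
  }
  ysq_e <- vapply(seq_len(NE), function(m)
    sum(w_data[, m, , ] * Mod(y$data[, m, , ])^2) * dscale^2, numeric(1))

  # channel scalings: the water/fat channels are anchored to the measured
  # image amplitude (which also pins the coil gauge at initialization),
  # and the R2*/B0 scales to the r.m.s. echo time, so all Jacobian
  # channels present comparable curvature to the inner solver
  te_rms <- sqrt(mean(te_s^2))
  r2s_sc <- if (is.null(cfg$r2s_scale)) 1 / te_rms else cfg$r2s_scale
  fb0_sc <- if (is.null(cfg$fb0_scale)) 1 / (2 * pi * te_rms) else cfg$fb0_scale
  sos1 <- matrix(0, n, n)
  for (k in seq_len(K)) sos1 <- sos1 + Mod(qstack[, , k])^2
  w_sc <- max(sqrt(stats::quantile(sos1, 0.95)), .Machine$double.eps)

  # Sobolev preconditioners (FFT order)
  wb_inv <- 1 / .sobolev_fft(n, cfg$sobolev_s, cfg$sobolev_l, fov_mm = y$meta$fov_mm)
  wc_inv <- 1 / .sobolev_fft(n, cfg$coil_sobolev_a, cfg$coil_sobolev_l)
  pb <- function(x) Re(.ifft2u(wb_inv * .fft2u(x)))
  pc <- function(x) .ifft2u(wc_inv * .fft2u(x))

  fixed_coils <- !is.null(coils)
  x <- .ch_zero(n, K)
  x$W <- matrix(1 + 0i, n, n)

  do_init <- isTRUE(cfg$fb0_init %||% TRUE) && NE >= 6L && ynorm > 0
  ref_fbi <- x$fbi
  if (do_init) {
    # Field-map pre-estimation (still calibrationless): the ramp-weighted
    # adjoint images in qstack are quick-look gridded echo images; the
    # coil-phase-free echo combination J_m = sum_k q_km conj(q_k1)
    # follows the voxel signal model with all constants absorbed into W
    # and F, so the multi-start voxelwise fitter recovers the
    # off-resonance (and R2*) per coarse block across the full
    # +/-1/(2 dTE) band. The smoothed estimates initialize the field and
    # relaxation channels; the Gauss-Newton iteration refines them.
    f <- max(1L, n %/% 24L)
    while (n %% f != 0L) f <- f - 1L
    nb <- n %/% f
    Agg <- matrix(0, nb, n)
    Agg[cbind(rep(seq_len(nb), each = f), seq_len(n))] <- 1 / f
    Jc <- array(0i, dim = c(nb, nb, NE))
    qb1 <- vector("list", K)
    for (k in seq_len(K)) qb1[[k]] <- Agg %*% qstack[, , k] %*% t(Agg)
    for (m in seq_len(NE)) {
      Jm <- matrix(0i, nb, nb)
      for (k in seq_len(K))
        Jm <- Jm + (Agg %*% qstack[, , (m - 1L) * K + k] %*% t(Agg)) *
          Conj(qb1[[k]])
      Jc[, , m] <- Jm
    }
    mag <- Mod(Jc[, , 1])
    fitmask <- mag > 0.1 * stats::quantile(mag, 0.98)
    fb0_c <- matrix(0, nb, nb)
    r2_c <- matrix(0, nb, nb)
    for (i in which(fitmask)) {
      sig <- Jc[seq(i, by = nb * nb, length.out = NE)]
      ft <- try(fit_voxel_complex(sig, echoes, spectrum,
                                  with_fat = cfg$with_fat), silent = TRUE)
      if (!inherits(ft, "try-error") && is.finite(ft$fb0)) {
        fb0_c[i] <- ft$fb0
        r2_c[i] <- ft$r2star
      }
    }
    # preconditioned coefficients chosen so the realized field Pb(fbi) is
    # only mildly smoothed (sqrt of the Sobolev filter): heavier
    # smoothing would shrink large off-resonance below the capture range
    # of the refinement
    x$fbi <- Re(.ifft2u(sqrt(1 / wb_inv) *
                          .fft2u(kronecker(fb0_c, matrix(1, f, f))))) / fb0_sc
    x$r2i <- pmin(pmax(Re(.ifft2u(wb_inv *
                                    .fft2u(kronecker(r2_c, matrix(1, f, f))))), 0),
                  cfg$r2s_max) / r2s_sc
  }
  # the quadratic field penalty is centred at the initial estimate (the
  # classical IRGNM reference); a zero-centred penalty would erase the
  # pre-estimated field during the strongly regularized early steps
  ref_fbi <- x$fbi

  zero_cube_K <- array(0i, dim = c(n, n, K))

  # Echo-time continuation: the off-resonance landscape has phase-wrap
  # local minima whose basin width scales with 1/(echo-time span), so the
  # early Gauss-Newton steps see only the leading echoes (wide basins for
  # the field map) and the echo set grows as the estimate settles.
  n_act <- function(gn) {
    if (!isTRUE(cfg$echo_ladder %||% FALSE)) return(NE)
    na <- if (gn <= 9L) ceiling(NE / 8)
    else if (gn <= 13L) ceiling(NE / 4)
    else if (gn <= 17L) ceiling(NE / 2)
    else NE
    min(NE, max(4L, na))
  }
  act_n <- -1L
  te_a <- zm_a <- kern_a <- ysq_a <- sl_a <- NE_a <- NULL
  set_active <- function(na) {
    act_n <<- na
    NE_a <<- na
    te_a <<- te_s[seq_len(na)]
    zm_a <<- zm[seq_len(na)]
    kern_a <<- plan$kern[, , seq_len(na), drop = FALSE]
    ysq_a <<- sum(ysq_e[seq_len(na)])
    sl_a <<- lapply(seq_len(K), function(k) (seq_len(na) - 1L) * K + k)
  }

  # physical-domain coils and echo images at the linearization point
  linearize <- function(xc) {
    C <- array(0i, dim = c(n, n, K))
    if (fixed_coils) C[] <- coils
    else for (k in seq_len(K)) C[, , k] <- pc(xc$chat[, , k])
    fb0 <- fb0_sc * pb(xc$fbi)
    r2 <- r2s_sc * pmin(pmax(xc$r2i, 0), cfg$r2s_max / r2s_sc)
    E <- array(0i, dim = c(n, n, NE_a))
    B <- array(0i, dim = c(n, n, NE_a))
    for (m in seq_len(NE_a)) {
      Em <- exp((1i * 2 * pi * fb0 - r2) * te_a[m])
      E[, , m] <- Em
      B[, , m] <- w_sc * (xc$W + xc$F * zm_a[m]) * Em
    }
    list(C = C, E = E, B = B, fb0 = fb0, r2 = r2)
  }

  # Jacobian map-part image stack for a channel perturbation dx
  build_dM <- function(dx, lp) {
    pbd <- pb(dx$fbi)
    dM <- array(0i, dim = c(n, n, NE_a))
    for (m in seq_len(NE_a)) {
      dM[, , m] <- w_sc * lp$E[, , m] * (dx$W + zm_a[m] * dx$F) +
        lp$B[, , m] * (-te_a[m] * r2s_sc * dx$r2i +
                         1i * 2 * pi * te_a[m] * fb0_sc * pbd)
    }
    dM
  }

  # contract per-echo / per-coil image-stack gradients to channel gradients
  chain_adj <- function(gM, gC, lp) {
    g <- .ch_zero(n, K)
    gMm <- matrix(gM, nS, NE_a)
    Em <- matrix(lp$E, nS, NE_a)
    Bm <- matrix(lp$B, nS, NE_a)
    g$W <- matrix(w_sc * rowSums(Conj(Em) * gMm), n, n)
    g$F <- matrix(w_sc * rowSums(Conj(Em) * gMm %*% diag(Conj(zm_a))), n, n)
    cB <- Conj(Bm) * gMm
    g$r2i <- matrix(-r2s_sc * Re(cB %*% te_a), n, n)
    g$fbi <- pb(matrix(2 * pi * fb0_sc * Im(cB %*% te_a), n, n))
    if (!fixed_coils)
      for (k in seq_len(K)) g$chat[, , k] <- pc(gC[, , k])
    g
  }

  normal_op <- function(dx, lp) {
    dC <- zero_cube_K
    if (!fixed_coils)
      for (k in seq_len(K)) dC[, , k] <- pc(dx$chat[, , k])
    nc <- normal_core_cpp(build_dM(dx, lp), lp$B, lp$C, dC, kern_a,
                          !fixed_coils)
    chain_adj(nc$gM, nc$gC, lp)
  }

  # proximal map of alpha*R plus the R2* projection, step size t
  prox <- function(zc, t, alpha) {
    tri <- joint_l1_prox(list(zc$W, zc$F, zc$r2i), t * alpha,
                         levels = cfg$wavelet_levels)
    zc$W <- tri[[1]]
    zc$F <- if (cfg$with_fat) tri[[2]] else matrix(0i, n, n)
    zc$r2i <- pmin(pmax(Re(tri[[3]]), 0), cfg$r2s_max / r2s_sc)
    sh <- 1 / (1 + t * alpha)
    zc$fbi <- ref_fbi + (zc$fbi - ref_fbi) * sh
    zc$chat <- zc$chat * sh
    zc
  }

  # refine the normalization so the full linearized operator (all coils,
  # echoes and channels) at the initial state has unit spectral norm: the
  # alpha schedule then acts as a genuine trust region for the bilinear
  # and exponential nonlinearities
  set_active(n_act(1L))
  lp0 <- linearize(x)
  set.seed(cfg$seed + 1L)
  pv <- .ch_zero(n, K)
  pv$W <- matrix(complex(real = stats::rnorm(nS), imaginary = stats::rnorm(nS)), n, n)
  pv$F <- matrix(complex(real = stats::rnorm(nS), imaginary = stats::rnorm(nS)), n, n)
  pv$r2i <- matrix(stats::rnorm(nS), n, n)
  pv$fbi <- matrix(stats::rnorm(nS), n, n)
  pv$chat <- array(complex(real = stats::rnorm(nS * K),
                           imaginary = stats::rnorm(nS * K)), dim = c(n, n, K))
  L0 <- 1
  for (it in seq_len(30L)) {
    pv <- normal_op(.ch_axpby(1 / .ch_norm(pv), pv, 0, pv), lp0)
    L0 <- .ch_norm(pv)
  }
  plan$kern <- plan$kern / L0
  qstack <- qstack / sqrt(L0)
  s_op <- s_op * sqrt(L0)
  set_active(act_n)               # refresh the cached kernel subset

  # linearization plus the data-side contractions and weighted misfit
  eval_point <- function(xc) {
    lp <- linearize(xc)
    Bm <- matrix(lp$B, nS, NE_a)
    qMm <- matrix(0i, nS, NE_a)
    qC <- zero_cube_K
    for (k in seq_len(K)) {
      qk <- matrix(qstack[, , sl_a[[k]]], nS, NE_a)
      qMm <- qMm + qk * as.vector(Conj(lp$C[, , k]))
      if (!fixed_coils) qC[, , k] <- matrix(rowSums(Conj(Bm) * qk), n, n)
    }
    nc0 <- normal_core_cpp(lp$B, lp$B, lp$C, zero_cube_K, kern_a,
                           !fixed_coils)
    quad <- Re(sum(Conj(lp$B) * nc0$gM))
    cross <- Re(sum(Conj(Bm) * qMm))
    list(lp = lp, qMm = qMm, qC = qC, nc0 = nc0,
         misfit = sqrt(max(quad - 2 * cross + ysq_a, 0)))
  }

  log_rows <- vector("list", cfg$n_gn)
  ev <- eval_point(x)
  lm_boost <- 1

  nuw <- if (cfg$n_gn >= 10L) min(cfg$n_unweighted %||% 0L, cfg$n_gn - 1L) else 0L
  cur_gamma <- 1

  # density-weight annealing: the ramp metric (gamma = 1) conditions the
  # bulk of the schedule; the final steps anneal through sqrt-ramp to the
  # plain least-squares metric, so low and mid spatial frequencies of the
  # maps converge in a metric where they are well-conditioned while the
  # objective ends as the plain (noise-matched) one
  metric_gamma <- function(gn) {
    if (nuw <= 0L || gn <= cfg$n_gn - nuw) return(1)
    pos <- gn - (cfg$n_gn - nuw)             # 1..nuw
    if (pos <= ceiling(nuw / 2)) 0.5 else 0
  }
  set_metric <- function(gamma) {
    wg <- w_spoke^gamma
    plan$kern <<- toeplitz_plan(traj, n, weights = wg)$kern / s_op^2
    wg_flat <- rep(wg, each = nsp)
    for (m in seq_len(NE)) {
      co <- .echo_coords(traj, m)
      for (k in seq_len(K)) {
        sv <- wg_flat * as.vector(y$data[k, m, , ]) * (dscale / s_op)
        qstack[, , (m - 1L) * K + k] <<- nufft_adjoint(sv, co, n)
      }
    }
    wg_data <- aperm(array(wg, dim = c(n, nsp, NE, K)), c(4, 3, 2, 1))
    ysq_e <<- vapply(seq_len(NE), function(m)
      sum(wg_data[, m, , ] * Mod(y$data[, m, , ])^2) * dscale^2, numeric(1))
    cur_gamma <<- gamma
    act_n <<- -1L             # force refresh of the cached subsets
  }

  for (gn in seq_len(cfg$n_gn)) {
    polish_changed <- FALSE
    alpha <- alpha_schedule(gn - 1L, cfg)
    gam <- metric_gamma(gn)
    if (gam != cur_gamma) set_metric(gam)
    na <- n_act(gn)
    if (na != act_n) {
      set_active(na)
      ev <- eval_point(x)
    }
    lp <- ev$lp
    misfit <- ev$misfit

    b <- chain_adj(array(ev$qMm, c(n, n, NE_a)) - ev$nc0$gM, ev$qC - ev$nc0$gC, lp)
    b <- .ch_axpby(1, b, 1, normal_op(x, lp))

    # Lipschitz constant of the linearized normal operator; the power
    # iteration is warm-started from the previous outer step's principal
    # vector (the spectrum drifts slowly between linearizations)
    set.seed(cfg$seed + 7919L * gn)
    noise <- .ch_zero(n, K)
    noise$W <- matrix(complex(real = stats::rnorm(nS), imaginary = stats::rnorm(nS)), n, n)
    noise$F <- matrix(complex(real = stats::rnorm(nS), imaginary = stats::rnorm(nS)), n, n)
    noise$r2i <- matrix(stats::rnorm(nS), n, n)
    noise$fbi <- matrix(stats::rnorm(nS), n, n)
    noise$chat <- array(complex(real = stats::rnorm(nS * K),
                                imaginary = stats::rnorm(nS * K)), dim = c(n, n, K))
    v <- .ch_axpby(1, pv, 0.05 * .ch_norm(pv) / .ch_norm(noise), noise)
    L <- 1
    npow <- if (gn == 1L || (gn > 1L && metric_gamma(gn) != metric_gamma(gn - 1L)))
      15L else 6L
    for (it in seq_len(npow)) {
      v <- normal_op(.ch_axpby(1 / .ch_norm(v), v, 0, v), lp)
      L <- .ch_norm(v)
    }
    pv <- v

    # FISTA warm-started at the current iterate. The smooth part carries a
    # Levenberg-Marquardt damping mu*||dx||^2 on the map channels, centred
    # at the linearization point: it vanishes with the alpha schedule and
    # does not bias the converged solution, but keeps each Gauss-Newton
    # update inside the validity region of the linearized exponentials.
    # A step that still increases the data misfit is rejected and re-solved
    # with boosted damping (classical LM control).
    solve_sub <- function(mu) {
      t_step <- 1 / (1.3 * max(L, .Machine$double.eps) + alpha + mu)
      # reduced-echo stages cost a fraction of a full step, so they can
      # afford a deeper inner solve (helps the field map walk its basins)
      n_inner <- if (act_n < NE) 2L * cfg$n_fista else cfg$n_fista
      z <- x
      vmom <- x
      tk <- 1
      for (it in seq_len(n_inner)) {
        g <- .ch_axpby(1, normal_op(vmom, lp), -1, b)
        g$W <- g$W + mu * (vmom$W - x$W)
        g$F <- g$F + mu * (vmom$F - x$F)
        g$r2i <- g$r2i + mu * (vmom$r2i - x$r2i)
        g$fbi <- g$fbi + mu * (vmom$fbi - x$fbi)
        znew <- prox(.ch_axpby(1, vmom, -t_step, g), t_step, alpha)
        tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
        mom <- (tk - 1) / tk_new
        vmom <- .ch_axpby(1 + mom, znew, -mom, z)
        z <- znew
        tk <- tk_new
      }
      z
    }

    retries <- 0L
    repeat {
      z <- solve_sub(alpha * lm_boost)
      ev_new <- eval_point(z)
      if (ev_new$misfit <= misfit * 1.01 || retries >= 3L) break
      lm_boost <- lm_boost * 8
      retries <- retries + 1L
    }
    if (ev_new$misfit > misfit * 1.05)
      stop(sprintf(paste0("model-based solver diverged: data misfit grew from ",
                          "%.4g to %.4g at Gauss-Newton step %d despite damping"),
                   misfit, ev_new$misfit, gn))
    x <- z
    ev <- ev_new
    lm_boost <- max(1, lm_boost / 4)

    # Model-subtracted swap polish, once near the end of the schedule:
    # voxels whose coil-combined model residual stays far above the
    # object median are candidates for fat-water-swap local minima (the
    # aliased main fat peak mimics a shifted water resonance, and gridded
    # pre-fits cannot decide the hypothesis where point-spread leakage
    # from slowly-decaying neighbours dominates). Their signals are
    # re-fitted voxelwise on leakage-cleaned data (residual plus the
    # voxel's own modelled self-term), and a changed field hypothesis is
    # refined by the remaining Gauss-Newton steps.
    if (gn %in% c(8L, max(1L, cfg$n_gn - nuw - 1L)) &&
        isTRUE(cfg$swap_polish %||% TRUE) && do_init && NE_a == NE &&
        cur_gamma == 1) {
      lpc <- ev$lp
      sos <- matrix(0, n, n)
      for (k in seq_len(K)) sos <- sos + Mod(lpc$C[, , k])^2
      gMm <- matrix(ev$nc0$gM, nS, NE)
      t0 <- Re(sum(kern_a[, , 1])) / (2 * n)^2
      Bm <- matrix(lpc$B, nS, NE)
      self_m <- t0 * as.vector(sos) * Bm
      res_map <- matrix(rowSums(Mod(ev$qMm - gMm)^2), n, n)
      sig_map <- matrix(rowSums(Mod(self_m)^2), n, n)
      # support requires both coil coverage and modelled object signal
      # (otherwise empty background trivially has residual >> self-energy)
      support <- sos > 0.3 * stats::quantile(sos, 0.95) &
        sig_map > 0.05 * stats::quantile(sig_map, 0.95)
      # a swapped voxel is a *good* local fit in absolute terms, so the
      # flag is relative: residual energy comparable to the voxel's own
      # modelled signal energy marks a wrong hypothesis, while Gibbs
      # partial-volume edges stay below it
      rel_res <- res_map / pmax(sig_map, 1e-9 * max(sig_map))
      flag <- support & rel_res > 0.25
      if (!is.null(cfg$polish_debug_file))
        saveRDS(list(qMm = ev$qMm, gM = ev$nc0$gM, sos = sos, B = lpc$B,
                     fb0 = lpc$fb0, r2 = lpc$r2, t0 = t0, n = n, NE = NE,
                     support = support, res_map = res_map, sig_map = sig_map),
                cfg$polish_debug_file)
      if (any(flag) && mean(flag[support]) < 0.2) {
        sclean <- ev$qMm - gMm + self_m
        fb0_cur <- lpc$fb0
        dfb0 <- matrix(0, n, n)
        dr2 <- matrix(0, n, n)
        changed <- FALSE
        nflip <- 0L
        # refit per connected cluster on the cluster-mean cleaned signal:
        # within a wrongly-hypothesized region every voxel's cleaning is
        # corrupted by the region's own (wrong) point-spread leakage, but
        # that structured error largely averages out over the cluster
        lab <- .label_components(flag)
        for (cl in seq_len(max(lab))) {
          vox <- which(lab == cl)
          if (length(vox) < 3L) next
          sig <- colMeans(sclean[vox, , drop = FALSE])
          rn_cur <- sqrt(sum(Mod(sig - colMeans(self_m[vox, , drop = FALSE]))^2))
          ft <- try(fit_voxel_complex(sig, echoes, spectrum,
                                      with_fat = cfg$with_fat), silent = TRUE)
          if (inherits(ft, "try-error") || !is.finite(ft$fb0)) next
          med_cur <- stats::median(fb0_cur[vox])
          if (abs(ft$fb0 - med_cur) > 15 && ft$residual < 0.7 * rn_cur) {
            dfb0[vox] <- ft$fb0 - fb0_cur[vox]
            dr2[vox] <- ft$r2star - lpc$r2[vox]
            changed <- TRUE
            nflip <- nflip + 1L
            if (verbose && nflip <= 8L)
              message(sprintf("  polish flip (n=%d): fb0 %+.1f -> %+.1f, r2 -> %.1f",
                              length(vox), med_cur, ft$fb0, ft$r2star))
          }
        }
        if (verbose)
          message(sprintf("  swap polish: %d flagged, %d clusters flipped",
                          sum(flag), nflip))
        if (changed) {
          polish_changed <- TRUE
          x$fbi <- x$fbi +
            Re(.ifft2u(sqrt(1 / wb_inv) * .fft2u(dfb0))) / fb0_sc
          ref_fbi <- x$fbi
          x$r2i <- pmin(pmax(x$r2i + Re(.ifft2u(wb_inv * .fft2u(dr2))) / r2s_sc,
                             0), cfg$r2s_max / r2s_sc)
          ev <- eval_point(x)
          lm_boost <- 1
        }
      } else if (verbose) {
        message(sprintf("  swap polish: %d flagged (rel_res q95 %.3g), skipped",
                        sum(flag), stats::quantile(rel_res[support], 0.95)))
      }
    }
    log_rows[[gn]] <- data.frame(gn = gn, alpha = alpha, misfit = misfit,
                                 lipschitz = L, lm_boost = lm_boost,
                                 retries = retries, n_echoes = act_n,
                                 metric_gamma = cur_gamma,
                                 polish_changed = polish_changed)
    if (verbose)
      message(sprintf("GN %2d  alpha %.4g  misfit %.5g  L %.4g  echoes %d  retries %d",
                      gn, alpha, misfit, L, act_n, retries))
  }

  set_active(NE)
  lp <- linearize(x)
  unscale <- w_sc / (dscale * s_op)
  maps <- parameter_maps(x$W * unscale, x$F * unscale, lp$r2, lp$fb0)
  recon_state(maps, lp$C, alpha = alpha_schedule(cfg$n_gn - 1L, cfg),
              gn_iteration = cfg$n_gn, log = do.call(rbind, log_rows))
}
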