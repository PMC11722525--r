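#' Voxelwise complex multi-echo model fit
#'
#' Nonlinear least-squares fit of the water-fat signal model to the
#' complex signal of one voxel across echoes, as used for Cartesian
#' reference reconstructions. With `with_fat = FALSE` the fat component is
#' excluded (3-parameter variant for known fat-free objects). To avoid
#' phase-wrap local minima, the fit is multi-started over the
#' off-resonance with starts spanning the alias-free band
#' `+/- 1/(2*delta_te)` of the echo spacing.
#'
#' @param signal Complex vector, one value per echo.
#' @param echoes An [echo_train()] matching `signal`.
#' @param spectrum A [fat_spectrum()].
#' @param with_fat Include the fat component (default `TRUE`).
#' @param n_starts Number of off-resonance starts (default 5).
#' @return List of class `voxel_fit`: `water`, `fat` (complex), `r2star`
#'   (1/s, >= 0), `fb0` (Hz), `fat_fraction` (%), `residual` (norm),
#'   `converged`.
#' @export
fit_voxel_complex <- function(signal, echoes, spectrum = fat_spectrum(),
                              with_fat = TRUE, n_starts = 5L) {
  stopifnot(inherits(echoes, "echo_train"), length(signal) == echoes$n_echoes,
            all(is.finite(Re(signal))), all(is.finite(Im(signal))))
  n_par <- if (with_fat) 6L else 4L
  if (echoes$n_echoes < ceiling(n_par / 2))
    stop("need at least as many echoes as complex model parameters")
  te <- echo_times(echoes)
  te_s <- te / 1000
  z <- fat_modulation(spectrum, te)

  model <- function(p) {
    W <- complex(real = p[1], imaginary = p[2])
    Fc <- if (with_fat) complex(real = p[5], imaginary = p[6]) else 0
    (W + Fc * z) * exp((1i * 2 * pi * p[4] - p[3]) * te_s)
  }
  resid <- function(p) {
    d <- model(p) - signal
    c(Re(d), Im(d))
  }

  band <- 1 / (2 * echoes$delta_te / 1000)     # Hz
  starts <- if (n_starts > 1L) seq(-band, band, length.out = n_starts) else 0
  # damp extreme starts toward the interior of the band
  starts <- starts * 0.8
  a0 <- mean(Mod(signal[1]))
  lower <- c(-Inf, -Inf, 0, -Inf, if (with_fat) c(-Inf, -Inf) else NULL)
  run_start <- function(f0) {
    p0 <- c(Re(signal[1]), Im(signal[1]), 10, f0,
            if (with_fat) c(0.1 * a0, 0) else NULL)
    fit <- try(minpack.lm::nls.lm(p0, lower = lower, fn = resid,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
               silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    list(fit = fit, rn = sqrt(sum(resid(fit$par)^2)))
  }
  best <- NULL
  for (f0 in starts) {
    cand <- run_start(f0)
    if (!is.null(cand) && (is.null(best) || cand$rn < best$rn)) best <- cand
  }
  if (with_fat && !is.null(best)) {
    # guard against fat-water swaps: the dominant fat peak, aliased into
    # the band of the echo spacing, mimics a shifted water resonance;
    # re-fit with the off-resonance displaced by that shift both ways
    f_main <- spectrum$peak_shifts_ppm[which.max(spectrum$peak_amplitudes)] *
      spectrum$hz_per_ppm
    dte_s <- echoes$delta_te / 1000
    f_alias <- f_main - round(f_main * dte_s) / dte_s
    for (f0 in best$fit$par[4] + c(-f_alias, f_alias)) {
      cand <- run_start(f0)
      if (!is.null(cand) && cand$rn < best$rn) best <- cand
    }
  }
  if (is.null(best))
    return(list(water = NA_complex_, fat = NA_complex_, r2star = NA_real_,
                fb0 = NA_real_, fat_fraction = NA_real_, residual = NA_real_,
                converged = FALSE))
  p <- best$fit$par
  W <- complex(real = p[1], imaginary = p[2])
  Fc <- if (with_fat) complex(real = p[5], imaginary = p[6]) else 0 + 0i
  # arithmetic echo trains make the model exactly periodic in fb0 with
  # period 1/delta_te (the per-echo phase collapses to a constant that W
  # and F absorb); report the equivalent in-band solution
  dte_s <- echoes$delta_te / 1000
  k_alias <- round(p[4] * dte_s)
  if (k_alias != 0) {
    shift <- k_alias / dte_s
    ph <- exp(1i * 2 * pi * shift * echoes$te_first / 1000)
    W <- W * ph
    Fc <- Fc * ph
    p[4] <- p[4] - shift
  }
  den <- Mod(W) + Mod(Fc)
  list(water = W, fat = Fc, r2star = max(p[3], 0), fb0 = p[4],
       fat_fraction = if (den > 0) 100 * Mod(Fc) / den else 0,
       residual = best$rn,
       converged = best$fit$info %in% 1:4)
}

#' Voxelwise magnitude-exponential R2* fit
#'
#' Least-squares fit of `y_m = rho * exp(-TE_m * R2*)` to per-echo
#' magnitudes (the standard multi-echo EPI R2* estimator): log-linear
#' initialization (when all magnitudes are positive) refined by
#' Levenberg-Marquardt with the constraint R2* >= 0.
#'
#' @param magnitudes Non-negative vector, one per echo.
#' @param echoes An [echo_train()] matching `magnitudes`.
#' @return List of class `voxel_fit`: `rho`, `r2star` (1/s), `residual`,
#'   `converged`.
#' @export
fit_magnitude_exp <- function(magnitudes, echoes) {
  stopifnot(inherits(echoes, "echo_train"),
            length(magnitudes) == echoes$n_echoes, echoes$n_echoes >= 2L,
            all(is.finite(magnitudes)))
  te_s <- echo_times(echoes) / 1000
  if (all(magnitudes > 0)) {
    co <- unname(stats::coef(stats::lm(log(magnitudes) ~ te_s)))
    p0 <- c(exp(co[1]), max(-co[2], 0))
  } else {
    p0 <- c(max(magnitudes), 10)
  }
  resid <- function(p) p[1] * exp(-p[2] * te_s) - magnitudes
  fit <- minpack.lm::nls.lm(p0, lower = c(0, 0), fn = resid,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-14, ptol = 1e-14))
  list(rho = unname(fit$par[1]), r2star = unname(fit$par[2]),
       residual = sqrt(sum(resid(fit$par)^2)),
       converged = fit$info %in% 1:4)
}

#' Fit parameter maps voxelwise from a multi-echo image stack
#'
#' Applies [fit_voxel_complex()] (or [fit_magnitude_exp()] on magnitudes)
#' to every voxel above a magnitude threshold.
#'
#' @param images Complex array `n x n x n_echoes` (or real magnitudes for
#'   `method = "magnitude"`).
#' @param echoes An [echo_train()].
#' @param method `"complex"` (water-fat model) or `"magnitude"`
#'   (exponential).
#' @param spectrum A [fat_spectrum()] (complex method only).
#' @param with_fat Include fat (complex method only).
#' @param mask Optional logical matrix of voxels to fit; default: voxels
#'   with first-echo magnitude above 5 % of the maximum.
#' @return A [parameter_maps()] object for the complex method (plus
#'   attribute `converged`), or a list with `rho`, `r2star` matrices for
#'   the magnitude method.
#' @export
fit_map <- function(images, echoes, method = c("complex", "magnitude"),
                    spectrum = fat_spectrum(), with_fat = TRUE, mask = NULL) {
  method <- match.arg(method)
  d <- dim(images)
  stopifnot(length(d) == 3L, d[3] == echoes$n_echoes)
  first <- Mod(images[, , 1])
  if (is.null(mask)) mask <- first > 0.05 * max(first)
  idx <- which(mask)
  if (method == "complex") {
    W <- matrix(0i, d[1], d[2]); Fc <- matrix(0i, d[1], d[2])
    R2 <- matrix(0, d[1], d[2]); B0 <- matrix(0, d[1], d[2])
    conv <- matrix(TRUE, d[1], d[2])
    for (i in idx) {
      v <- images[seq(i, by = d[1] * d[2], length.out = d[3])]
      ft <- fit_voxel_complex(v, echoes, spectrum, with_fat)
      W[i] <- ft$water; Fc[i] <- ft$fat
      R2[i] <- ft$r2star; B0[i] <- ft$fb0; conv[i] <- ft$converged
    }
    out <- parameter_maps(W, Fc, R2, B0)
    attr(out, "converged") <- conv
    out
  } else {
    rho <- matrix(0, d[1], d[2]); R2 <- matrix(0, d[1], d[2])
    for (i in idx) {
      v <- Mod(images[seq(i, by = d[1] * d[2], length.out = d[3])])
      ft <- fit_magnitude_exp(v, echoes)
      rho[i] <- ft$rho; R2[i] <- ft$r2star
    }
    list(rho = rho, r2star = R2)
  }
}
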