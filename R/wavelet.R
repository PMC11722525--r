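# Periodized separable 2D Daubechies-4 (two vanishing moments, 4 taps)
# wavelet transform, used by the joint l1 sparsity prox of the solver.
# The transform is orthonormal, so Parseval holds and the inverse is the
# transpose; coefficients are stored in the usual in-place pyramid layout
# (approximation band in the top-left corner).

.db4_lo <- {
  s3 <- sqrt(3)
  c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
}
.db4_hi <- rev(.db4_lo) * c(1, -1, 1, -1)

# single-level periodic analysis along columns of x
.dwt_cols <- function(x) {
  n <- nrow(x)
  h <- n %/% 2L
  lo <- matrix(0, h, ncol(x)); hi <- matrix(0, h, ncol(x))
  if (is.complex(x)) { lo <- lo + 0i; hi <- hi + 0i }
  even <- 2L * seq_len(h) - 1L          # rows 1,3,5,... (0-based 2k)
  for (t in 1:4) {
    idx <- ((even - 1L + (t - 1L)) %% n) + 1L
    lo <- lo + .db4_lo[t] * x[idx, , drop = FALSE]
    hi <- hi + .db4_hi[t] * x[idx, , drop = FALSE]
  }
  rbind(lo, hi)
}

# single-level periodic synthesis along columns (transpose of .dwt_cols)
.idwt_cols <- function(x) {
  n <- nrow(x)
  h <- n %/% 2L
  lo <- x[seq_len(h), , drop = FALSE]
  hi <- x[h + seq_len(h), , drop = FALSE]
  out <- matrix(0, n, ncol(x))
  if (is.complex(x)) out <- out + 0i
  even <- 2L * seq_len(h) - 1L
  for (t in 1:4) {
    idx <- ((even - 1L + (t - 1L)) %% n) + 1L
    acc <- .db4_lo[t] * lo + .db4_hi[t] * hi
    # scatter-add with wrapped indices (each idx vector has no duplicates)
    out[idx, ] <- out[idx, , drop = FALSE] + acc
  }
  out
}

#' 2D periodized orthogonal wavelet transform (Daubechies-4)
#'
#' @param x Numeric or complex square matrix; each dimension must be
#'   divisible by `2^levels`.
#' @param levels Number of decomposition levels (default 4).
#' @return Coefficient matrix, same shape, pyramid layout.
#' @export
dwt2 <- function(x, levels = 4L) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(ncol(x) == n, n %% (2^levels) == 0L)
  out <- x
  sz <- n
  for (l in seq_len(levels)) {
    blk <- out[seq_len(sz), seq_len(sz), drop = FALSE]
    blk <- .dwt_cols(blk)
    blk <- t(.dwt_cols(t(blk)))
    out[seq_len(sz), seq_len(sz)] <- blk
    sz <- sz %/% 2L
  }
  out
}

#' Inverse of [dwt2()]
#'
#' @param w Coefficient matrix from [dwt2()].
#' @param levels Number of levels used in the forward transform.
#' @return Reconstructed matrix.
#' @export
idwt2 <- function(w, levels = 4L) {
  w <- as.matrix(w)
  n <- nrow(w)
  stopifnot(ncol(w) == n, n %% (2^levels) == 0L)
  out <- w
  sz <- n %/% (2^(levels - 1L))
  for (l in seq_len(levels)) {
    blk <- out[seq_len(sz), seq_len(sz), drop = FALSE]
    blk <- t(.idwt_cols(t(blk)))
    blk <- .idwt_cols(blk)
    out[seq_len(sz), seq_len(sz)] <- blk
    sz <- sz * 2L
  }
  out
}

#' Joint l1-wavelet proximal operator on a map triplet
#'
#' Wavelet-transforms each of the three maps (water, fat, R2*), applies
#' joint soft-thresholding across the maps at each coefficient position
#' (the cross-map l2 magnitude is shrunk by the threshold, preserving the
#' direction), and inverse-transforms. The coarsest approximation band is
#' not thresholded. This is the proximal map of the joint l1 penalty
#' `sum_i ||(cW_i, cF_i, cR_i)||_2`, exploiting shared edge structure
#' between the maps.
#'
#' @param triplet List of three same-shaped matrices (complex allowed).
#' @param threshold Non-negative soft threshold.
#' @param levels Wavelet decomposition levels.
#' @return List of three thresholded maps.
#' @export
joint_l1_prox <- function(triplet, threshold, levels = 4L) {
  stopifnot(is.list(triplet), length(triplet) == 3L, threshold >= 0)
  if (threshold == 0) return(triplet)
  w <- lapply(triplet, dwt2, levels = levels)
  n <- nrow(w[[1]])
  mag <- sqrt(Mod(w[[1]])^2 + Mod(w[[2]])^2 + Mod(w[[3]])^2)
  shrink <- ifelse(mag > threshold, 1 - threshold / pmax(mag, .Machine$double.eps), 0)
  napp <- n %/% (2^levels)
  shrink[seq_len(napp), seq_len(napp)] <- 1   # keep approximation band
  lapply(w, function(c) idwt2(c * shrink, levels = levels))
}
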