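#' ROI mean and standard deviation
#'
#' @param map Numeric matrix (a parameter map).
#' @param roi Logical mask of the same shape, non-empty.
#' @return Named vector `c(mean, sd)`; the SD uses the n-1 denominator and
#'   is 0 for a single-voxel ROI.
#' @export
roi_stats <- function(map, roi) {
  stopifnot(identical(dim(map), dim(roi)), is.logical(roi))
  v <- map[roi]
  if (length(v) == 0L) stop("empty ROI mask")
  c(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0)
}

#' Bland-Altman agreement analysis
#'
#' Paired-difference analysis between two measurement methods: mean
#' difference (bias), SD of the differences, and the 95 % limits of
#' agreement `mean +/- 1.96 * SD`.
#'
#' @param x,y Paired numeric vectors of equal length >= 2 (`x` minus `y`).
#' @return Object of class `agreement_result`: list with `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `n` (and `icc = NA`).
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  stopifnot(length(x) >= 2L)
  d <- x - y
  m <- mean(d); s <- stats::sd(d)
  structure(list(mean_diff = m, sd_diff = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 n = length(d), icc = NA_real_),
            class = "agreement_result")
}

#' Intra-class correlation coefficient ICC(A,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC
#' (McGraw & Wong ICC(A,1)) between two paired measurement series,
#' computed from the two-way ANOVA mean squares
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))` with k = 2 raters.
#' Absolute agreement penalizes a systematic offset between methods, which
#' is the appropriate form when comparing quantitative values.
#'
#' @param x,y Paired numeric vectors of equal length >= 3.
#' @return List with `icc` (in `[-1, 1]`, `NA` with `defined = FALSE` for
#'   degenerate zero-variance input) and the mean squares `msr`, `msc`,
#'   `mse`.
#' @export
icc_agreement <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  stopifnot(n >= 3L)
  val <- c(x, y)
  subj <- factor(rep(seq_len(n), 2L))
  rater <- factor(rep(1:2, each = n))
  if (stats::var(val) == 0)
    return(list(icc = NA_real_, defined = FALSE,
                msr = 0, msc = 0, mse = 0))
  ms <- summary(stats::aov(val ~ subj + rater))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  icc <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  list(icc = icc, defined = TRUE, msr = msr, msc = msc, mse = mse)
}

#' Per-ROI agreement summary between two maps
#'
#' Convenience wrapper: ROI means of both maps, their Bland-Altman
#' statistics and the ICC across ROIs.
#'
#' @param map_x,map_y Two maps on the same grid.
#' @param rois Named list of logical masks.
#' @return List with `table` (data.frame of per-ROI means), `bland_altman`
#'   and `icc`.
#' @export
roi_agreement <- function(map_x, map_y, rois) {
  mx <- vapply(rois, function(r) roi_stats(map_x, r)[["mean"]], numeric(1))
  my <- vapply(rois, function(r) roi_stats(map_y, r)[["mean"]], numeric(1))
  list(table = data.frame(roi = names(rois), mean_x = mx, mean_y = my),
       bland_altman = bland_altman(mx, my),
       icc = if (length(mx) >= 3L) icc_agreement(mx, my) else NULL)
}
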