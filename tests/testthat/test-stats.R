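test_that("ROI statistics use mean and sample SD", {
  m <- matrix(7, 4, 4)
  roi <- matrix(TRUE, 4, 4)
  expect_equal(roi_stats(m, roi), c(mean = 7, sd = 0))
  m2 <- matrix(0, 2, 2); m2[1:3] <- c(1, 2, 3)
  roi2 <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  expect_equal(roi_stats(m2, roi2), c(mean = 2, sd = 1))
  roi1 <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  expect_equal(roi_stats(m2, roi1), c(mean = 1, sd = 0))
  expect_error(roi_stats(m2, matrix(FALSE, 2, 2)), "empty")
})

test_that("Bland-Altman statistics match hand computation", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$sd_diff, 0)
  ba <- bland_altman(c(1, 3), c(2, 5))
  expect_equal(ba$mean_diff, -1.5)
  expect_equal(ba$sd_diff, sqrt(0.5), tolerance = 1e-12)
  expect_equal(ba$loa_low, -1.5 - 1.96 * sqrt(0.5), tolerance = 1e-12)
  expect_equal(ba$loa_high, -1.5 + 1.96 * sqrt(0.5), tolerance = 1e-12)
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("Bland-Altman is antisymmetric and translation-equivariant", {
  set.seed(41)
  x <- rnorm(12); y <- rnorm(12)
  expect_equal(bland_altman(x, y)$mean_diff, -bland_altman(y, x)$mean_diff)
  expect_equal(bland_altman(x + 2.5, y)$mean_diff,
               bland_altman(x, y)$mean_diff + 2.5, tolerance = 1e-12)
})

test_that("ICC(A,1) behaves as absolute agreement", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(icc_agreement(x, x)$icc, 1, tolerance = 1e-12)
  # a large constant offset is penalized (well below 1)
  expect_lt(icc_agreement(x, x + 10)$icc, 0.2)
  # degenerate constant input flagged undefined
  deg <- icc_agreement(rep(2, 4), rep(2, 4))
  expect_false(deg$defined)
  expect_true(is.na(deg$icc))
})

test_that("ICC matches an independently coded ANOVA-table computation", {
  set.seed(42)
  n <- 20
  x <- rnorm(n, 10, 3)
  y <- x + rnorm(n, 0.5, 1)
  got <- icc_agreement(x, y)
  # independent oracle from raw sums of squares (two-way, k = 2 raters)
  k <- 2
  dat <- c(x, y)
  grand <- mean(dat)
  row_means <- (x + y) / 2
  col_means <- c(mean(x), mean(y))
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((dat - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc_oracle <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  expect_equal(got$icc, icc_oracle, tolerance = 1e-10)
  expect_equal(got$msr, msr, tolerance = 1e-10)
  expect_equal(got$mse, mse, tolerance = 1e-10)
})

test_that("ICC is symmetric and scale-invariant", {
  set.seed(43)
  x <- rnorm(15, 5); y <- rnorm(15, 5)
  expect_equal(icc_agreement(x, y)$icc, icc_agreement(y, x)$icc,
               tolerance = 1e-12)
  expect_equal(icc_agreement(3 * x, 3 * y)$icc, icc_agreement(x, y)$icc,
               tolerance = 1e-12)
})

test_that("roi_agreement summarizes per-ROI means of two maps", {
  set.seed(44)
  m1 <- matrix(rnorm(64, 10), 8, 8)
  m2 <- m1 + 0.3
  rois <- list(a = matrix(rep(c(TRUE, FALSE), each = 32), 8, 8),
               b = matrix(rep(c(FALSE, TRUE), each = 32), 8, 8),
               c = matrix(rep(c(TRUE, FALSE), 32), 8, 8))
  ag <- roi_agreement(m1, m2, rois)
  expect_equal(nrow(ag$table), 3)
  expect_equal(ag$bland_altman$mean_diff, -0.3, tolerance = 1e-12)
  expect_lt(ag$icc$icc, 1)
})
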