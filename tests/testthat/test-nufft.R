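test_that("forward NUFFT matches direct DFT summation", {
  set.seed(11)
  n <- 16
  x <- random_complex_matrix(n, 11)
  co <- cbind(runif(50, -n / 2, n / 2), runif(50, -n / 2, n / 2))
  expect_lt(rel_err(nufft_forward(x, co), direct_nudft(x, co)), 1e-6)
  # delta at the grid origin -> unit-magnitude samples
  d <- matrix(0i, n, n); d[n / 2 + 1, n / 2 + 1] <- 1
  expect_lt(max(abs(Mod(nufft_forward(d, co)) - 1)), 1e-6)
  # zero image -> zero samples
  expect_equal(max(Mod(nufft_forward(matrix(0i, n, n), co))), 0, tolerance = 1e-9)
  expect_error(nufft_forward(x, co * 10), "Nyquist")
})

test_that("adjoint passes the dot-product test on random trajectories", {
  set.seed(12)
  for (n in c(8, 16, 32)) {
    x <- random_complex_matrix(n, n)
    nco <- 40
    co <- cbind(runif(nco, -n / 2, n / 2), runif(nco, -n / 2, n / 2))
    y <- complex(real = rnorm(nco), imaginary = rnorm(nco))
    lhs <- sum(nufft_forward(x, co) * Conj(y))
    rhs <- sum(x * Conj(nufft_adjoint(y, co, n)))
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-10)
  }
})

test_that("adjoint matches the conjugate-transpose DFT matrix on an 8x8 grid", {
  set.seed(13)
  n <- 8
  nco <- 20
  co <- cbind(runif(nco, -n / 2, n / 2), runif(nco, -n / 2, n / 2))
  ctr <- seq_len(n) - 1 - n %/% 2
  # explicit DFT matrix: rows = samples, cols = pixels
  px <- expand.grid(ctr, ctr)
  A <- exp(-1i * 2 * pi * (outer(co[, 1], px[, 1]) + outer(co[, 2], px[, 2])) / n)
  y <- complex(real = rnorm(nco), imaginary = rnorm(nco))
  oracle <- matrix(Conj(t(A)) %*% y, n, n)
  expect_lt(rel_err(nufft_adjoint(y, co, n), oracle), 1e-6)
  # single DC sample of value 1 -> constant unit image
  dc <- nufft_adjoint(1 + 0i, matrix(c(0, 0), 1, 2), n)
  expect_lt(max(Mod(dc - 1)), 1e-6)
})

test_that("Toeplitz path equals adjoint-of-forward for radial patterns", {
  set.seed(14)
  n <- 32
  x <- random_complex_matrix(n, 14)
  tr <- build_trajectory(5, 3, n)
  plan <- toeplitz_plan(tr, n)
  for (m in 1:3) {
    co <- cbind(as.vector(tr$coords[[m]][, , 1]),
                as.vector(tr$coords[[m]][, , 2]))
    direct <- nufft_adjoint(nufft_forward(x, co), co, n)
    expect_lt(rel_err(toeplitz_normal(plan, x, echo = m), direct), 1e-5)
  }
})

test_that("Toeplitz path handles random coordinate subsets and weights", {
  set.seed(15)
  n <- 16
  x <- random_complex_matrix(n, 15)
  nco <- 60
  co <- cbind(runif(nco, -n / 2, n / 2), runif(nco, -n / 2, n / 2))
  plan <- toeplitz_plan(co, n)
  direct <- nufft_adjoint(nufft_forward(x, co), co, n)
  expect_lt(rel_err(toeplitz_normal(plan, x), direct), 1e-5)
  w <- runif(nco)
  planw <- toeplitz_plan(co, n, weights = w)
  directw <- nufft_adjoint(w * nufft_forward(x, co), co, n)
  expect_lt(rel_err(toeplitz_normal(planw, x), directw), 1e-5)
})

test_that("the Toeplitz normal operator is linear and positive semidefinite", {
  set.seed(16)
  n <- 16
  tr <- build_trajectory(3, 2, n)
  plan <- toeplitz_plan(tr, n)
  x1 <- random_complex_matrix(n, 16); x2 <- random_complex_matrix(n, 17)
  lin <- toeplitz_normal(plan, 2 * x1 + (1 - 2i) * x2)
  expect_lt(rel_err(lin, 2 * toeplitz_normal(plan, x1) +
                      (1 - 2i) * toeplitz_normal(plan, x2)), 1e-12)
  for (i in 1:5) {
    x <- random_complex_matrix(n, 20 + i)
    quad <- sum(Conj(x) * toeplitz_normal(plan, x))
    expect_lt(abs(Im(quad)) / abs(quad), 1e-10)
    expect_gte(Re(quad), 0)
  }
})

test_that("ramp density weights are positive and grow with |k|", {
  co <- cbind(c(0, 1, 4, 8), c(0, 0, 0, 0))
  w <- dcf_ramp(co)
  expect_true(all(w > 0))
  expect_true(all(diff(w) >= 0))
})
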