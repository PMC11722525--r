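test_that("fat modulation matches the term-by-term oracle and is bounded", {
  sp <- fat_spectrum()
  expect_equal(fat_modulation(sp, 0), 1 + 0i)
  # single peak: closed form exp(i 2 pi f te)
  one <- fat_spectrum(peak_shifts_ppm = -440 / 127.73, peak_amplitudes = 1)
  te <- 1000 / (4 * 440)                     # quarter period in ms
  expect_equal(fat_modulation(one, te), exp(-1i * pi / 2), tolerance = 1e-12)
  # default spectrum vs independent summation
  for (te in c(1.1, 2.37, 10, 33.3)) {
    oracle <- 0 + 0i
    for (p in seq_along(sp$peak_shifts_ppm))
      oracle <- oracle + sp$peak_amplitudes[p] *
        exp(1i * 2 * pi * sp$peak_shifts_ppm[p] * sp$hz_per_ppm * te / 1000)
    expect_equal(fat_modulation(sp, te), oracle, tolerance = 1e-12)
    expect_lte(Mod(fat_modulation(sp, te)), 1 + 1e-12)
  }
  expect_equal(sum(sp$peak_amplitudes), 1, tolerance = 1e-12)
})

test_that("echo image evaluates the closed-form signal model", {
  n <- 8
  W <- matrix(1 + 0i, n, n)
  # pure water, no decay: M = W for all echoes
  m0 <- parameter_maps(W)
  for (te in c(0, 5, 50)) expect_equal(echo_image(m0, te), W)
  # exponential decay magnitude
  m1 <- parameter_maps(W, r2star = 10)
  expect_equal(Mod(echo_image(m1, 100)[1, 1]), exp(-1), tolerance = 1e-12)
  # off-resonance phase: 50 Hz over 10 ms is half a cycle
  m2 <- parameter_maps(W, fb0 = 50)
  expect_equal(Arg(echo_image(m2, 10)[1, 1]), pi, tolerance = 1e-12)
  expect_error(parameter_maps(W, r2star = -1), "non-negative")
})

test_that("analytic Jacobian matches central finite differences", {
  set.seed(7)
  n <- 4
  maps <- parameter_maps(
    water = random_complex_matrix(n, 7),
    fat = random_complex_matrix(n, 8),
    r2star = matrix(runif(n * n, 0, 60), n, n),
    fb0 = matrix(rnorm(n * n, sd = 30), n, n)
  )
  te <- 7.3
  jac <- signal_jacobian(maps, te)
  eps <- 1e-6
  fd <- function(field, delta) {
    mp <- maps; mm <- maps
    mp[[field]] <- maps[[field]] + delta
    mm[[field]] <- maps[[field]] - delta
    (echo_image(mp, te) - echo_image(mm, te)) / (2 * eps)
  }
  expect_lt(rel_err(fd("water", eps), jac$dW), 1e-6)
  expect_lt(rel_err(fd("fat", eps), jac$dF), 1e-6)
  expect_lt(rel_err(fd("r2star", eps), jac$dR2star), 1e-6)
  expect_lt(rel_err(fd("fb0", eps), jac$dFb0), 1e-6)
})

test_that("Jacobian at zero echo time has the closed-form values", {
  maps <- parameter_maps(matrix(1 + 0i, 2, 2))
  jac0 <- signal_jacobian(maps, 0)
  expect_equal(jac0$dW, matrix(1 + 0i, 2, 2))
  expect_equal(jac0$dF, matrix(1 + 0i, 2, 2))
  expect_equal(jac0$dR2star, matrix(0i, 2, 2))
  expect_equal(jac0$dFb0, matrix(0i, 2, 2))
  # dM/dR2* = -TE for unit water at 10 ms
  jac <- signal_jacobian(maps, 10)
  expect_equal(jac$dR2star[1, 1], -0.01 + 0i, tolerance = 1e-12)
})

test_that("magnitude decays monotonically for fat-free voxels", {
  maps <- parameter_maps(matrix(2 + 1i, 3, 3), r2star = 35, fb0 = -20)
  te <- seq(0, 80, by = 4)
  mags <- vapply(te, function(t) Mod(echo_image(maps, t)[1, 1]), numeric(1))
  expect_true(all(diff(mags) <= 0))
})

test_that("fat fraction uses the 0/0 -> 0 convention", {
  maps <- parameter_maps(matrix(c(1 + 0i, 0i, 3i, 0i), 2, 2),
                         fat = matrix(c(1 + 0i, 0i, 1i, 2i), 2, 2))
  ff <- fat_fraction(maps)
  expect_equal(ff[1, 1], 50)
  expect_equal(ff[2, 1], 0)      # 0/0 voxel
  expect_equal(ff[1, 2], 25)
  expect_equal(ff[2, 2], 100)
})
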