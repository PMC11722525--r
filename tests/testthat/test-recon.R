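test_that("Sobolev weights follow the closed form", {
  expect_equal(sobolev_weight(0, 0, s = 22, l = 4)[1, 1], 1)
  # s = 22 mm^2 at ||k||^2 = 1/22 mm^-2 gives (1+1)^(4/2) = 4
  expect_equal(sobolev_weight(sqrt(1 / 22), 0, s = 22, l = 4)[1, 1], 4,
               tolerance = 1e-12)
  k <- seq(0, 0.4, by = 0.05)
  w <- sobolev_weight(k, 0, s = 22, l = 4)[, 1]
  expect_true(all(diff(w) > 0))
})

test_that("the regularization schedule starts at alpha0 and floors at alpha_min", {
  cfg <- recon_config(alpha0 = 1, alpha_min = 0.002, reduction_factor = 3)
  expect_equal(alpha_schedule(0, cfg), 1)
  expect_equal(alpha_schedule(1, cfg), 1 / 3)
  expect_equal(alpha_schedule(10, cfg), 0.002)
  expect_true(all(diff(alpha_schedule(0:12, cfg)) <= 0))
})

test_that("constraint projection clamps R2* and is idempotent", {
  cfg <- recon_config(r2s_max = 500)
  maps <- parameter_maps(matrix(1 + 0i, 2, 2))
  st <- recon_state(maps, array(1 + 0i, c(2, 2, 1)))
  st$maps$r2star <- matrix(c(-5, 50, 700, 0), 2, 2)
  pr <- project_constraints(st, cfg)
  expect_equal(pr$maps$r2star, matrix(c(0, 50, 500, 0), 2, 2))
  expect_equal(project_constraints(pr, cfg)$maps$r2star, pr$maps$r2star)
})

test_that("the forward operator matches the analytic simulation", {
  # single water-only disk, flat single coil: model evaluated on the grid
  # and sampled with the NUFFT must match the closed-form ellipse k-space
  ph <- structure(list(fov_mm = 128, base_resolution = 32, regions = list(
    list(center = c(0, 0), semi_axes = c(40, 40), water = 1, fat = 0,
         r2star = 20, fb0 = 10)
  )), class = "phantom_spec")
  n <- 64
  tr <- build_trajectory(6, 2, n)
  et <- echo_train(2.37, 1.88, 2)
  cs <- simulate_coils(coil_model(n_coils = 1, flat = TRUE), n, 128)
  y <- simulate_kspace(ph, cs, tr, et, noise_sd = 0, dc_norm = NA)
  ras <- rasterize_phantom(ph, n)
  maps <- parameter_maps(ras$maps$water * (128 / n)^2, ras$maps$fat,
                         ras$maps$r2star, ras$maps$fb0)
  st <- recon_state(maps, cs$maps)
  pred <- forward_operator(st, tr, et)
  expect_lt(rel_err(pred, y$data), 0.05)    # rasterization error only
  # zero maps give zero data; linearity in (W, F)
  st0 <- recon_state(parameter_maps(matrix(0i, n, n)), cs$maps)
  expect_equal(max(Mod(forward_operator(st0, tr, et))), 0, tolerance = 1e-12)
  st2 <- st; st2$maps$water <- 2 * st$maps$water; st2$maps$fat <- 2 * st$maps$fat
  expect_lt(rel_err(forward_operator(st2, tr, et), 2 * pred), 1e-10)
})

test_that("coil/object rescaling leaves the forward operator invariant", {
  set.seed(71)
  n <- 32
  tr <- build_trajectory(4, 2, n)
  et <- echo_train(2.37, 1.88, 2)
  cs <- simulate_coils(coil_model(n_coils = 3, seed = 2), n, 128)
  maps <- parameter_maps(random_complex_matrix(n, 71),
                         random_complex_matrix(n, 72),
                         matrix(runif(n * n, 0, 50), n, n),
                         matrix(rnorm(n * n, sd = 20), n, n))
  gamma <- 1.7 - 0.6i
  st1 <- recon_state(maps, cs$maps)
  maps2 <- maps
  maps2$water <- maps$water / gamma
  maps2$fat <- maps$fat / gamma
  st2 <- recon_state(maps2, cs$maps * gamma)
  expect_lt(rel_err(forward_operator(st1, tr, et),
                    forward_operator(st2, tr, et)), 1e-10)
})

test_that("synthesized weighted images follow the model closed form", {
  maps <- parameter_maps(matrix(2 + 0i, 3, 3), fat = matrix(1 + 0i, 3, 3),
                         r2star = 20, fb0 = 5)
  st <- recon_state(maps, array(1 + 0i, c(3, 3, 1)))
  expect_equal(synthesize_weighted_image(st, 0), matrix(3, 3, 3))
  te <- 60
  z <- fat_modulation(fat_spectrum(), te)
  expect_equal(synthesize_weighted_image(st, te)[1, 1],
               Mod((2 + z) * exp(-0.06 * 20)), tolerance = 1e-12)
  # monotone decay for a fat-free voxel
  mw <- parameter_maps(matrix(1 + 0i, 2, 2), r2star = 30)
  stw <- recon_state(mw, array(1 + 0i, c(2, 2, 1)))
  mags <- vapply(seq(0, 80, 10),
                 function(t) synthesize_weighted_image(stw, t)[1, 1], numeric(1))
  expect_true(all(diff(mags) <= 0))
})

test_that("model-based recon recovers a noiseless single tube", {
  ph <- single_tube_phantom()
  n <- 48
  tr <- build_trajectory(10, 12, n)
  et <- echo_train(2.37, 3.3, 12)
  cs <- simulate_coils(coil_model(n_coils = 4, seed = 3), n, 128)
  y <- simulate_kspace(ph, cs, tr, et, noise_sd = 0, seed = 2)
  cfg <- recon_config(n_gn = 16, n_fista = 40, seed = 3)
  st <- irgnm_fista(y, cfg = cfg)
  x <- grid_coords(n, 128)
  roi <- outer((x - 5)^2, (x + 3)^2, `+`) <= 10^2
  ff <- fat_fraction(st$maps)
  expect_lt(abs(mean(ff[roi]) - 30), 1)                      # FF < 1 %
  expect_lt(abs(mean(st$maps$r2star[roi]) - 25) / 25, 0.02)  # R2* < 2 %
  expect_lt(abs(mean(st$maps$fb0[roi]) - 20), 0.5)           # B0 < 0.5 Hz
  # misfit is non-increasing within each solver stage (segments share the
  # echo set and data metric; a swap-polish write-back legitimately resets
  # the following step)
  lg <- st$log
  seg_id <- cumsum(c(1, diff(lg$n_echoes) != 0 | diff(lg$metric_gamma) != 0) +
                     c(0, head(lg$polish_changed, -1)))
  for (sid in unique(seg_id)) {
    seg <- lg$misfit[seg_id == sid]
    expect_true(all(diff(seg) <= 0.05 * seg[-length(seg)] + 1e-6))
  }
  # model consistency: forward of the reconstruction reproduces the data
  pred <- forward_operator(st, tr, et)
  expect_lt(rel_err(pred, y$data), 0.1)
})

test_that("zero data drives the object signal to zero", {
  n <- 32
  tr <- build_trajectory(4, 3, n)
  et <- echo_train(2.37, 1.88, 3)
  dat <- array(0i, c(2, 3, 4, n))
  y <- multi_echo_kspace(dat, tr, et, meta = list(fov_mm = 128))
  st <- irgnm_fista(y, cfg = recon_config(n_gn = 3, n_fista = 5, seed = 1))
  expect_equal(max(Mod(st$coils)), 0, tolerance = 1e-8)
  expect_equal(max(Mod(st$maps$fat)), 0, tolerance = 1e-8)
  expect_equal(max(abs(st$maps$fb0)), 0, tolerance = 1e-8)
  pred <- forward_operator(st, tr, et)
  expect_equal(max(Mod(pred)), 0, tolerance = 1e-8)
})

test_that("3-parameter mode matches 4-parameter mode on fat-free data", {
  ph <- single_tube_phantom(water = 1, fat = 0)
  n <- 48
  tr <- build_trajectory(10, 12, n)
  et <- echo_train(2.37, 3.3, 12)
  cs <- simulate_coils(coil_model(n_coils = 3, seed = 5), n, 128)
  y <- simulate_kspace(ph, cs, tr, et, noise_sd = 0, seed = 2)
  cfg4 <- recon_config(n_gn = 16, n_fista = 40, seed = 3)
  cfg3 <- recon_config(n_gn = 16, n_fista = 40, seed = 3, with_fat = FALSE)
  st4 <- irgnm_fista(y, cfg = cfg4)
  st3 <- irgnm_fista(y, cfg = cfg3)
  x <- grid_coords(n, 128)
  roi <- outer((x - 5)^2, (x + 3)^2, `+`) <= 10^2
  expect_equal(max(Mod(st3$maps$fat)), 0)
  expect_lt(abs(mean(st3$maps$r2star[roi]) - mean(st4$maps$r2star[roi])), 1)
  expect_lt(abs(mean(st3$maps$fb0[roi]) - mean(st4$maps$fb0[roi])), 0.5)
})
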