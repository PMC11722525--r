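# shared fixtures, built in code

random_complex_matrix <- function(n, seed = 1) {
  set.seed(seed)
  matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
}

# direct type-2 DFT oracle: s_j = sum_n x(n) exp(-i 2 pi k_j . n / N)
direct_nudft <- function(image, coords) {
  n <- nrow(image)
  ctr <- seq_len(n) - 1 - n %/% 2
  vapply(seq_len(nrow(coords)), function(j) {
    ph <- exp(-1i * 2 * pi * (outer(ctr, rep(1, n)) * coords[j, 1] +
                                outer(rep(1, n), ctr) * coords[j, 2]) / n)
    sum(image * ph)
  }, complex(1))
}

rel_err <- function(a, b) sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))

# single-tube phantom on an empty background, for small recon fixtures
single_tube_phantom <- function(fov = 128, tube_radius = 20,
                                center = c(5, -3), water = 0.7, fat = 0.3,
                                r2star = 25, fb0 = 20) {
  structure(list(fov_mm = fov, base_resolution = 64, regions = list(
    list(center = c(0, 0), semi_axes = c(50, 50), water = 0, fat = 0,
         r2star = 0, fb0 = 0),
    list(center = center, semi_axes = c(tube_radius, tube_radius),
         water = water, fat = fat, r2star = r2star, fb0 = fb0)
  )), class = "phantom_spec")
}
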