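test_that("rasterization reproduces analytic sphere, shell and background masses", {
  grid <- c(40L, 40L, 30L)
  center <- c(19.5, 19.5, 29)
  ## wall-less sphere, activity 1, no background
  s <- sphere_spec("s", center, 10, sphere_activity = 1)
  img <- rasterize_phantom(phantom_spec(list(s), 0, grid), oversample = 4)
  expect_equal(sum(img$values) * voxel_volume(img), (pi / 6) * 10^3,
               tolerance = 0.005)

  ## cold shell only: activity in the 1 mm wall, nothing inside
  sw <- sphere_spec("w", center, 10, wall_thickness = 1,
                    sphere_activity = 0, wall_activity = 1)
  imw <- rasterize_phantom(phantom_spec(list(sw), 0, grid), oversample = 4)
  expect_equal(sum(imw$values) * voxel_volume(imw), (4 * pi / 3) * (6^3 - 5^3),
               tolerance = 0.01)

  ## no spheres: uniform background
  imb <- rasterize_phantom(phantom_spec(list(), 2.5, c(8L, 8L, 8L)))
  expect_true(all(imb$values == 2.5))

  ## total mass with sphere + background: A*V_s + B*(V_grid - V_s)
  s2 <- sphere_spec("s2", center, 13, sphere_activity = 7)
  im2 <- rasterize_phantom(phantom_spec(list(s2), 2, grid), oversample = 4)
  v_s <- (pi / 6) * 13^3
  v_grid <- prod(grid) * prod(c(1, 1, 2))
  expect_equal(sum(im2$values) * voxel_volume(im2),
               7 * v_s + 2 * (v_grid - v_s), tolerance = 0.005)
})

test_that("rasterization rejects bad geometry and converges with oversampling", {
  grid <- c(40L, 40L, 30L)
  a <- sphere_spec("a", c(15, 20, 29), 10)
  b <- sphere_spec("b", c(23, 20, 29), 10)   # centres 8 mm apart, radii 5+5
  expect_error(rasterize_phantom(phantom_spec(list(a, b), 0, grid)), "overlap")
  out <- sphere_spec("o", c(2, 20, 29), 10)
  expect_error(rasterize_phantom(phantom_spec(list(out), 0, grid)), "outside")
  expect_error(rasterize_phantom(phantom_spec(list(a), 0, grid), oversample = 0))

  ## doubling the oversample rate changes voxels less than the previous
  ## doubling did
  ph <- phantom_spec(list(sphere_spec("s", c(19.7, 20.2, 29.3), 10)), 0, grid)
  v2 <- rasterize_phantom(ph, 2)$values
  v4 <- rasterize_phantom(ph, 4)$values
  v8 <- rasterize_phantom(ph, 8)$values
  expect_lt(max(abs(v8 - v4)), max(abs(v4 - v2)))
})

test_that("Gaussian PSF preserves constants, mass, step midpoints, and linearity", {
  psf <- psf_spec(7)
  ## constants are fixed points
  u <- image_volume(array(3.2, c(12, 12, 10)), c(1, 1, 2))
  expect_equal(apply_psf(u, psf, pad_value = 3.2)$values, u$values,
               tolerance = 1e-10)

  ## mass conservation for an interior object on a zero background
  obj <- make_sphere_image(D = 10, fwhm = 0, A = 1, B = 0)$image
  bl <- apply_psf(obj, psf, pad_value = 0)
  expect_equal(sum(bl$values), sum(obj$values), tolerance = 0.001)

  ## half-space step of height A: the edge value is A/2 (mean of the two
  ## voxels straddling the plane, by kernel symmetry)
  A <- 8
  st <- array(0, c(60, 20, 20))
  st[1:30, , ] <- A
  stv <- image_volume(st, c(1, 1, 1))
  blv <- apply_psf(stv, psf, pad_value = NULL)
  edge <- (blv$values[30, 10, 10] + blv$values[31, 10, 10]) / 2
  expect_equal(edge, A / 2, tolerance = 0.01)

  ## linearity: psf(a X + b Y) = a psf(X) + b psf(Y)
  set.seed(42)
  X <- image_volume(array(runif(1000), c(10, 10, 10)))
  Y <- image_volume(array(runif(1000), c(10, 10, 10)))
  Z <- image_volume(2 * X$values + 3 * Y$values)
  lhs <- apply_psf(Z, psf, pad_value = 0)$values
  rhs <- 2 * apply_psf(X, psf, pad_value = 0)$values +
    3 * apply_psf(Y, psf, pad_value = 0)$values
  expect_equal(lhs, rhs, tolerance = 1e-8)

  ## fwhm 0 is the identity
  expect_identical(apply_psf(X, psf_spec(0)), X)
})

test_that("successive Gaussian passes compose as a single wider Gaussian", {
  obj <- make_sphere_image(D = 13, fwhm = 0, A = 10, B = 1)$image
  two <- apply_psf(apply_psf(obj, psf_spec(5), pad_value = 1),
                   psf_spec(5), pad_value = 1)
  one <- apply_psf(obj, psf_spec(sqrt(5^2 + 5^2)), pad_value = 1)
  rng <- diff(range(obj$values))
  expect_lt(max(abs(two$values - one$values)) / rng, 0.01)
})

test_that("noise is mean-scaled, seeded, reproducible, and RNG-clean", {
  img <- image_volume(array(10, c(100, 100, 100)))
  expect_identical(add_noise(img, noise_spec(0, 1)), img)

  n1 <- add_noise(img, noise_spec(0.05, 7))
  n2 <- add_noise(img, noise_spec(0.05, 7))
  expect_identical(n1$values, n2$values)
  n3 <- add_noise(img, noise_spec(0.05, 8))
  expect_false(identical(n1$values, n3$values))

  ## std = relative_sigma * mean = 0.5, law of large numbers at 1e6 voxels
  expect_equal(sd(n1$values), 0.5, tolerance = 0.01)

  ## the caller's RNG stream is not disturbed
  set.seed(123)
  r1 <- runif(3)
  set.seed(123)
  invisible(add_noise(img, noise_spec(0.05, 7)))
  expect_identical(runif(3), r1)
})

test_that("SBR series fixes sphere activity and scales the background", {
  base <- phantom_spec(list(sphere_spec("s", c(23.5, 23.5, 35), 17,
                                        sphere_activity = 10)),
                       0, c(48L, 48L, 36L))
  ser <- simulate_sbr_series(base, c(2, 4, 6, 8, 10), psf_spec(0),
                             oversample = 2)
  B <- vapply(ser, function(el) el$spec$background_activity, 0)
  expect_equal(B, 10 / c(2, 4, 6, 8, 10))
  A <- vapply(ser, function(el) el$spec$spheres[[1]]$sphere_activity, 0)
  expect_true(all(A == 10))
  expect_error(simulate_sbr_series(base, c(2, 1), psf_spec(0)), "> 1")
})

test_that("measured SBR of a simulated high-contrast phantom matches the target", {
  ## 37 mm sphere: the 20 mm core VOI barely sees spill-out at 7 mm FWHM
  sim <- make_sphere_image(D = 37, fwhm = 7, A = 10, B = 1,
                           grid = c(80L, 80L, 60L))
  bg_voi <- spherical_voi(c(8, 8, 12), 8, sim$image)
  sbr <- measure_sbr(sim$image, sim$center, bg_voi)
  expect_equal(sbr, 10, tolerance = 0.02)
})

test_that("autoradiography fields are deterministic with controllable structure", {
  ## no hotspots, no noise: constant baseline
  flat <- generate_autoradiography_field(extent = c(5, 5), pixel_size = 0.1,
                                         baseline = 3, hotspot_density = 0,
                                         pixel_noise_sigma = 0, seed = 1)
  expect_true(all(flat$values == 3))
  expect_equal(dim(flat$values), c(50L, 50L, 1L))
  expect_equal(flat$spacing, c(0.1, 0.1, 1))

  ## same seed, same field; different seed, different field
  f1 <- generate_autoradiography_field(extent = c(10, 5), pixel_size = 0.05,
                                       seed = 11)
  f2 <- generate_autoradiography_field(extent = c(10, 5), pixel_size = 0.05,
                                       seed = 11)
  f3 <- generate_autoradiography_field(extent = c(10, 5), pixel_size = 0.05,
                                       seed = 12)
  expect_identical(f1$values, f2$values)
  expect_false(identical(f1$values, f3$values))

  expect_error(generate_autoradiography_field(extent = c(-1, 5)), "extent")
})

test_that("default autoradiography field has the intended raw variability", {
  ## defaults target a raw CV near 11.7%; allow for hotspot shot noise on
  ## a reduced-area field
  f <- generate_autoradiography_field(extent = c(30, 20), pixel_size = 0.05,
                                      seed = 5)
  cv <- sd(f$values) / mean(f$values)
  expect_gt(cv, 0.07)
  expect_lt(cv, 0.17)
})
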