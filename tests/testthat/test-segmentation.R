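test_that("connected threshold handles constants, isolation, and seed exclusion", {
  img <- image_volume(array(4, c(6, 6, 6)))
  seg <- connected_threshold(img, c(3, 3, 3), 4)
  expect_equal(seg$n_voxels, 216L)
  expect_equal(seg$volume, 216)

  ## two bright blobs separated by a sub-threshold gap: only the seeded
  ## one is returned
  v <- array(0, c(10, 10, 10))
  v[2:4, 2:4, 2:4] <- 5
  v[7:9, 7:9, 7:9] <- 5
  img2 <- image_volume(v)
  seg2 <- connected_threshold(img2, c(3, 3, 3), 1)
  expect_equal(seg2$n_voxels, 27L)
  expect_identical(unname(seg2$mask[7:9, 7:9, 7:9]),
                   array(FALSE, c(3, 3, 3)))
  expect_identical(seg2$mask[2:4, 2:4, 2:4], array(TRUE, c(3, 3, 3)),
                   ignore_attr = TRUE)

  expect_error(connected_threshold(img2, c(3, 3, 3), 5 + 1e-9),
               "seed-excluded")
  expect_error(connected_threshold(img2, c(0, 3, 3), 1), "outside")
  expect_error(connected_threshold(img2, c(11, 3, 3), 1), "outside")
})

test_that("connected threshold matches the brute-force flood-fill oracle", {
  set.seed(99)
  for (i in 1:30) {
    conn <- if (i %% 2 == 0) 6L else 26L
    v <- array(runif(12^3), c(12, 12, 12))
    img <- image_volume(v)
    seed_vox <- sample(1:12, 3, replace = TRUE)
    T <- v[seed_vox[1], seed_vox[2], seed_vox[3]] * runif(1)
    seg <- connected_threshold(img, seed_vox, T, connectivity = conn)
    oracle <- flood_fill_oracle(v, seed_vox, T, connectivity = conn)
    expect_identical(unclass(seg$mask), oracle, ignore_attr = TRUE)
  }
})

test_that("segmented volume is non-increasing in the threshold", {
  sim <- make_sphere_image(D = 13, fwhm = 7, A = 10, B = 1)
  seed_vox <- nearest_voxel(sim$image, sim$center)
  Ts <- seq(1.05, max(sim$image$values), length.out = 50)
  vols <- vapply(Ts, function(T)
    connected_threshold(sim$image, seed_vox, T)$volume, 0)
  expect_true(all(diff(vols) <= 0))
})

test_that("VRT bisection reproduces the true volume of blurred spheres", {
  sim <- make_sphere_image(D = 37, fwhm = 7, A = 10, B = 1,
                           grid = c(80L, 80L, 60L))
  seed_vox <- nearest_voxel(sim$image, sim$center)
  vt <- (pi / 6) * 37^3
  seg <- find_vrt_threshold(sim$image, seed_vox, vt,
                            search_bounds = c(1, max(sim$image$values)))
  expect_lt(abs(seg$volume - vt), voxel_volume(sim$image) / 2)

  ## the threshold agrees with a dense sweep over all attainable volumes
  ## (the suprathreshold set of this radially monotone image is connected,
  ## so plain voxel counting is a valid independent oracle)
  vals <- sort(as.numeric(sim$image$values))
  keep <- vals > 1
  cand <- vals[keep]                      # distinct for this generic offset
  vols <- (length(vals) - which(keep) + 1) * voxel_volume(sim$image)
  best <- min(abs(vols - vt))
  expect_equal(abs(seg$volume - vt), best)
  expect_equal(seg$threshold_T, min(cand[abs(vols - vt) == best]))
})

test_that("VRT bisection reports the smallest threshold on a plateau", {
  ## two-level image: inner box at 10 in a background at 1; any threshold
  ## in (1, 10] reproduces the inner volume, and its canonical
  ## representative is the inner level itself
  v <- array(1, c(12, 12, 12))
  v[4:9, 4:9, 4:9] <- 10
  img <- image_volume(v)
  seg <- find_vrt_threshold(img, c(6, 6, 6), V_true = 6^3,
                            search_bounds = c(1, 10))
  expect_equal(seg$threshold_T, 10)
  expect_equal(seg$volume, 216)
})

test_that("VRT bisection reports which search bound is violated", {
  sim <- make_sphere_image(D = 10, fwhm = 7, A = 10, B = 1)
  seed_vox <- nearest_voxel(sim$image, sim$center)
  v_grid <- prod(dim(sim$image$values)) * voxel_volume(sim$image)
  expect_error(find_vrt_threshold(sim$image, seed_vox, 2 * v_grid,
                                  search_bounds = c(1, max(sim$image$values))),
               "lower bound")
  expect_error(find_vrt_threshold(sim$image, seed_vox, 1e-3,
                                  search_bounds = c(2, 3)),
               "upper bound")
})

test_that("VRT masks of radially monotone spheres are compact and centred", {
  sim <- make_sphere_image(D = 22, fwhm = 7, A = 10, B = 1)
  seed_vox <- nearest_voxel(sim$image, sim$center)
  seg <- find_vrt_threshold(sim$image, seed_vox, (pi / 6) * 22^3,
                            search_bounds = c(1, max(sim$image$values)))
  m <- seg$mask
  expect_true(m[seed_vox[1], seed_vox[2], seed_vox[3]])
  ## axis-convexity through the centre: one contiguous run of TRUE
  runs <- function(x) sum(rle(x)$values)
  expect_equal(runs(m[, seed_vox[2], seed_vox[3]]), 1L)
  expect_equal(runs(m[seed_vox[1], , seed_vox[3]]), 1L)
  expect_equal(runs(m[seed_vox[1], seed_vox[2], ]), 1L)
  ## connectedness: region growing from the seed inside the mask covers it
  sub <- image_volume(array(as.numeric(m), dim = dim(m)), sim$image$spacing)
  expect_equal(connected_threshold(sub, seed_vox, 1)$n_voxels, sum(m))
})

test_that("segmentation of blurred phantoms is insensitive to connectivity", {
  sim <- make_sphere_image(D = 17, fwhm = 7, A = 10, B = 1)
  seed_vox <- nearest_voxel(sim$image, sim$center)
  vt <- (pi / 6) * 17^3
  s6 <- find_vrt_threshold(sim$image, seed_vox, vt,
                           search_bounds = c(1, max(sim$image$values)),
                           connectivity = 6L)
  s26 <- find_vrt_threshold(sim$image, seed_vox, vt,
                            search_bounds = c(1, max(sim$image$values)),
                            connectivity = 26L)
  expect_equal(s6$threshold_T, s26$threshold_T)
  expect_equal(s6$volume, s26$volume)
})

test_that("centre of mass is intensity-weighted and voxel-rounded", {
  v <- array(0, c(9, 9, 9))
  v[5, 5, 5] <- 2
  img <- image_volume(v)
  voi <- array(TRUE, dim = dim(v))
  expect_equal(center_of_mass(img, voi), c(5L, 5L, 5L))

  ## two equal voxels two apart along one axis: midpoint voxel
  v2 <- array(0, c(9, 9, 9))
  v2[4, 5, 5] <- 1
  v2[6, 5, 5] <- 1
  expect_equal(center_of_mass(image_volume(v2), voi), c(5L, 5L, 5L))

  ## symmetric blurred sphere: its geometric centre voxel
  sim <- make_sphere_image(D = 17, fwhm = 7, A = 10, B = 0, offset = FALSE,
                           grid = c(41L, 41L, 31L), spacing = c(1, 1, 1))
  voi_s <- spherical_voi(sim$center, 30, sim$image)
  expect_equal(center_of_mass(sim$image, voi_s),
               nearest_voxel(sim$image, sim$center))

  expect_error(center_of_mass(img, array(FALSE, dim = dim(v))), "empty")
})

test_that("spherical VOIs count the voxels their geometry dictates", {
  img <- image_volume(array(0, c(40, 40, 30)), c(1, 1, 2))
  ## sub-voxel diameter centred on a voxel centre: exactly one voxel
  one <- spherical_voi(c(10, 10, 20), 0.5, img)
  expect_equal(sum(one), 1L)
  ## 20 mm VOI on the 1 x 1 x 2 mm grid: (pi/6) 20^3 within 3%
  v20 <- spherical_voi(c(19.5, 19.5, 29), 20, img)
  expect_equal(mask_volume(v20), (pi / 6) * 20^3, tolerance = 0.03)
  ## centre far outside the grid: empty mask, flagged via a message
  expect_message(out <- spherical_voi(c(-100, 0, 0), 5, img), "empty")
  expect_equal(sum(out), 0L)
})
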