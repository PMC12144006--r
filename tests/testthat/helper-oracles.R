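## Independent oracles and small fixture builders used across the tests.

## Brute-force seeded flood fill: per-voxel breadth-first search with an
## explicit queue, independent of the package's vectorized frontier code.
flood_fill_oracle <- function(values, seed, T, connectivity = 6L) {
  d <- dim(values)
  offs <- if (connectivity == 6L) {
    list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  } else {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
    lapply(seq_len(nrow(g)), function(i) g[i, ])
  }
  mask <- array(FALSE, dim = d)
  if (values[seed[1], seed[2], seed[3]] < T) stop("seed below threshold")
  queue <- list(seed)
  mask[seed[1], seed[2], seed[3]] <- TRUE
  while (length(queue)) {
    cur <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (o in offs) {
      nb <- cur + o
      if (any(nb < 1L) || any(nb > d)) next
      if (!mask[nb[1], nb[2], nb[3]] && values[nb[1], nb[2], nb[3]] >= T) {
        mask[nb[1], nb[2], nb[3]] <- TRUE
        queue[[length(queue) + 1L]] <- nb
      }
    }
  }
  mask
}

## Brute-force two-sample KS statistic: ECDF difference evaluated at
## every sample point.
ks_D_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(x) mean(a <= x), 0)
  Fb <- vapply(pts, function(x) mean(b <= x), 0)
  max(abs(Fa - Fb))
}

## Closed-form radial profile of a unit sphere of radius R convolved with
## an isotropic 3D Gaussian of standard deviation sigma (verified against
## direct numerical integration of the spherical-shell integral).
blurred_sphere_profile <- function(r, R, sigma) {
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  a <- (r + R) / (sigma * sqrt(2))
  b <- (r - R) / (sigma * sqrt(2))
  ifelse(r < 1e-9,
         erf(R / (sigma * sqrt(2))) -
           sqrt(2 / pi) * (R / sigma) * exp(-R^2 / (2 * sigma^2)),
         0.5 * (erf(a) - erf(b)) -
           (sigma / (r * sqrt(2 * pi))) * (exp(-b^2) - exp(-a^2)))
}

## Simulated single-sphere image: rasterized and PSF-blurred, with a
## generic sub-voxel centre offset unless asked otherwise.
make_sphere_image <- function(D = 10, fwhm = 7, A = 10, B = 1,
                              wall = 0, grid = c(48L, 48L, 36L),
                              spacing = c(1, 1, 2), offset = TRUE,
                              oversample = 4L) {
  extent <- (grid - 1) * spacing
  center <- extent / 2 + if (offset) c(0.333, 0.251, 0.107) * spacing else 0
  s <- sphere_spec("s", center, D, wall_thickness = wall,
                   sphere_activity = A)
  ph <- phantom_spec(list(s), background_activity = B, grid_shape = grid,
                     voxel_spacing = spacing)
  img <- rasterize_phantom(ph, oversample = oversample)
  if (fwhm > 0) img <- apply_psf(img, psf_spec(fwhm), pad_value = B)
  list(image = img, sphere = s, spec = ph, center = center)
}

## seed voxel nearest a physical point
nearest_voxel <- function(img, point) {
  as.integer(round((point - img$origin) / img$spacing)) + 1L
}
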