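#' Configuration of a wall-less vs. fillable threshold experiment
#'
#' Collects every parameter that, together with the package version,
#' fully determines a simulated experiment.  The defaults reproduce the
#' reference study conditions: the six NEMA sphere diameters on the
#' clinical 1 x 1 x 2 mm reconstruction grid, SBR targets 2/4/6/8/10, a
#' 7 mm effective Gaussian resolution (5 mm reconstruction filter
#' combined with intrinsic scanner resolution), a 1 mm cold wall for the
#' fillable variant, and noiseless images.
#'
#' @param diameters_mm sphere inner diameters in mm.
#' @param wall_thickness_mm cold-wall thickness of the fillable variant.
#' @param sphere_activity fixed sphere activity concentration.
#' @param sbr_targets signal-to-background ratios (> 1 each).
#' @param psf_fwhm_mm effective Gaussian resolution, FWHM in mm.
#' @param noise_sigma relative noise level (0 = noiseless).
#' @param seed integer base seed for all random draws.
#' @param grid_shape per-sphere sub-volume grid (voxels).
#' @param voxel_spacing_mm voxel pitch in mm.
#' @param oversample rasterization anti-aliasing rate.
#' @param connectivity region-growing connectivity, 6 or 26.
#' @param a_definition reference-activity definition,
#'   \code{"image_mean"} or \code{"true"}
#'   (see \code{\link{reference_activity}}).
#' @param kl_bins histogram bins for KL divergence.
#' @param profile_margin_mm margin for radial profiles.
#' @return object of class \code{experiment_config} (a list).
#' @export
experiment_config <- function(diameters_mm = c(10, 13, 17, 22, 28, 37),
                              wall_thickness_mm = 1,
                              sphere_activity = 10,
                              sbr_targets = c(2, 4, 6, 8, 10),
                              psf_fwhm_mm = 7,
                              noise_sigma = 0,
                              seed = 1L,
                              grid_shape = c(80L, 80L, 60L),
                              voxel_spacing_mm = c(1, 1, 2),
                              oversample = 4L,
                              connectivity = 6L,
                              a_definition = c("image_mean", "true"),
                              kl_bins = 64L,
                              profile_margin_mm = 10) {
  a_definition <- match.arg(a_definition)
  if (any(sbr_targets <= 1)) stop("'sbr_targets' must all exceed 1")
  if (any(diameters_mm <= 0)) stop("'diameters_mm' must be positive")
  structure(list(diameters_mm = diameters_mm,
                 wall_thickness_mm = wall_thickness_mm,
                 sphere_activity = sphere_activity,
                 sbr_targets = sbr_targets,
                 psf_fwhm_mm = psf_fwhm_mm,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed),
                 grid_shape = as.integer(grid_shape),
                 voxel_spacing_mm = voxel_spacing_mm,
                 oversample = as.integer(oversample),
                 connectivity = as.integer(connectivity),
                 a_definition = a_definition,
                 kl_bins = as.integer(kl_bins),
                 profile_margin_mm = profile_margin_mm),
            class = "experiment_config")
}

## build the single-sphere sub-volume phantom for one diameter; the
## centre gets a generic sub-voxel offset, as a physical sphere is never
## aligned with the voxel grid (alignment would create degenerate
## intensity ties that coarsen the attainable segmented volumes)
single_sphere_phantom <- function(config, diameter, walled) {
  extent <- (config$grid_shape - 1) * config$voxel_spacing_mm
  center <- extent / 2 + c(0.333, 0.251, 0.107) * config$voxel_spacing_mm
  s <- sphere_spec(id = sprintf("D%02.0fmm", diameter), center = center,
                   inner_diameter = diameter,
                   wall_thickness = if (walled) config$wall_thickness_mm else 0,
                   sphere_activity = config$sphere_activity,
                   wall_activity = 0)
  phantom_spec(spheres = list(s), background_activity = 0,
               grid_shape = config$grid_shape,
               voxel_spacing = config$voxel_spacing_mm)
}

## VRT of one simulated sphere image: seed at the centre-of-mass voxel of
## a generous VOI, bisection bounds (background, image max)
vrt_for_image <- function(img, spec, config) {
  s <- spec$spheres[[1]]
  B <- spec$background_activity
  voi <- spherical_voi(s$center, s$inner_diameter + 2 * config$psf_fwhm_mm, img)
  seed_vox <- center_of_mass(img, voi)
  seg <- find_vrt_threshold(img, seed_vox, true_volume(s),
                            search_bounds = c(B, max(img$values)),
                            connectivity = config$connectivity)
  A <- reference_activity(img, s, definition = config$a_definition)
  list(seg = seg, seed_voxel = seed_vox, A = A, B = B,
       vrt = relative_vrt(seg$threshold_T, A, B))
}

#' Run the full wall-less vs. fillable threshold experiment
#'
#' Simulates every sphere diameter at every SBR target in both variants
#' (wall-less and fillable with a cold wall), determines each sphere's
#' volume-reproducing threshold by bisection over seeded region growing,
#' converts it to the background-corrected relative threshold, and
#' derives the contrast-dependence statistics, the per-SBR differences in
#' percentage points between the variants, and the volume overestimation
#' obtained when the fillable-derived relative thresholds are used to
#' segment the wall-less images.
#'
#' @param config an \code{\link{experiment_config}}.
#' @param keep_images keep the simulated \code{image_volume}s in the
#'   returned object (default \code{FALSE}; they are large).
#' @param verbose print progress.
#' @return object of class \code{vrt_experiment} with elements
#'   \code{records} (data frame: sphere_id, diameter_mm, sbr_target,
#'   sbr_measured, variant, T, A, B, vrt, volume_mm3), \code{cv_wallless}
#'   and \code{cv_walled} (from \code{\link{vrt_contrast_cv}}),
#'   \code{diff_pp} (data frame of wall-less minus fillable VRT in
#'   percentage points), \code{overestimation} (data frame from
#'   \code{\link{cross_apply_vrt}}) and \code{config}.
#' @export
run_vrt_experiment <- function(config = experiment_config(),
                               keep_images = FALSE, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  psf <- psf_spec(config$psf_fwhm_mm)
  rows <- list()
  over_rows <- list()
  images <- list()
  wl_cache <- list()   # per (diameter, sbr): wall-less image + fit

  for (variant in c("wallless", "walled")) {
    walled <- variant == "walled"
    for (di in seq_along(config$diameters_mm)) {
      D <- config$diameters_mm[di]
      base <- single_sphere_phantom(config, D, walled)
      noise <- noise_spec(config$noise_sigma,
                          config$seed + 1000L * di + if (walled) 500L else 0L)
      series <- simulate_sbr_series(base, config$sbr_targets, psf, noise,
                                    oversample = config$oversample)
      for (si in seq_along(series)) {
        el <- series[[si]]
        fit <- vrt_for_image(el$image, el$spec, config)
        s <- el$spec$spheres[[1]]
        bg_voi <- background_corner_voi(el$image, el$spec, config$psf_fwhm_mm)
        sbr_meas <- measure_sbr(el$image, s$center, bg_voi,
                                voi_diameter = min(20, s$inner_diameter))
        rows[[length(rows) + 1L]] <- data.frame(
          sphere_id = s$id, diameter_mm = D, sbr_target = el$sbr_target,
          sbr_measured = sbr_meas, variant = variant,
          T = fit$seg$threshold_T, A = fit$A, B = fit$B, vrt = fit$vrt,
          volume_mm3 = fit$seg$volume)
        key <- sprintf("%s_sbr%g", s$id, el$sbr_target)
        if (!walled)
          wl_cache[[key]] <- list(image = el$image, fit = fit, spec = el$spec)
        if (keep_images)
          images[[paste(variant, key, sep = "_")]] <- el$image
        if (verbose)
          message(sprintf("%s %s SBR %g: T = %.3f, VRT = %.1f%%",
                          variant, s$id, el$sbr_target, fit$seg$threshold_T,
                          100 * fit$vrt))
      }
    }
  }
  records <- do.call(rbind, rows)

  wl <- records[records$variant == "wallless", ]
  wd <- records[records$variant == "walled", ]
  cv_wallless <- vrt_contrast_cv(wl)
  cv_walled <- vrt_contrast_cv(wd)

  key_of <- function(df) sprintf("%s_sbr%g", df$sphere_id, df$sbr_target)
  m <- match(key_of(wd), key_of(wl))
  diff_pp <- data.frame(sphere_id = wd$sphere_id,
                        diameter_mm = wd$diameter_mm,
                        sbr_target = wd$sbr_target,
                        diff_pp = 100 * (wl$vrt[m] - wd$vrt))

  for (i in seq_len(nrow(wd))) {
    cache <- wl_cache[[key_of(wd)[i]]]
    s <- cache$spec$spheres[[1]]
    rec <- cross_apply_vrt(wd$vrt[i], cache$fit$A, cache$fit$B,
                           cache$image, cache$fit$seed_voxel,
                           true_volume(s), config$connectivity)
    over_rows[[i]] <- data.frame(
      sphere_id = wd$sphere_id[i], diameter_mm = wd$diameter_mm[i],
      sbr_target = wd$sbr_target[i], V_true = rec$V_true,
      V_star = rec$V_star, overestimation_pct = rec$overestimation)
  }
  overestimation <- do.call(rbind, over_rows)

  structure(list(records = records, cv_wallless = cv_wallless,
                 cv_walled = cv_walled, diff_pp = diff_pp,
                 overestimation = overestimation, config = config,
                 images = if (keep_images) images else NULL),
            class = "vrt_experiment")
}

## spherical background VOI tucked into a grid corner, clear of the
## sphere and of the convolution boundary
background_corner_voi <- function(img, spec, fwhm) {
  s <- spec$spheres[[1]]
  sigma <- fwhm / 2.3548
  d <- dim(img$values)
  corner_idx <- pmax(1, round(d * 0.12))
  corner <- voxel_position(img, matrix(corner_idx, 1))
  spherical_voi(as.numeric(corner), 8, img)
}

#' @export
print.vrt_experiment <- function(x, ...) {
  nl <- length(unique(x$records$diameter_mm))
  cat(sprintf("<vrt_experiment> %d spheres x %d SBR levels x 2 variants\n",
              nl, length(x$config$sbr_targets)))
  cat(sprintf("  mean VRT CV over SBRs: wall-less %.2f%%, fillable %.2f%%\n",
              100 * x$cv_wallless$mean_cv, 100 * x$cv_walled$mean_cv))
  cat(sprintf("  max VRT difference: %.1f pp; max volume overestimation: %.1f%%\n",
              max(x$diff_pp$diff_pp), max(x$overestimation$overestimation_pct)))
  invisible(x)
}

#' @export
summary.vrt_experiment <- function(object, ...) {
  cat("Volume-reproducing thresholds (%) by sphere and SBR\n\n")
  for (variant in c("wallless", "walled")) {
    r <- object$records[object$records$variant == variant, ]
    tab <- round(100 * stats::xtabs(vrt ~ diameter_mm + sbr_target, data = r), 1)
    cat(sprintf("-- %s --\n", c(wallless = "wall-less",
                                walled = "fillable (cold wall)")[variant]))
    print(tab)
    cat("\n")
  }
  cat(sprintf("Per-sphere VRT CV over SBRs (%%), wall-less:\n"))
  print(round(100 * object$cv_wallless$per_sphere, 3))
  cat(sprintf("mean: %.3f%%\n\n", 100 * object$cv_wallless$mean_cv))
  cat(sprintf("Per-sphere VRT CV over SBRs (%%), fillable:\n"))
  print(round(100 * object$cv_walled$per_sphere, 3))
  cat(sprintf("mean: %.3f%%\n\n", 100 * object$cv_walled$mean_cv))
  cat("Volume overestimation (%) from cross-applied fillable thresholds\n")
  print(round(stats::xtabs(overestimation_pct ~ diameter_mm + sbr_target,
                           data = object$overestimation), 1))
  invisible(object)
}

#' @export
plot.vrt_experiment <- function(x, which = c("vrt", "overestimation"), ...) {
  which <- match.arg(which)
  cols <- grDevices::hcl.colors(length(unique(x$records$diameter_mm)),
                                "Dark 3")
  if (which == "vrt") {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
    for (variant in c("wallless", "walled")) {
      r <- x$records[x$records$variant == variant, ]
      tab <- stats::xtabs(vrt ~ sbr_target + diameter_mm, data = r)
      graphics::matplot(as.numeric(rownames(tab)), 100 * tab, type = "b",
                        pch = 16, lty = 1, col = cols, ylim = c(30, 85),
                        xlab = "SBR", ylab = "VRT [%]",
                        main = c(wallless = "wall-less",
                                 walled = "fillable")[variant])
      graphics::legend("topright", legend = paste0(colnames(tab), " mm"),
                       col = cols, lty = 1, pch = 16, cex = 0.7, bty = "n")
    }
  } else {
    tab <- stats::xtabs(overestimation_pct ~ sbr_target + diameter_mm,
                        data = x$overestimation)
    graphics::matplot(as.numeric(rownames(tab)), tab, type = "b", pch = 16,
                      lty = 1, col = cols, xlab = "SBR",
                      ylab = "volume overestimation [%]")
    graphics::legend("topright", legend = paste0(colnames(tab), " mm"),
                     col = cols, lty = 1, pch = 16, cex = 0.7, bty = "n")
  }
  invisible(x)
}

#' Write experiment result tables to CSV files
#'
#' @param x a \code{vrt_experiment}.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_vrt_results <- function(x, dir) {
  stopifnot(inherits(x, "vrt_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("vrt_records.csv", "vrt_diff_pp.csv",
                            "overestimation.csv"))
  utils::write.csv(x$records, paths[1], row.names = FALSE)
  utils::write.csv(x$diff_pp, paths[2], row.names = FALSE)
  utils::write.csv(x$overestimation, paths[3], row.names = FALSE)
  invisible(paths)
}
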