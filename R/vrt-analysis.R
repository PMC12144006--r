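#' Background-corrected relative volume-reproducing threshold
#'
#' Converts an absolute threshold \code{T} into the background-corrected
#' relative threshold \code{(T - B) / (A - B)}, which for wall-less
#' objects is independent of the sphere activity \code{A} and background
#' activity \code{B} individually.
#'
#' @param T absolute intensity threshold.
#' @param A reference activity concentration of the sphere (> B).
#' @param B background activity concentration.
#' @return the relative threshold as a fraction (0 when \code{T = B},
#'   1 when \code{T = A}).
#' @export
relative_vrt <- function(T, A, B) {
  if (any(A <= B)) stop("'A' must exceed 'B' (undefined contrast)")
  (T - B) / (A - B)
}

#' Measure the signal-to-background ratio of a phantom image
#'
#' Ratio of the mean intensity in a small VOI at the centre of the
#' largest sphere (20 mm diameter by default, small enough that spill-out
#' from a 37 mm sphere barely reaches it) to the mean intensity in a
#' user-supplied background VOI.
#'
#' @param img an \code{\link{image_volume}}.
#' @param largest_sphere_center physical centre (mm) of the largest sphere.
#' @param background_voi logical array congruent with \code{img}.
#' @param voi_diameter diameter of the central VOI in mm.
#' @return the measured SBR (scalar).
#' @export
measure_sbr <- function(img, largest_sphere_center, background_voi,
                        voi_diameter = 20) {
  voi <- spherical_voi(largest_sphere_center, voi_diameter, img)
  if (!any(voi)) stop("central VOI is empty")
  if (!any(background_voi)) stop("background VOI is empty")
  bg <- mean(img$values[background_voi])
  if (bg <= 0) stop("background mean must be > 0")
  mean(img$values[voi]) / bg
}

#' Image-derived reference activity of a sphere
#'
#' Mean image intensity over the sphere's true geometry (a spherical VOI
#' of the nominal inner diameter at the sphere centre).  This mean-based
#' reference decreases with decreasing sphere size under blurring, which
#' is what makes the relative threshold size-dependent.  Alternatively
#' the true (specified) concentration can be requested.
#'
#' @param img an \code{\link{image_volume}}.
#' @param sphere a \code{\link{sphere_spec}}.
#' @param definition \code{"image_mean"} (default) or \code{"true"}.
#' @return the reference activity concentration (scalar).
#' @export
reference_activity <- function(img, sphere,
                               definition = c("image_mean", "true")) {
  definition <- match.arg(definition)
  if (definition == "true") return(sphere$sphere_activity)
  voi <- spherical_voi(sphere$center, sphere$inner_diameter, img)
  if (!any(voi)) stop("sphere VOI covers no voxel centres")
  mean(img$values[voi])
}

#' Contrast dependence of the relative threshold
#'
#' For each sphere, the coefficient of variation (sample sd / mean, n-1
#' denominator) of its relative threshold across the SBR levels; these
#' per-sphere CVs are then averaged, unweighted, over the sphere sizes.
#'
#' @param records data frame with columns \code{sphere_id} and \code{vrt}
#'   (one row per sphere x SBR), e.g. the \code{$records} table of
#'   \code{\link{run_vrt_experiment}}.
#' @return list with \code{per_sphere} (named numeric vector of CVs) and
#'   \code{mean_cv} (scalar).
#' @export
vrt_contrast_cv <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("sphere_id", "vrt") %in% names(records)))
  counts <- table(records$sphere_id)
  if (any(counts < 2L))
    stop("every sphere needs at least two SBR levels to compute a CV")
  per <- tapply(records$vrt, records$sphere_id,
                function(v) stats::sd(v) / mean(v))
  per <- per[unique(as.character(records$sphere_id))]
  list(per_sphere = per, mean_cv = mean(per))
}

#' Segment a wall-less image with a threshold derived elsewhere
#'
#' Applies a relative threshold obtained from one phantom type (typically
#' the fillable, walled spheres) to a wall-less image: the absolute
#' threshold \code{T = B + vrt * (A - B)} is computed from the wall-less
#' image's own reference activities and used for region growing, and the
#' resulting volume \code{V*} is compared with the true volume.
#'
#' @param vrt_from_walled relative threshold (fraction) to cross-apply.
#' @param A,B reference sphere and background activity concentrations of
#'   the wall-less image (\code{A > B}).
#' @param wallless_img the wall-less \code{\link{image_volume}}.
#' @param seed_voxel 1-based voxel index inside the sphere.
#' @param V_true true sphere volume in mm^3.
#' @param connectivity passed to \code{\link{connected_threshold}}.
#' @return list of class \code{overestimation_record}: \code{V_true},
#'   \code{V_star}, \code{overestimation} (percent,
#'   \code{100 (V* - V_true) / V_true}), \code{threshold_T} and the
#'   segmentation itself.
#' @export
cross_apply_vrt <- function(vrt_from_walled, A, B, wallless_img, seed_voxel,
                            V_true, connectivity = 6L) {
  if (A <= B) stop("'A' must exceed 'B'")
  if (V_true <= 0) stop("'V_true' must be > 0")
  T <- B + vrt_from_walled * (A - B)
  seg <- connected_threshold(wallless_img, seed_voxel, T, connectivity)
  structure(list(V_true = V_true, V_star = seg$volume,
                 overestimation = 100 * (seg$volume - V_true) / V_true,
                 threshold_T = T, segmentation = seg),
            class = "overestimation_record")
}

#' @export
print.overestimation_record <- function(x, ...) {
  cat(sprintf("<overestimation_record> V_true = %.0f, V* = %.0f mm^3 (%+.1f%%), T = %g\n",
              x$V_true, x$V_star, x$overestimation, x$threshold_T))
  invisible(x)
}

#' Mirrored radial intensity profile of a sphere
#'
#' Collects every voxel within \code{inner_diameter/2 + margin} of the
#' sphere's centre-of-mass voxel and records its intensity against its
#' radial distance from that voxel; a mirrored copy (negated distances,
#' with r = 0 not duplicated) is appended so the profile plots
#' symmetrically about the centre.
#'
#' @param img an \code{\link{image_volume}}.
#' @param sphere a \code{\link{sphere_spec}}.
#' @param margin extra radius beyond the nominal sphere in mm (>= 0).
#' @param vrt_level optional absolute threshold to attach for plotting.
#' @return object of class \code{profile_series}: list with
#'   \code{points} (data frame \code{r_mm}, \code{intensity}),
#'   \code{reference_level} (the sphere's true concentration),
#'   \code{vrt_level}, \code{sphere_radius} and \code{center_voxel}.
#' @export
radial_intensity_profile <- function(img, sphere, margin = 10,
                                     vrt_level = NULL) {
  stopifnot(inherits(img, "image_volume"), inherits(sphere, "sphere_spec"))
  if (margin < 0) stop("'margin' must be >= 0")
  radius <- sphere$inner_diameter / 2 + margin
  voi <- spherical_voi(sphere$center, 2 * radius, img)
  if (!any(voi)) stop("profile VOI covers no voxel centres")
  com <- center_of_mass(img, voi)
  com_pos <- voxel_position(img, matrix(com, 1))
  idx <- arrayInd(which(voi), dim(img$values))
  pos <- voxel_position(img, idx)
  r <- sqrt(rowSums(sweep(pos, 2L, as.numeric(com_pos), `-`)^2))
  intens <- img$values[voi]
  pts <- data.frame(r_mm = c(r, -r[r > 0]),
                    intensity = c(intens, intens[r > 0]))
  structure(list(points = pts[order(pts$r_mm), ],
                 reference_level = sphere$sphere_activity,
                 vrt_level = vrt_level,
                 sphere_radius = sphere$inner_diameter / 2,
                 center_voxel = com),
            class = "profile_series")
}

#' @export
plot.profile_series <- function(x, ...,
                                xlab = "radial distance [mm]",
                                ylab = "intensity") {
  plot(x$points$r_mm, x$points$intensity, pch = 16, cex = 0.4,
       col = grDevices::grey(0.3), xlab = xlab, ylab = ylab, ...)
  graphics::abline(v = c(-1, 1) * x$sphere_radius, lty = 3)
  graphics::abline(h = x$reference_level, col = "grey60", lwd = 4)
  if (!is.null(x$vrt_level))
    graphics::abline(h = x$vrt_level, col = "red3", lty = 2)
  invisible(x)
}
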