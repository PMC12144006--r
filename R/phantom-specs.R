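#' Specification of a single phantom sphere
#'
#' Describes one sphere of a digital NEMA-style phantom: its position, its
#' nominal (inner) diameter, an optional inactive wall shell, and the
#' activity concentrations of the sphere interior and of the wall.  NEMA
#' sphere diameters are inner diameters; a wall of thickness
#' \code{wall_thickness} is placed outside the nominal diameter and
#' displaces background.  \code{wall_thickness = 0} gives a wall-less
#' (3D-printed-like) sphere.
#'
#' @param id character label.
#' @param center numeric length-3, sphere centre in physical mm.
#' @param inner_diameter nominal sphere diameter in mm (> 0).
#' @param wall_thickness wall shell thickness in mm (>= 0; 0 = wall-less).
#' @param sphere_activity activity concentration of the sphere interior
#'   (arbitrary units per mL).
#' @param wall_activity activity concentration of the wall (default 0,
#'   i.e. a cold wall).
#' @return object of class \code{sphere_spec}.
#' @export
sphere_spec <- function(id, center, inner_diameter, wall_thickness = 0,
                        sphere_activity = 1, wall_activity = 0) {
  stopifnot(length(center) == 3L, all(is.finite(center)))
  if (!is.finite(inner_diameter) || inner_diameter <= 0)
    stop("'inner_diameter' must be > 0")
  if (!is.finite(wall_thickness) || wall_thickness < 0)
    stop("'wall_thickness' must be >= 0")
  structure(list(id = as.character(id), center = as.numeric(center),
                 inner_diameter = inner_diameter,
                 wall_thickness = wall_thickness,
                 sphere_activity = sphere_activity,
                 wall_activity = wall_activity),
            class = "sphere_spec")
}

#' True (analytic) volume of a sphere specification
#' @param sphere a \code{sphere_spec}
#' @return volume of the inner sphere in mm^3, (pi/6) d^3
#' @export
true_volume <- function(sphere) (pi / 6) * sphere$inner_diameter^3

#' Specification of a digital phantom
#'
#' A set of spheres in a uniform active background on a voxel grid.
#'
#' @param spheres list of \code{\link{sphere_spec}} objects.
#' @param background_activity background activity concentration (>= 0).
#' @param grid_shape integer length-3, number of voxels per axis.
#' @param voxel_spacing numeric length-3, mm per voxel (default the
#'   clinical reconstruction grid 1 x 1 x 2 mm).
#' @param origin physical position (mm) of the centre of voxel (1,1,1).
#' @return object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(spheres = list(), background_activity = 0,
                         grid_shape = c(80L, 80L, 60L),
                         voxel_spacing = c(1, 1, 2),
                         origin = c(0, 0, 0)) {
  if (inherits(spheres, "sphere_spec")) spheres <- list(spheres)
  stopifnot(all(vapply(spheres, inherits, TRUE, "sphere_spec")))
  if (!is.finite(background_activity) || background_activity < 0)
    stop("'background_activity' must be >= 0")
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L))
  voxel_spacing <- as.numeric(voxel_spacing)
  stopifnot(length(voxel_spacing) == 3L, all(voxel_spacing > 0))
  structure(list(spheres = spheres, background_activity = background_activity,
                 grid_shape = grid_shape, voxel_spacing = voxel_spacing,
                 origin = as.numeric(origin)),
            class = "phantom_spec")
}

#' Gaussian point-spread-function specification
#'
#' Isotropic effective resolution of the simulated scanner, combining the
#' intrinsic detector resolution and the reconstruction smoothing filter
#' into a single Gaussian full width at half maximum.
#'
#' @param fwhm full width at half maximum in mm (>= 0; 0 disables blurring).
#' @return object of class \code{psf_spec}.
#' @export
psf_spec <- function(fwhm) {
  if (!is.finite(fwhm) || fwhm < 0) stop("'fwhm' must be >= 0")
  structure(list(fwhm = fwhm), class = "psf_spec")
}

#' Image-noise specification
#'
#' Zero-mean Gaussian noise with standard deviation
#' \code{relative_sigma * mean(image)}, added per voxel before PSF
#' filtering so that the reconstruction smoothing correlates it, as it
#' does for real count noise.
#'
#' @param relative_sigma unitless noise level (>= 0; 0 = noiseless).
#' @param seed integer seed making each noise draw reproducible.
#' @return object of class \code{noise_spec}.
#' @export
noise_spec <- function(relative_sigma = 0, seed = 1L) {
  if (!is.finite(relative_sigma) || relative_sigma < 0)
    stop("'relative_sigma' must be >= 0")
  structure(list(relative_sigma = relative_sigma, seed = as.integer(seed)),
            class = "noise_spec")
}
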