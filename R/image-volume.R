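#' Image volume with physical voxel geometry
#'
#' Lightweight container for a 3D intensity grid together with its physical
#' voxel spacing and origin.  All geometry is in millimetres; voxel indices
#' are 1-based and a voxel's physical position is the position of its
#' centre.  2D data (e.g. autoradiography fields) are stored with a
#' singleton third axis.
#'
#' @param values numeric array, 2D or 3D; 2D input gains a singleton third
#'   axis.  All values must be finite.
#' @param spacing numeric vector of length 3 (mm per voxel along each
#'   axis), strictly positive.  A scalar is recycled.
#' @param origin numeric vector of length 3: physical position (mm) of the
#'   centre of voxel (1, 1, 1).
#' @return An object of class \code{image_volume}: a list with elements
#'   \code{values}, \code{spacing}, \code{origin}.
#' @export
image_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.matrix(values)) dim(values) <- c(dim(values), 1L)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 2D or 3D array")
  if (!all(is.finite(values))) stop("'values' must be finite")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive values (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("'origin' must have length 3")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x ")))
  cat(sprintf("  value range [%g, %g], origin (%s) mm\n",
              min(x$values), max(x$values),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$values)

#' Volume of one voxel in cubic millimetres
#' @param img an \code{image_volume} (or a \code{voi_mask})
#' @return scalar, mm^3
#' @export
voxel_volume <- function(img) {
  sp <- if (inherits(img, "image_volume")) img$spacing else attr(img, "spacing")
  prod(sp)
}

## physical coordinates (mm) of voxel centres along one axis
axis_coords <- function(img, axis) {
  n <- dim(img$values)[axis]
  img$origin[axis] + (seq_len(n) - 1) * img$spacing[axis]
}

## physical position (mm) of given 1-based voxel indices (matrix n x 3)
voxel_position <- function(img, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  sweep(sweep(idx - 1, 2L, img$spacing, `*`), 2L, img$origin, `+`)
}
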