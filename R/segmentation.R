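#' Seeded connected-threshold segmentation
#'
#' Region growing: returns the maximal connected set of voxels with value
#' \code{>= T} (inclusive comparison) that contains the seed voxel, under
#' face (6) or face+edge+corner (26) connectivity.
#'
#' @param img an \code{\link{image_volume}}.
#' @param seed_voxel integer length-3, 1-based voxel index.
#' @param T absolute intensity threshold.
#' @param connectivity 6 (default) or 26.
#' @return object of class \code{segmentation_result}: list with
#'   \code{mask} (logical array, a \code{voi_mask} with the image spacing
#'   attached), \code{threshold_T}, \code{volume} (mm^3, voxel count times
#'   voxel volume), \code{n_voxels} and \code{seed_voxel}.
#' @export
connected_threshold <- function(img, seed_voxel, T, connectivity = 6L) {
  stopifnot(inherits(img, "image_volume"))
  if (!connectivity %in% c(6L, 26L)) stop("'connectivity' must be 6 or 26")
  d <- dim(img$values)
  seed_voxel <- as.integer(seed_voxel)
  if (length(seed_voxel) != 3L || any(seed_voxel < 1L) || any(seed_voxel > d))
    stop("seed voxel outside the image grid")
  if (img$values[seed_voxel[1], seed_voxel[2], seed_voxel[3]] < T)
    stop("seed-excluded: seed voxel intensity is below the threshold")

  above <- img$values >= T
  visited <- array(FALSE, dim = d)
  seed_lin <- seed_voxel[1] + (seed_voxel[2] - 1L) * d[1] +
    (seed_voxel[3] - 1L) * d[1] * d[2]
  visited[seed_lin] <- TRUE
  offsets <- if (connectivity == 6L) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
          c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  }
  frontier <- seed_lin
  while (length(frontier)) {
    co <- arrayInd(frontier, d)
    nxt <- integer(0)
    for (k in seq_len(nrow(offsets))) {
      nb <- co + matrix(offsets[k, ], nrow(co), 3L, byrow = TRUE)
      ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] &
            nb[, 2] >= 1L & nb[, 2] <= d[2] &
            nb[, 3] >= 1L & nb[, 3] <= d[3]
      if (!any(ok)) next
      lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] + (nb[ok, 3] - 1L) * d[1] * d[2]
      lin <- lin[above[lin] & !visited[lin]]
      if (length(lin)) {
        visited[lin] <- TRUE
        nxt <- c(nxt, lin)
      }
    }
    frontier <- unique(nxt)
  }
  mask <- structure(visited, spacing = img$spacing, class = "voi_mask")
  structure(list(mask = mask, threshold_T = T,
                 volume = sum(visited) * prod(img$spacing),
                 n_voxels = sum(visited), seed_voxel = seed_voxel),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> T = %g, %d voxels, volume = %.1f mm^3\n",
              x$threshold_T, x$n_voxels, x$volume))
  invisible(x)
}

#' Find the absolute volume-reproducing threshold by bisection
#'
#' Determines the threshold \code{T} at which the seeded
#' connected-threshold segmentation reproduces the known true volume of
#' the object.  Because the segmented volume is non-increasing in
#' \code{T}, the search is a bisection between \code{search_bounds}.  It
#' terminates when the volume error falls below half a voxel or the
#' bracket has shrunk below 1e-6 of its initial width, and returns the
#' best-visited iterate (ties broken toward the lower threshold).  On a
#' discrete image the segmented volume is a step function of \code{T}
#' constant on intervals between consecutive voxel values; the returned
#' threshold is snapped to the canonical representative of its plateau,
#' the smallest voxel value producing the same segment, so that plateaus
#' of exactly volume-reproducing thresholds report their smallest member.
#'
#' @param img an \code{\link{image_volume}}.
#' @param seed_voxel 1-based voxel index inside the object.
#' @param V_true target volume in mm^3 (> 0).
#' @param search_bounds length-2 numeric \code{c(lower, upper)}; the
#'   volume at the lower bound must be >= \code{V_true} and at the upper
#'   bound <= \code{V_true}.  Default: \code{c(min(img), max(img))}.
#' @param connectivity passed to \code{\link{connected_threshold}}.
#' @return a \code{segmentation_result} at the selected threshold.
#' @export
find_vrt_threshold <- function(img, seed_voxel, V_true,
                               search_bounds = NULL, connectivity = 6L) {
  stopifnot(inherits(img, "image_volume"))
  if (!is.finite(V_true) || V_true <= 0) stop("'V_true' must be > 0")
  if (is.null(search_bounds))
    search_bounds <- range(img$values)
  lo <- search_bounds[1]
  hi <- search_bounds[2]
  if (!(lo < hi)) stop("'search_bounds' must be an increasing pair")
  vv <- prod(img$spacing)

  seg_at <- function(T) connected_threshold(img, seed_voxel, T, connectivity)
  s_lo <- seg_at(lo)
  if (s_lo$volume < V_true)
    stop(sprintf(paste0("lower bound fails: segmented volume at T = %g is ",
                        "%.1f mm^3 < V_true = %.1f mm^3"),
                 lo, s_lo$volume, V_true))
  seg_hi_vol <- tryCatch(seg_at(hi)$volume, error = function(e) 0)
  if (seg_hi_vol > V_true)
    stop(sprintf(paste0("upper bound fails: segmented volume at T = %g is ",
                        "%.1f mm^3 > V_true = %.1f mm^3"),
                 hi, seg_hi_vol, V_true))

  best <- s_lo
  best_err <- abs(s_lo$volume - V_true)
  width0 <- hi - lo
  while (best_err >= vv / 2 && (hi - lo) >= 1e-6 * width0) {
    mid <- (lo + hi) / 2
    s <- tryCatch(seg_at(mid), error = function(e) NULL)
    v <- if (is.null(s)) 0 else s$volume
    err <- abs(v - V_true)
    if (!is.null(s) &&
        (err < best_err || (err == best_err && mid < best$threshold_T))) {
      best <- s
      best_err <- err
    }
    if (v >= V_true) lo <- mid else hi <- mid
  }
  ## snap to the plateau's canonical (smallest) threshold: the smallest
  ## image value >= T gives the identical voxel set
  cand <- img$values[img$values >= best$threshold_T]
  if (length(cand)) {
    T_snap <- min(cand)
    if (T_snap != best$threshold_T) best <- seg_at(T_snap)
  }
  best
}

#' Intensity-weighted centre of mass of a region
#'
#' @param img an \code{\link{image_volume}}.
#' @param voi logical array congruent with \code{img} (a \code{voi_mask}).
#' @return integer length-3: the intensity-weighted mean voxel position
#'   over the region, rounded to the nearest voxel index (1-based).
#' @export
center_of_mass <- function(img, voi) {
  stopifnot(inherits(img, "image_volume"),
            identical(dim(voi), dim(img$values)))
  w <- img$values[voi]
  if (length(w) == 0L || sum(w) <= 0)
    stop("region is empty or has non-positive total intensity")
  idx <- arrayInd(which(voi), dim(img$values))
  as.integer(round(colSums(idx * w) / sum(w)))
}

#' Spherical volume of interest
#'
#' Mask of voxels whose centres lie within \code{diameter/2} of a
#' physical point.  An empty mask (e.g. centre outside the grid) is
#' allowed and reported via a message.
#'
#' @param center physical point in mm, length 3.
#' @param diameter VOI diameter in mm (> 0).
#' @param img an \code{\link{image_volume}} supplying grid and spacing.
#' @return logical array of class \code{voi_mask} with the image spacing
#'   attached.
#' @export
spherical_voi <- function(center, diameter, img) {
  stopifnot(inherits(img, "image_volume"))
  if (!is.finite(diameter) || diameter <= 0) stop("'diameter' must be > 0")
  d <- dim(img$values)
  r <- diameter / 2
  dx2 <- (axis_coords(img, 1) - center[1])^2
  dy2 <- (axis_coords(img, 2) - center[2])^2
  dz2 <- (axis_coords(img, 3) - center[3])^2
  mask <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r^2
  if (!any(mask))
    message("spherical_voi: empty mask (VOI does not cover any voxel centre)")
  structure(mask, spacing = img$spacing, class = "voi_mask")
}

#' Volume of a voxel mask in mm^3
#' @param mask a \code{voi_mask} (logical array with a spacing attribute)
#' @return scalar mm^3
#' @export
mask_volume <- function(mask) sum(mask) * prod(attr(mask, "spacing"))
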