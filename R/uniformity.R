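#' Coefficient of variation within a volume of interest
#'
#' Sample standard deviation divided by mean of the voxel intensities
#' inside the VOI; scale-invariant, so insensitive to global calibration.
#'
#' @param img an \code{\link{image_volume}}.
#' @param voi logical array congruent with \code{img}.
#' @return the CV as a fraction.
#' @export
voi_cv <- function(img, voi) {
  stopifnot(inherits(img, "image_volume"),
            identical(dim(voi), dim(img$values)))
  v <- img$values[voi]
  if (!length(v)) stop("VOI is empty")
  m <- mean(v)
  if (m <= 0) stop("VOI mean must be > 0")
  stats::sd(v) / m
}

#' Kullback-Leibler divergence between two intensity samples
#'
#' Histograms both samples on shared equal-width bins spanning the union
#' of their ranges, regularizes every bin with a small epsilon before
#' normalization, and returns KL(P_a || P_b) in nats.
#'
#' @param sample_a,sample_b numeric vectors (non-empty).  By convention
#'   the first argument is the test distribution.
#' @param n_bins number of shared bins (default 64).
#' @param eps regularization added to every bin count.
#' @return KL divergence in nats (>= 0 up to the epsilon regularization).
#' @export
kl_divergence <- function(sample_a, sample_b, n_bins = 64L, eps = 1e-12) {
  if (!length(sample_a) || !length(sample_b)) stop("samples must be non-empty")
  rng <- range(c(sample_a, sample_b))
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  ha <- tabulate(.bincode(sample_a, breaks, include.lowest = TRUE), n_bins)
  hb <- tabulate(.bincode(sample_b, breaks, include.lowest = TRUE), n_bins)
  p <- (ha + eps) / sum(ha + eps)
  q <- (hb + eps) / sum(hb + eps)
  sum(p * log(p / q))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' The KS statistic D = sup |ECDF_a - ECDF_b| with the asymptotic
#' two-sample p-value (effective n = n_a n_b / (n_a + n_b)), as
#' appropriate for the voxel counts involved here (thousands).
#'
#' @param sample_a,sample_b numeric vectors (non-empty).
#' @return list with \code{D} and \code{p}.
#' @export
ks_two_sample <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) stop("samples must be non-empty")
  res <- suppressWarnings(
    stats::ks.test(sample_a, sample_b, exact = FALSE))
  list(D = unname(res$statistic), p = res$p.value)
}

#' Full uniformity comparison of two intensity regions
#'
#' Combines the per-region coefficient of variation with the
#' Kullback-Leibler divergence and Kolmogorov-Smirnov comparison of the
#' two voxel-intensity distributions, as used to compare the activity
#' distribution of printed versus fillable spheres within central VOIs
#' that exclude spill-in/spill-out.
#'
#' @param img_a,img_b \code{\link{image_volume}}s.
#' @param voi_a,voi_b logical arrays congruent with their images.
#' @param n_bins histogram bins for the KL divergence.
#' @return object of class \code{uniformity_report}: \code{cv_a},
#'   \code{cv_b}, \code{kl} (nats, KL(a || b)), \code{ks_D}, \code{ks_p},
#'   \code{n_voxels_a}, \code{n_voxels_b}.
#' @export
compare_uniformity <- function(img_a, voi_a, img_b, voi_b, n_bins = 64L) {
  a <- img_a$values[voi_a]
  b <- img_b$values[voi_b]
  ks <- ks_two_sample(a, b)
  structure(list(cv_a = voi_cv(img_a, voi_a), cv_b = voi_cv(img_b, voi_b),
                 kl = kl_divergence(a, b, n_bins = n_bins),
                 ks_D = ks$D, ks_p = ks$p,
                 n_voxels_a = length(a), n_voxels_b = length(b)),
            class = "uniformity_report")
}

#' @export
print.uniformity_report <- function(x, ...) {
  cat(sprintf("<uniformity_report> CV_a = %.2f%%, CV_b = %.2f%% (n = %d, %d)\n",
              100 * x$cv_a, 100 * x$cv_b, x$n_voxels_a, x$n_voxels_b))
  cat(sprintf("  KL(a||b) = %.4g nats, KS D = %.4g (p = %.3g)\n",
              x$kl, x$ks_D, x$ks_p))
  invisible(x)
}

#' Smooth a count field and compare its coefficient of variation
#'
#' Applies the reconstruction-like Gaussian filter to a (typically 2D
#' autoradiography) field and reports the CV over the whole field before
#' and after smoothing.
#'
#' @param field an \code{\link{image_volume}} (2D fields have a singleton
#'   third axis).
#' @param fwhm Gaussian FWHM in physical mm (default 5, the
#'   reconstruction filter).
#' @return list with \code{cv_raw}, \code{cv_smoothed} and
#'   \code{smoothed} (the filtered \code{image_volume}).
#' @export
smooth_and_cv <- function(field, fwhm = 5) {
  stopifnot(inherits(field, "image_volume"))
  all_voi <- array(TRUE, dim = dim(field$values))
  sm <- apply_psf(field, psf_spec(fwhm), pad_value = mean(field$values))
  list(cv_raw = voi_cv(field, all_voi),
       cv_smoothed = voi_cv(sm, all_voi),
       smoothed = sm)
}
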