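#' Read an image volume from a NIfTI-1 file
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file.
#' @return an \code{\link{image_volume}} with spacing taken from the
#'   header \code{pixdim}.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  nii <- RNifti::readNifti(path)
  vals <- as.array(nii)
  if (length(dim(vals)) == 2L) dim(vals) <- c(dim(vals), 1L)
  if (length(dim(vals)) != 3L)
    stop("only 2D/3D NIfTI volumes are supported")
  sp <- RNifti::pixdim(nii)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("NIfTI header has non-positive voxel spacing")
  image_volume(vals, spacing = sp)
}

#' Write an image volume to a NIfTI-1 file
#'
#' The voxel spacing is stored in the header \code{pixdim}; a write/read
#' round trip preserves the voxel values bit-exactly and the spacing to
#' float precision.
#'
#' @param img an \code{\link{image_volume}}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return invisibly, \code{path}.
#' @export
write_volume <- function(img, path) {
  stopifnot(inherits(img, "image_volume"))
  nii <- RNifti::asNifti(img$values)
  RNifti::pixdim(nii) <- img$spacing
  RNifti::writeNifti(nii, path, datatype = "double")
  invisible(path)
}

#' Write a 2D field as a plain-text matrix
#'
#' Tab-separated values, one row per first-axis index; intended for
#' autoradiography-like fields.
#'
#' @param img an \code{\link{image_volume}} with singleton third axis.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_field_txt <- function(img, path) {
  stopifnot(inherits(img, "image_volume"), dim(img$values)[3] == 1L)
  utils::write.table(img$values[, , 1], path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an experiment configuration to a YAML file
#'
#' @param config an \code{\link{experiment_config}}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read an experiment configuration from a YAML file
#'
#' Unknown keys are an error, so that typos in hand-edited configuration
#' files do not silently fall back to defaults.
#'
#' @param path path to a YAML file whose keys are arguments of
#'   \code{\link{experiment_config}}.
#' @return an \code{experiment_config}.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(bad, collapse = ", ")))
  do.call(experiment_config, vals)
}
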