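#' Voxel volumes and label volumes
#'
#' A `voxel_volume` is a 3D numeric array with a physical voxel spacing in mm;
#' a `label_volume` is the integer counterpart holding class ids on the same
#' grid (0 = background, 1 = humerus, 2 = scapula). Both are thin S3 wrappers
#' around base arrays so that all numeric code can treat them as arrays.
#'
#' @param data 3D numeric (or integer) array.
#' @param spacing Numeric length-3, voxel size in mm along each axis.
#' @return An object of class `voxel_volume` or `label_volume` (also `array`).
#' @examples
#' v <- voxel_volume(array(0, c(16, 16, 16)), spacing = c(1, 1, 1))
#' dim(v)
#' @export
voxel_volume <- function(data, spacing = c(1, 1, 1)) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive finite values (mm/voxel)")
  }
  structure(data, spacing = spacing, class = c("voxel_volume", "array"))
}

#' @rdname voxel_volume
#' @export
label_volume <- function(data, spacing = c(1, 1, 1)) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (any(data != round(data), na.rm = TRUE)) stop("label data must be integer-valued")
  v <- voxel_volume(data, spacing)
  class(v) <- c("label_volume", class(v))
  v
}

#' @rdname voxel_volume
#' @param x Object to query.
#' @export
voxel_spacing <- function(x) {
  sp <- attr(x, "spacing")
  if (is.null(sp)) c(1, 1, 1) else sp
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing %s mm\n",
              class(x)[1L], d[1L], d[2L], d[3L],
              paste(signif(voxel_spacing(x), 4), collapse = " x ")))
  invisible(x)
}

#' Read and write volumes as NIfTI
#'
#' Volumes round-trip through `.nii`/`.nii.gz` with the voxel spacing stored in
#' the header `pixdim`. Label volumes are written as-is (integer codes).
#'
#' @param x A `voxel_volume` or `label_volume`.
#' @param path File path ending in `.nii` or `.nii.gz`.
#' @return `write_volume` returns `path` invisibly; the readers return the
#'   reconstructed volume object.
#' @export
write_volume <- function(x, path) {
  img <- RNifti::asNifti(unclass(as.array(x)), pixdim = voxel_spacing(x))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  voxel_volume(array(as.numeric(img), dim = dim(img)[1:3]), spacing = sp)
}

#' @rdname write_volume
#' @export
read_label_volume <- function(path) {
  v <- read_volume(path)
  label_volume(array(as.integer(round(v)), dim = dim(v)), spacing = voxel_spacing(v))
}
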