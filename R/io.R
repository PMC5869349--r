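# NIfTI I/O. The grid model is deliberately reduced to spacing + origin:
# the analysis workflow registers everything to one axis-aligned grid before
# comparison, so oblique/rotated affines are rejected rather than silently
# reinterpreted.

xform_to_grid <- function(img, path) {
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(rot^2))
  if (any(spacing <= 0) || any(!is.finite(spacing)))
    stop("non-positive or invalid voxel spacing in NIfTI header: ", path)
  off <- rot - diag(spacing)
  if (max(abs(off)) > 1e-4 * max(spacing))
    stop("oblique or rotated NIfTI affine in ", path,
         "; only axis-aligned grids are supported (resample upstream)")
  list(spacing = spacing, origin = aff[1:3, 4])
}

read_volume <- function(path, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.numeric(img), dim = d[1:3])
    grid <- xform_to_grid(img, path)
    return(list(data = img2, grid = grid))
  }
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), "D: ", path)
  grid <- xform_to_grid(img, path)
  list(data = array(as.numeric(img), dim = d), grid = grid)
}

#' Read a binary mask from a NIfTI file
#'
#' Non-zero voxels become TRUE. Spacing and origin are taken from the file's
#' qform/sform; oblique or rotated affines are rejected with an error.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path, "mask")
  binary_mask(v$data != 0, v$grid$spacing, v$grid$origin)
}

#' Read a scalar image from a NIfTI file
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [scalar_image()].
#' @export
read_image <- function(path) {
  v <- read_volume(path, "image")
  scalar_image(v$data, v$grid$spacing, v$grid$origin)
}

write_volume <- function(data, spacing, origin, path, datatype) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a binary mask to a NIfTI file
#'
#' Voxel values are 0/1 (uint8); header spacing and origin reproduce the
#' mask's grid exactly, so `read_mask(write_mask(m, p))` is an identity.
#'
#' @param mask A [binary_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot_mask(mask)
  write_volume(array(as.integer(mask$data), dim = dim(mask$data)),
               mask$spacing, mask$origin, path, "uint8")
}

#' Write a scalar image to a NIfTI file
#' @param image A [scalar_image()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_image <- function(image, path) {
  if (!inherits(image, "scalar_image")) stop("image must be a scalar_image")
  write_volume(image$data, image$spacing, image$origin, path, "double")
}
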