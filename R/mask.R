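#' Construct a 3D binary mask on a regular voxel grid
#'
#' A `binary_mask` couples a 3D logical lattice (axes ordered x, y, z) with
#' the physical voxel spacing in millimetres and the world position of the
#' centre of voxel (1,1,1). All volume-of-interest (VOI) objects in the
#' package -- truth volumes, reader segmentations, margin expansions -- are
#' `binary_mask` objects. World coordinates follow the voxel-centre
#' convention: `world_mm = origin + (index - 1) * spacing`.
#'
#' @param data Logical (or coercible 0/non-zero numeric) 3D array.
#' @param spacing Numeric length-3, mm per voxel along x, y, z; all > 0.
#' @param origin Numeric length-3, mm world coordinates of the first voxel
#'   centre. Defaults to `c(0, 0, 0)`.
#' @return An object of class `binary_mask`.
#' @examples
#' m <- binary_mask(array(TRUE, c(10, 10, 10)), spacing = c(1, 1, 1))
#' mask_volume_ml(m)  # 1 mL
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("mask data must be a 3D array, got ", length(dim(data)), " dims")
  if (!is.logical(data)) {
    storage <- array(data != 0, dim = dim(data))
    data <- storage
  }
  if (anyNA(data)) stop("mask data contains NA")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "binary_mask")
}

#' Construct a 3D scalar image (SUV-like intensities)
#'
#' Same grid model as [binary_mask()] but with finite float voxel values,
#' e.g. a PET uptake image feeding the gradient segmenter.
#'
#' @param data Numeric 3D array of finite values.
#' @param spacing,origin As in [binary_mask()].
#' @return An object of class `scalar_image`.
#' @export
scalar_image <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("image data must be a 3D array")
  data <- array(as.numeric(data), dim = dim(data))
  if (any(!is.finite(data))) stop("image data must be finite")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "scalar_image")
}

is_binary_mask <- function(x) inherits(x, "binary_mask")

stopifnot_mask <- function(x, arg = deparse(substitute(x))) {
  if (!is_binary_mask(x)) stop(arg, " must be a binary_mask")
  invisible(x)
}

#' Test whether two grids are compatible
#'
#' Two masks/images are compatible iff they share lattice shape, spacing and
#' origin. All binary operations require compatibility; no silent resampling
#' is ever performed (use [resample_nearest()] for deliberate regridding).
#'
#' @param a,b `binary_mask` or `scalar_image` objects.
#' @param tol Tolerance (mm) on spacing/origin agreement.
#' @return Logical scalar.
#' @export
compatible_grids <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

check_compatible <- function(a, b) {
  if (!compatible_grids(a, b))
    stop("masks are on different grids (shape/spacing/origin); ",
         "resample explicitly before comparing")
  invisible(TRUE)
}

#' Number of true voxels in a mask
#' @param mask A `binary_mask`.
#' @return Integer count.
#' @export
mask_count <- function(mask) {
  stopifnot_mask(mask)
  sum(mask$data)
}

#' Mask volume in millilitres
#'
#' Volume is the count of true voxels times the voxel volume, converted at
#' 1000 mm^3/mL: the tumor volume is the sum of voxels encompassed by the
#' drawn VOI.
#'
#' @param mask A `binary_mask`.
#' @return Volume in mL (0 for an empty mask).
#' @export
mask_volume_ml <- function(mask) {
  stopifnot_mask(mask)
  sum(mask$data) * prod(mask$spacing) / 1000
}

#' Voxelwise union of segmentations
#'
#' Spatially combines segmentations of one tumor into their union (the
#' "combined" segmentation, conventionally seg4 when fed seg1--seg3).
#'
#' @param masks Non-empty list of pairwise compatible `binary_mask` objects.
#' @return A `binary_mask`, the voxelwise OR.
#' @export
union_masks <- function(masks) {
  if (!is.list(masks) || length(masks) == 0L)
    stop("union_masks needs a non-empty list of masks")
  out <- masks[[1L]]
  stopifnot_mask(out)
  acc <- out$data
  for (m in masks[-1L]) {
    stopifnot_mask(m)
    check_compatible(out, m)
    acc <- acc | m$data
  }
  binary_mask(acc, out$spacing, out$origin)
}

#' Nearest-neighbour resampling onto a target grid
#'
#' Explicit regridding utility for masks defined on different grids: each
#' target voxel centre is mapped to the nearest source voxel (in world mm);
#' target voxels falling outside the source lattice become FALSE.
#'
#' @param mask Source `binary_mask`.
#' @param shape Integer length-3 target lattice shape.
#' @param spacing,origin Target grid geometry (mm).
#' @return A `binary_mask` on the target grid.
#' @export
resample_nearest <- function(mask, shape, spacing, origin = c(0, 0, 0)) {
  stopifnot_mask(mask)
  shape <- as.integer(shape)
  idx <- lapply(1:3, function(ax) {
    world <- origin[ax] + (seq_len(shape[ax]) - 1) * spacing[ax]
    round((world - mask$origin[ax]) / mask$spacing[ax]) + 1
  })
  src <- mask$data
  dims <- dim(src)
  ok <- lapply(1:3, function(ax) idx[[ax]] >= 1 & idx[[ax]] <= dims[ax])
  cl <- lapply(1:3, function(ax) pmin(pmax(idx[[ax]], 1L), dims[ax]))
  out <- src[cl[[1]], cl[[2]], cl[[3]], drop = FALSE]
  out[!ok[[1]], , ] <- FALSE
  out[, !ok[[2]], ] <- FALSE
  out[, , !ok[[3]]] <- FALSE
  binary_mask(out, spacing, origin)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, spacing (%s) mm, %d true, %.3f mL\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              sum(x$data), mask_volume_ml(x)))
  invisible(x)
}

#' @export
print.scalar_image <- function(x, ...) {
  cat(sprintf("<scalar_image> %s voxels, spacing (%s) mm, range [%.3g, %.3g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Bundle a truth mask with candidate segmentations
#'
#' @param case_id Character identifier.
#' @param truth Non-empty `binary_mask` reference volume.
#' @param candidates Named list of `binary_mask` candidates (e.g. seg1..seg3),
#'   each compatible with `truth`. Empty candidates are allowed (a reader may
#'   miss the lesion); downstream analysis records them as excluded.
#' @return A `segmentation_case` object.
#' @export
segmentation_case <- function(case_id, truth, candidates) {
  stopifnot_mask(truth)
  if (sum(truth$data) == 0L) stop("truth mask is empty")
  if (!is.list(candidates) || is.null(names(candidates)) ||
      any(names(candidates) == ""))
    stop("candidates must be a named list of binary_mask")
  for (m in candidates) {
    stopifnot_mask(m)
    check_compatible(truth, m)
  }
  structure(list(case_id = as.character(case_id), truth = truth,
                 candidates = candidates),
            class = "segmentation_case")
}
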