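# Overlap and surface-distance coefficients between a candidate VOI and the
# reference (truth) VOI, on a shared voxel grid. Dice and Jaccard are
# computed on voxel counts; HD and MDA on centre-to-centre distances between
# surface voxels (6-connectivity surface), via the exact distance transform.

check_nonempty <- function(mask, arg) {
  if (sum(mask$data) == 0L) stop(arg, " mask is empty")
  invisible(TRUE)
}

#' Dice overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`: 0 for disjoint volumes, 1 for perfect
#' overlap.
#'
#' @param a,b Compatible [binary_mask()] objects; at least one non-empty.
#' @return Numeric in \[0, 1\].
#' @export
dice <- function(a, b) {
  stopifnot_mask(a); stopifnot_mask(b)
  check_compatible(a, b)
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0L) stop("Dice undefined: both masks empty")
  2 * sum(a$data & b$data) / (na + nb)
}

#' Jaccard overlap coefficient
#'
#' `|A intersect B| / |A union B|`. Related to Dice by `J = D / (2 - D)`.
#'
#' @inheritParams dice
#' @return Numeric in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  stopifnot_mask(a); stopifnot_mask(b)
  check_compatible(a, b)
  u <- sum(a$data | b$data)
  if (u == 0L) stop("Jaccard undefined: both masks empty")
  sum(a$data & b$data) / u
}

#' Surface voxels of a mask
#'
#' TRUE voxels with at least one FALSE face-neighbour (6-connectivity);
#' voxels on the lattice boundary count as surface.
#'
#' @param mask Non-empty [binary_mask()].
#' @return A [binary_mask()] marking the surface voxels.
#' @export
surface_voxels <- function(mask) {
  stopifnot_mask(mask)
  check_nonempty(mask, "input")
  m <- mask$data
  dm <- dim(m)
  # interior voxels whose 6 face-neighbours are all TRUE
  interior <- array(FALSE, dm)
  if (all(dm >= 3)) {
    cx <- 2:(dm[1] - 1); cy <- 2:(dm[2] - 1); cz <- 2:(dm[3] - 1)
    interior[cx, cy, cz] <-
      m[cx, cy, cz] &
      m[cx - 1, cy, cz] & m[cx + 1, cy, cz] &
      m[cx, cy - 1, cz] & m[cx, cy + 1, cz] &
      m[cx, cy, cz - 1] & m[cx, cy, cz + 1]
  }
  binary_mask(m & !interior, mask$spacing, mask$origin)
}

#' Directed surface-to-surface distances
#'
#' For every surface voxel of `a`, the Euclidean distance (mm) to the
#' nearest surface voxel of `b`, measured between voxel centres with
#' spacing-aware geometry.
#'
#' @param a,b Compatible non-empty [binary_mask()] objects.
#' @return Numeric vector, one distance per surface voxel of `a`.
#' @export
directed_surface_distances <- function(a, b) {
  stopifnot_mask(a); stopifnot_mask(b)
  check_compatible(a, b)
  check_nonempty(a, "first"); check_nonempty(b, "second")
  sa <- surface_voxels(a)
  dt_b <- distance_transform(surface_voxels(b))
  dt_b[sa$data]
}

#' Hausdorff distance (mm)
#'
#' Symmetric worst-case surface distance: the maximum over all surface
#' points of either mask of the distance to the closest point on the other
#' surface. 0 mm reflects the ideal outcome. The full maximum is reported
#' (no percentile variant).
#'
#' @inheritParams directed_surface_distances
#' @return Non-negative distance in mm.
#' @export
hausdorff_mm <- function(a, b) {
  max(max(directed_surface_distances(a, b)),
      max(directed_surface_distances(b, a)))
}

#' Mean distance to agreement (mm)
#'
#' Mean closest-point surface distance, symmetrised by pooling the directed
#' distance sets of both masks so every surface point contributes equally.
#'
#' @inheritParams directed_surface_distances
#' @return Non-negative distance in mm; always `<= hausdorff_mm(a, b)`.
#' @export
mda_mm <- function(a, b) {
  mean(c(directed_surface_distances(a, b),
         directed_surface_distances(b, a)))
}

#' Missed (underestimated) tumor volume
#'
#' The part of the reference tumor volume not included in the candidate
#' segmentation: volume of `truth AND NOT candidate`, absolute (mL) and as a
#' percentage of the truth volume.
#'
#' @param truth Non-empty reference [binary_mask()].
#' @param candidate Compatible candidate [binary_mask()].
#' @return Named list with `ml` and `percent`.
#' @export
missed_volume <- function(truth, candidate) {
  stopifnot_mask(truth); stopifnot_mask(candidate)
  check_compatible(truth, candidate)
  check_nonempty(truth, "truth")
  voxvol <- prod(truth$spacing) / 1000
  n_truth <- sum(truth$data)
  n_missed <- sum(truth$data & !candidate$data)
  list(ml = n_missed * voxvol, percent = 100 * n_missed / n_truth)
}

#' Full similarity report for one (truth, candidate) pair
#'
#' Computes all four similarity coefficients (Dice, Jaccard, Hausdorff
#' distance, mean distance to agreement), both volumes, and the missed
#' volume in one pass.
#'
#' @param truth,candidate Compatible non-empty [binary_mask()] objects.
#' @return A `similarity_report`: named list with fields `dice`, `jaccard`,
#'   `hd_mm`, `mda_mm`, `truth_volume_ml`, `candidate_volume_ml`,
#'   `missed_volume_ml`, `missed_percent`.
#' @export
similarity_report <- function(truth, candidate) {
  miss <- missed_volume(truth, candidate)
  check_nonempty(candidate, "candidate")
  structure(list(
    dice = dice(truth, candidate),
    jaccard = jaccard(truth, candidate),
    hd_mm = hausdorff_mm(truth, candidate),
    mda_mm = mda_mm(truth, candidate),
    truth_volume_ml = mask_volume_ml(truth),
    candidate_volume_ml = mask_volume_ml(candidate),
    missed_volume_ml = miss$ml,
    missed_percent = miss$percent
  ), class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<similarity_report>\n",
    "  Dice %.3f  Jaccard %.3f  HD %.2f mm  MDA %.2f mm\n",
    "  truth %.3f mL, candidate %.3f mL, missed %.3f mL (%.1f%%)\n"),
    x$dice, x$jaccard, x$hd_mm, x$mda_mm,
    x$truth_volume_ml, x$candidate_volume_ml,
    x$missed_volume_ml, x$missed_percent))
  invisible(x)
}
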