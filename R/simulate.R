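# Synthetic cohort generator. Emulates the statistical structure of the
# prostate focal-therapy segmentation problem: small irregular ground-truth
# tumors (median ~1.37 mL, range ~0.15-6.3 mL), reader segmentations that
# cover only a minority of the truth volume (~20% coverage, i.e. ~80%
# underestimation) with spatial decentring, and PET-like images blurred with
# a ~4.1 mm FWHM point-spread function. Reader error is decomposed into
# shrinkage + decentring + boundary noise, mirroring the two mechanisms that
# drive large required safety margins: volume underestimation and lack of
# centring of the segmentation within the true lesion.

#' Configuration for a synthetic segmentation cohort
#'
#' Defaults encode the study conditions the generator emulates: lognormal
#' tumor volumes with median 1.37 mL truncated to 0.15--6.31 mL, two readers
#' covering ~21% and ~20% of the truth with 3 mm decentring, and PET with
#' 4.1 mm FWHM resolution.
#'
#' @param n_cases Number of cases (>= 1).
#' @param grid_shape Integer length-3 lattice shape (default 64^3).
#' @param spacing_mm Voxel spacing (mm), default 1 mm isotropic (the common
#'   analysis grid).
#' @param volume_median_ml,volume_sdlog Lognormal tumor-volume law
#'   (median 1.37 mL; sdlog 0.9 spans the observed 0.15--6.3 mL range at
#'   roughly +/- 2 SD).
#' @param volume_range_ml Truncation bounds (mL); draws outside are redrawn.
#' @param irregularity Amplitude of the band-limited radial perturbation of
#'   the base ellipsoid (0 = smooth ellipsoid; default 0.25).
#' @param reader_coverage Named fractions of the truth volume each simulated
#'   reader covers (defaults seg1 = 0.21, seg2 = 0.20).
#' @param coverage_tol Calibration tolerance on achieved coverage.
#' @param reader_offset_sd_mm Total SD of each reader's decentring (mm).
#' @param reader_offset_shared_frac Fraction of the decentring variance
#'   shared between the readers of one case (default 0.7): readers looking
#'   at the same images mis-centre toward the same conspicuous subregion,
#'   with individual variation on top. The marginal decentring SD of each
#'   reader stays `reader_offset_sd_mm`.
#' @param boundary_noise_mm SD of the smooth boundary perturbation (mm).
#' @param pet_background_suv,pet_tumor_suv Piecewise-constant activity
#'   levels (4:1 tumor:background by default).
#' @param pet_fwhm_mm PET point-spread FWHM (mm), default 4.1.
#' @param pet_noise_sd_fraction Gaussian noise SD as a fraction of the tumor
#'   activity.
#' @param seed Integer master seed; the whole cohort is reproducible from
#'   it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_cases = 9,
                          grid_shape = c(64, 64, 64),
                          spacing_mm = c(1, 1, 1),
                          volume_median_ml = 1.37,
                          volume_sdlog = 0.9,
                          volume_range_ml = c(0.15, 6.31),
                          irregularity = 0.25,
                          reader_coverage = c(seg1 = 0.21, seg2 = 0.20),
                          coverage_tol = 0.03,
                          reader_offset_sd_mm = 3,
                          reader_offset_shared_frac = 0.7,
                          boundary_noise_mm = 0.75,
                          pet_background_suv = 2,
                          pet_tumor_suv = 8,
                          pet_fwhm_mm = 4.1,
                          pet_noise_sd_fraction = 0.05,
                          seed = 1) {
  stopifnot(n_cases >= 1,
            all(reader_coverage > 0), all(reader_coverage <= 1),
            reader_offset_sd_mm >= 0,
            reader_offset_shared_frac >= 0, reader_offset_shared_frac <= 1,
            boundary_noise_mm >= 0,
            pet_background_suv > 0, pet_tumor_suv > 0,
            pet_fwhm_mm >= 0, pet_noise_sd_fraction >= 0,
            irregularity >= 0)
  structure(as.list(environment()), class = "cohort_config")
}

# band-limited random radial modulation on the sphere: a mixture of
# low-order polynomials in (dir . u_j) for a few random axes u_j, i.e.
# spherical harmonics up to degree 3. Returns a function of an n x 3 matrix
# of unit directions.
random_radial_field <- function(n_axes = 8) {
  u <- matrix(rnorm(n_axes * 3), n_axes, 3)
  u <- u / sqrt(rowSums(u^2))
  a <- rnorm(n_axes)
  b <- rnorm(n_axes)
  function(dirs) {
    ct <- dirs %*% t(u)                       # n x n_axes cosines
    f <- (ct^2 - 1 / 3) %*% a + (ct^3 - 0.6 * ct) %*% b
    as.numeric(f) / sqrt(n_axes)
  }
}

#' Simulate an irregular ground-truth tumor mask
#'
#' Star-convex blob: a base ellipsoid (random mild axis anisotropy) whose
#' radius is modulated by band-limited random spherical perturbations of
#' amplitude `irregularity`, rescaled by bisection so the voxel-count volume
#' matches the drawn target volume within 2%.
#'
#' @param config A [cohort_config()].
#' @param target_volume_ml Optional fixed target volume (mL); by default
#'   drawn from the configured lognormal law. Uses the current RNG state.
#' @return A [binary_mask()] with attribute `target_volume_ml`.
#' @export
simulate_truth <- function(config, target_volume_ml = NULL) {
  shape <- as.integer(config$grid_shape)
  sp <- config$spacing_mm
  if (is.null(target_volume_ml)) {
    repeat {
      target_volume_ml <- rlnorm(1, meanlog = log(config$volume_median_ml),
                                 sdlog = config$volume_sdlog)
      if (target_volume_ml >= config$volume_range_ml[1] &&
          target_volume_ml <= config$volume_range_ml[2]) break
    }
  }
  r0 <- (3 * target_volume_ml * 1000 / (4 * pi))^(1 / 3)  # mm
  half_mm <- (shape - 1) * sp / 2
  if (r0 * (1 + config$irregularity) * 1.3 > min(half_mm))
    stop("target volume too large for the configured grid")
  centre <- config$spacing_mm * (shape - 1) / 2 + runif(3, -2, 2)
  ax <- exp(rnorm(3, 0, 0.15))
  ax <- ax / prod(ax)^(1 / 3)                 # volume-preserving anisotropy
  f <- random_radial_field()

  ax_coord <- lapply(1:3, function(i) (seq_len(shape[i]) - 1) * sp[i])
  wr <- ceiling(r0 * (1 + config$irregularity) * 1.4 / min(sp)) + 2
  win <- lapply(1:3, function(i) {
    ci <- round(centre[i] / sp[i]) + 1
    max(1, ci - wr):min(shape[i], ci + wr)
  })
  g <- as.matrix(expand.grid(win[[1]], win[[2]], win[[3]]))
  pts <- cbind(ax_coord[[1]][g[, 1]], ax_coord[[2]][g[, 2]],
               ax_coord[[3]][g[, 3]])
  rel <- sweep(pts, 2, centre, "-")
  rho <- sqrt(rowSums(rel^2))
  pos <- rho > 1e-9
  dirs <- rel[pos, , drop = FALSE] / rho[pos]
  mod <- pmax(1 + config$irregularity * f(dirs), 0.3)
  # direction-dependent ellipsoid radius: ||diag(1/ax) d|| = 1/r_ell(d)
  r_ell <- 1 / sqrt(rowSums(sweep(dirs, 2, ax, "/")^2))
  rad <- numeric(length(rho))
  rad[pos] <- r0 * r_ell * mod
  rad[!pos] <- r0

  voxvol <- prod(sp) / 1000
  target_n <- target_volume_ml / voxvol
  lo <- 0.5; hi <- 2.0
  best <- NULL; best_err <- Inf
  for (it in 1:40) {
    s <- (lo + hi) / 2
    inside <- rho <= s * rad
    n <- sum(inside)
    err <- abs(n - target_n) / target_n
    if (err < best_err) { best <- inside; best_err <- err }
    if (err < 0.005) break
    if (n < target_n) lo <- s else hi <- s
  }
  out <- array(FALSE, shape)
  out[g[best, , drop = FALSE]] <- TRUE
  m <- binary_mask(out, sp, c(0, 0, 0))
  attr(m, "target_volume_ml") <- target_volume_ml
  m
}

# trilinear sampling of a plain 3D array defined on a unit-index grid in mm
sample_field <- function(field, spacing, pts_mm) {
  img <- scalar_image(field, spacing, c(0, 0, 0))
  interp_trilinear(img, pts_mm)$values
}

#' Simulate a reader-like under-segmentation of a truth mask
#'
#' The truth is shrunk about a random interior anchor, randomly translated
#' (Gaussian decentring), and its boundary perturbed with a smooth noise
#' field; the shrink factor is calibrated by bisection so the achieved
#' coverage `|seg and truth| / |truth|` is within `tol` of
#' `coverage_target`. Uses the current RNG state.
#'
#' @param truth Non-empty [binary_mask()].
#' @param coverage_target Fraction of the truth volume to cover, in (0, 1].
#' @param offset_sd_mm SD of the random translation (mm).
#' @param boundary_noise_mm SD of the smooth boundary perturbation (mm).
#' @param tol Coverage calibration tolerance (relaxed to 0.1, with a flag,
#'   for tiny truths under 30 voxels).
#' @param offset_mm Optional explicit decentring vector (mm); when given it
#'   replaces the random draw, letting a cohort generator impose a shared
#'   mis-centring component across readers of one case.
#' @return A non-empty [binary_mask()] with attribute `achieved_coverage`
#'   (and `coverage_relaxed = TRUE` when the tolerance had to be relaxed).
#' @export
simulate_reader <- function(truth, coverage_target, offset_sd_mm = 3,
                            boundary_noise_mm = 0.75, tol = 0.03,
                            offset_mm = NULL) {
  stopifnot_mask(truth)
  check_nonempty(truth, "truth")
  if (coverage_target <= 0 || coverage_target > 1)
    stop("coverage_target must be in (0, 1]")
  sp <- truth$spacing
  dm <- dim(truth$data)
  tiny <- sum(truth$data) < 30
  if (tiny) tol <- max(tol, 0.1)

  d_out <- sqrt(cpp_edt_sq(as.logical(truth$data), dm, sp))
  d_in <- sqrt(cpp_edt_sq(!as.logical(truth$data), dm, sp))
  sdf <- array(d_out - d_in, dm)

  # anchor at the lesion core (deepest interior point): readers segment the
  # same conspicuous part of the lesion, which is what sustains non-trivial
  # inter-reader overlap despite heavy under-segmentation
  anchor_idx <- arrayInd(which.max(d_in), dm)
  anchor <- (as.numeric(anchor_idx) - 1) * sp
  offset <- if (is.null(offset_mm)) rnorm(3, 0, offset_sd_mm)
            else as.numeric(offset_mm)

  # evaluation window: truth bounding box padded for offset + noise
  idx <- which(truth$data, arr.ind = TRUE)
  pad <- ceiling((abs(offset) + 3 * boundary_noise_mm + 2) / sp)
  win <- lapply(1:3, function(ax)
    max(1, min(idx[, ax]) - pad[ax]):min(dm[ax], max(idx[, ax]) + pad[ax]))
  g <- as.matrix(expand.grid(win[[1]], win[[2]], win[[3]]))
  pts <- sweep(g - 1, 2, sp, "*")

  noise <- 0
  if (boundary_noise_mm > 0) {
    wdim <- vapply(win, length, integer(1))
    raw <- array(rnorm(prod(wdim)), wdim)
    sm <- gaussian_smooth(raw, 3, sp)
    noise <- as.numeric(sm) / sd(sm) * boundary_noise_mm
  }

  n_truth <- sum(truth$data)
  truth_lin <- (g[, 3] - 1) * dm[1] * dm[2] + (g[, 2] - 1) * dm[1] + g[, 1]
  in_truth <- truth$data[truth_lin]
  coverage_of <- function(s) {
    src <- sweep(sweep(pts, 2, anchor + offset, "-") / s, 2, anchor, "+")
    val <- sample_field(sdf, sp, src) + noise
    inside <- val <= 0
    list(inside = inside, coverage = sum(inside & in_truth) / n_truth)
  }
  lo <- 0.05; hi <- 1.6
  best <- NULL; best_gap <- Inf
  for (it in 1:35) {
    s <- (lo + hi) / 2
    r <- coverage_of(s)
    gap <- abs(r$coverage - coverage_target)
    if (gap < best_gap) { best <- r; best_gap <- gap }
    if (gap <= tol / 2) break
    if (r$coverage < coverage_target) lo <- s else hi <- s
  }
  out <- array(FALSE, dm)
  out[g[best$inside, , drop = FALSE]] <- TRUE
  if (!any(out)) out[anchor_idx] <- TRUE
  m <- binary_mask(out, sp, truth$origin)
  attr(m, "achieved_coverage") <- best$coverage
  if (best_gap > tol) attr(m, "coverage_relaxed") <- TRUE
  m
}

#' Simulate a PET-like uptake image for a truth mask
#'
#' Piecewise-constant activity (tumor level inside the truth, background
#' outside) convolved with an isotropic Gaussian point-spread function and
#' degraded with independent Gaussian noise, clipped at zero. Uses the
#' current RNG state.
#'
#' @param truth Non-empty [binary_mask()].
#' @param background_suv,tumor_suv Positive activity levels.
#' @param fwhm_mm Point-spread FWHM (mm).
#' @param noise_sd_fraction Noise SD as a fraction of `tumor_suv`.
#' @return A [scalar_image()] on the truth grid.
#' @export
simulate_pet <- function(truth, background_suv = 2, tumor_suv = 8,
                         fwhm_mm = 4.1, noise_sd_fraction = 0.05) {
  stopifnot_mask(truth)
  if (background_suv <= 0 || tumor_suv <= 0)
    stop("activity levels must be positive")
  act <- array(background_suv, dim(truth$data))
  act[truth$data] <- tumor_suv
  if (fwhm_mm > 0)
    act <- gaussian_smooth(act, fwhm_to_sigma(fwhm_mm), truth$spacing)
  if (noise_sd_fraction > 0)
    act <- act + array(rnorm(length(act), 0,
                             noise_sd_fraction * tumor_suv), dim(act))
  act[act < 0] <- 0
  scalar_image(act, truth$spacing, truth$origin)
}

mask_centroid_mm <- function(mask) {
  idx <- which(mask$data, arr.ind = TRUE)
  colMeans(sweep(idx - 1, 2, mask$spacing, "*")) + mask$origin
}

#' Simulate a full synthetic cohort
#'
#' For each case: an irregular truth tumor, two simulated readers (seg1,
#' seg2) at the configured coverage targets, a PET-like image, and seg3 from
#' [petedge_segment()] seeded at the truth centroid. Each case draws from
#' its own RNG substream derived from the master seed, so the cohort is
#' bit-reproducible and early cases do not change when `n_cases` grows.
#'
#' @param config A [cohort_config()].
#' @return A `cohort` object: list with `cases` (list of
#'   [segmentation_case()]), `pet_images` (list of [scalar_image()]), and
#'   `manifest` (data frame of per-case draws: seeds, target and achieved
#'   volumes, achieved coverages).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop("config must be a cohort_config")
  set.seed(config$seed)
  case_seeds <- sample.int(.Machine$integer.max, config$n_cases)
  cases <- vector("list", config$n_cases)
  pets <- vector("list", config$n_cases)
  rows <- vector("list", config$n_cases)
  for (i in seq_len(config$n_cases)) {
    set.seed(case_seeds[i])
    truth <- simulate_truth(config)
    sd_shared <- config$reader_offset_sd_mm *
      sqrt(config$reader_offset_shared_frac)
    sd_indiv <- config$reader_offset_sd_mm *
      sqrt(1 - config$reader_offset_shared_frac)
    shared_offset <- rnorm(3, 0, sd_shared)
    readers <- lapply(config$reader_coverage, function(cov)
      simulate_reader(truth, cov,
                      offset_mm = shared_offset + rnorm(3, 0, sd_indiv),
                      boundary_noise_mm = config$boundary_noise_mm,
                      tol = config$coverage_tol))
    pet <- simulate_pet(truth,
                        background_suv = config$pet_background_suv,
                        tumor_suv = config$pet_tumor_suv,
                        fwhm_mm = config$pet_fwhm_mm,
                        noise_sd_fraction = config$pet_noise_sd_fraction)
    seg3 <- tryCatch(
      petedge_segment(pet, mask_centroid_mm(truth)),
      error = function(e) binary_mask(array(FALSE, dim(truth$data)),
                                      truth$spacing, truth$origin))
    candidates <- c(readers, list(seg3 = seg3))
    case_id <- sprintf("case%03d", i)
    cases[[i]] <- segmentation_case(case_id, truth, candidates)
    pets[[i]] <- pet
    rows[[i]] <- data.frame(
      case_id = case_id, seed = case_seeds[i],
      target_volume_ml = attr(truth, "target_volume_ml"),
      truth_volume_ml = mask_volume_ml(truth),
      coverage_seg1 = attr(readers[[1]], "achieved_coverage"),
      coverage_seg2 = attr(readers[[2]], "achieved_coverage"),
      seg3_volume_ml = mask_volume_ml(seg3))
  }
  structure(list(cases = cases, pet_images = pets,
                 manifest = do.call(rbind, rows), config = config),
            class = "cohort")
}

#' Write a simulated cohort to disk
#'
#' One directory per case holding NIfTI masks (`truth`, each candidate) and
#' the PET image, plus a top-level `manifest.json` recording all draws.
#'
#' @param cohort A `cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$cases)) {
    cs <- cohort$cases[[i]]
    cdir <- file.path(dir, cs$case_id)
    dir.create(cdir, showWarnings = FALSE)
    write_mask(cs$truth, file.path(cdir, "truth.nii.gz"))
    for (nm in names(cs$candidates))
      write_mask(cs$candidates[[nm]], file.path(cdir, paste0(nm, ".nii.gz")))
    write_image(cohort$pet_images[[i]], file.path(cdir, "pet.nii.gz"))
  }
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
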