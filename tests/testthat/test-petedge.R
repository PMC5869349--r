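test_that("ray sampling reproduces voxel values and flags outside samples", {
  img <- scalar_image(array(7, c(10, 10, 10)))
  r <- sample_ray(img, c(4, 4, 4), c(1, 0, 0), 1, 8)
  expect_true(all(r$values == 7))
  expect_true(any(r$outside))  # ray leaves the 9 mm lattice at radius > 5
  # axis-aligned ray hits exact voxel values at integer steps
  vals <- array(0, c(10, 4, 4))
  vals[, 2, 2] <- seq(10, 1, length.out = 10)
  img2 <- scalar_image(vals)
  r2 <- sample_ray(img2, c(0, 1, 1), c(1, 0, 0), 1, 9)
  expect_equal(r2$values, seq(10, 1, length.out = 10))
  expect_error(sample_ray(img, c(-5, 4, 4), c(1, 0, 0), 1, 5), "outside")
  expect_error(sample_ray(img, c(4, 4, 4), c(1, 0, 0), 0, 5), "step")
})

test_that("ray sampling matches the closed-form blurred-sphere profile", {
  # 1D evaluation of a Gaussian-blurred ball along a radius has the exact
  # form bg + (A-bg)*F(r); compare against trilinear samples on a fine grid
  R <- 8; sigma <- 4.1 / (2 * sqrt(2 * log(2)))
  ph <- sphere_phantom(R, contrast = 10, n = 48)
  f_true <- function(r) {
    r <- pmax(r, 1e-9)
    1 + 9 * (pnorm((R - r) / sigma) - pnorm((-R - r) / sigma) -
      sigma / (r * sqrt(2 * pi)) *
        (exp(-(r - R)^2 / (2 * sigma^2)) - exp(-(r + R)^2 / (2 * sigma^2))))
  }
  pr <- sample_ray(ph$image, ph$seed_mm, c(1, 0, 0), 0.5, 15)
  expect_equal(pr$values, f_true(pr$radii_mm), tolerance = 0.02)
})

test_that("edge placement finds the steepest falling gradient", {
  e <- edge_along_ray(c(10, 10, 10, 1, 1, 1), 1)
  expect_true(e$found)
  expect_equal(e$radius_mm, 2.5)
  expect_equal(e$sigma_mm, 0)  # sharp step: stencil width fully explains it
  expect_false(edge_along_ray(rep(4, 10), 1)$found)
  expect_false(edge_along_ray(1:10, 1)$found)  # monotone increasing
  # error-function edge at r0: inflection = true edge, sub-step accuracy
  r0 <- 5.3; sigma <- 1.5
  r <- seq(0, 12, by = 0.5)
  prof <- 1 + 9 * pnorm((r0 - r) / sigma)
  e2 <- edge_along_ray(prof, 0.5)
  expect_equal(e2$radius_mm, r0, tolerance = 0.1)
  expect_equal(e2$sigma_mm, sigma, tolerance = 0.25)
})

test_that("radius regularization imputes gaps and removes outliers", {
  ico <- icosphere_directions(2)
  n <- nrow(ico$vertices)
  uniform <- rep(8, n)
  expect_equal(regularize_radii(uniform, ico$adjacency), uniform)
  spiked <- uniform; spiked[40] <- 24
  expect_equal(regularize_radii(spiked, ico$adjacency), uniform)
  set.seed(8)
  holey <- uniform; holey[sample(n, round(0.05 * n))] <- NA
  expect_equal(regularize_radii(holey, ico$adjacency), uniform)
  expect_error(regularize_radii(rep(NA_real_, n), ico$adjacency), "no edge")
})

test_that("rasterization of a constant radius field gives a digitized ball", {
  ico <- icosphere_directions(2)
  R <- 6
  m <- radii_to_mask(c(12, 12, 12), ico$vertices, rep(R, nrow(ico$vertices)),
                     c(25, 25, 25))
  co <- (-12:12)
  enum <- sum(outer(outer(co^2, co^2, "+"), co^2, "+") <= R^2)
  expect_equal(mask_count(m), enum, tolerance = 0.05 * enum)
  expect_true(m$data[13, 13, 13])
  # tiny radius still contains the seed voxel
  tiny <- radii_to_mask(c(12, 12, 12), ico$vertices,
                        rep(0.2, nrow(ico$vertices)), c(25, 25, 25))
  expect_true(tiny$data[13, 13, 13])
  # ellipsoidal radius field reproduces the axis extents
  ax <- c(8, 6, 4)
  rad <- 1 / sqrt(rowSums(sweep(ico$vertices, 2, ax, "/")^2))
  ell <- radii_to_mask(c(12, 12, 12), ico$vertices, rad, c(25, 25, 25))
  expect_true(all(abs(max_extents(ell) - 2 * ax) <= 2))
})

test_that("phantom segmentation recovers the true sphere", {
  ph <- sphere_phantom(8, contrast = 10, n = 48)
  seg <- petedge_segment(ph$image, ph$seed_mm)
  r_eq <- (3 * mask_volume_ml(seg) * 1000 / (4 * pi))^(1 / 3)
  expect_lt(abs(r_eq - 8), 1)              # within one voxel
  expect_gt(dice(seg, ph$truth), 0.9)
  # seed displaced 2 mm from the centre
  seg2 <- petedge_segment(ph$image, ph$seed_mm + c(2, 0, 0))
  expect_gt(dice(seg2, ph$truth), 0.9)
  # zero contrast: no edge anywhere
  flat <- scalar_image(array(3, c(20, 20, 20)))
  expect_error(petedge_segment(flat, c(10, 10, 10)), "no intensity edge")
})

test_that("segmentation is deterministic and intensity-scale invariant", {
  ph <- sphere_phantom(7, contrast = 6, n = 40)
  s1 <- petedge_segment(ph$image, ph$seed_mm)
  s2 <- petedge_segment(ph$image, ph$seed_mm)
  expect_identical(s1$data, s2$data)
  scaled <- scalar_image(ph$image$data * 37.5, ph$image$spacing,
                         ph$image$origin)
  s3 <- petedge_segment(scaled, ph$seed_mm)
  expect_identical(s1$data, s3$data)
  # output is a single connected component containing the seed
  comp <- segmargin:::connected_component(s1$data, c(20, 20, 20))
  expect_identical(comp, s1$data)
})
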