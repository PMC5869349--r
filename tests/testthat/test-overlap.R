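test_that("Dice and Jaccard match direct voxel counting", {
  a <- cube_mask(c(12, 12, 12), c(1, 1, 1), c(10, 10, 10))
  expect_equal(dice(a, a), 1)
  expect_equal(jaccard(a, a), 1)
  # two 10x10x10 cubes sharing a 5x10x10 slab
  big <- c(20, 12, 12)
  c1 <- cube_mask(big, c(1, 1, 1), c(10, 10, 10))
  c2 <- cube_mask(big, c(6, 1, 1), c(15, 10, 10))
  expect_equal(dice(c1, c2), 0.5)
  expect_equal(jaccard(c1, c2), 1 / 3)
  disj <- cube_mask(big, c(12, 1, 1), c(20, 10, 10))
  expect_equal(dice(c1, disj), 0)
  expect_equal(jaccard(c1, disj), 0)
  e <- binary_mask(array(FALSE, big))
  expect_error(dice(e, e), "empty")
  expect_error(jaccard(e, e), "empty")
  expect_error(dice(c1, cube_mask(c(5, 5, 5), c(1, 1, 1), c(2, 2, 2))),
               "grids")
})

test_that("surface voxels are the 6-connectivity boundary", {
  one <- binary_mask(array(c(rep(FALSE, 13), TRUE, rep(FALSE, 13)),
                           c(3, 3, 3)))
  expect_identical(surface_voxels(one)$data, one$data)
  c3 <- cube_mask(c(5, 5, 5), c(2, 2, 2), c(4, 4, 4))
  expect_equal(mask_count(surface_voxels(c3)), 26)
  c10 <- cube_mask(c(12, 12, 12), c(2, 2, 2), c(11, 11, 11))
  expect_equal(mask_count(surface_voxels(c10)), 1000 - 8^3)
  # lattice-boundary voxels count as surface
  full <- binary_mask(array(TRUE, c(4, 4, 4)))
  expect_equal(mask_count(surface_voxels(full)), 64 - 8)
  expect_error(surface_voxels(binary_mask(array(FALSE, c(3, 3, 3)))),
               "empty")
})

test_that("directed distances honour anisotropic spacing", {
  a <- binary_mask(array(FALSE, c(8, 4, 4))); a$data[2, 2, 2] <- TRUE
  b <- binary_mask(array(FALSE, c(8, 4, 4))); b$data[5, 2, 2] <- TRUE
  expect_equal(directed_surface_distances(a, b), 3.0)
  a2 <- binary_mask(a$data, c(2, 1, 1)); b2 <- binary_mask(b$data, c(2, 1, 1))
  expect_equal(directed_surface_distances(a2, b2), 6.0)
  expect_equal(hausdorff_mm(a, b), 3.0)
  expect_equal(mda_mm(a, b), 3.0)
  expect_equal(hausdorff_mm(a, a), 0.0)
  expect_equal(mda_mm(a, a), 0.0)
})

test_that("HD and MDA match the brute-force pairwise oracle", {
  inner <- cube_mask(c(10, 10, 10), c(4, 4, 4), c(7, 7, 7))
  outer_c <- cube_mask(c(10, 10, 10), c(1, 1, 1), c(10, 10, 10))
  expect_equal(hausdorff_mm(inner, outer_c), oracle_hd(inner, outer_c),
               tolerance = 1e-9)
  expect_equal(mda_mm(inner, outer_c), oracle_mda(inner, outer_c),
               tolerance = 1e-9)
  set.seed(2024)
  for (i in 1:12) {
    sp <- sample(list(c(1, 1, 1), c(0.7, 0.9, 3.0), c(2, 1, 1)), 1)[[1]]
    a <- random_mask(c(9, 8, 10), p = 0.25, spacing = sp)
    b <- random_mask(c(9, 8, 10), p = 0.25, spacing = sp)
    expect_equal(hausdorff_mm(a, b), oracle_hd(a, b), tolerance = 1e-9)
    expect_equal(mda_mm(a, b), oracle_mda(a, b), tolerance = 1e-9)
  }
})

test_that("metric symmetry, J = D/(2-D), MDA <= HD, spacing covariance", {
  set.seed(99)
  for (i in 1:15) {
    a <- random_mask(c(10, 10, 10), p = 0.3)
    b <- random_mask(c(10, 10, 10), p = 0.3)
    d <- dice(a, b); j <- jaccard(a, b)
    expect_equal(d, dice(b, a))
    expect_equal(j, jaccard(b, a))
    expect_equal(j, d / (2 - d), tolerance = 1e-12)
    expect_lte(j, d + 1e-15)
    hd <- hausdorff_mm(a, b); md <- mda_mm(a, b)
    expect_equal(hd, hausdorff_mm(b, a))
    expect_equal(md, mda_mm(b, a))
    expect_lte(md, hd + 1e-12)
    # scaling all spacings by s scales distances, leaves overlap unchanged
    s <- 2.5
    a2 <- binary_mask(a$data, a$spacing * s)
    b2 <- binary_mask(b$data, b$spacing * s)
    expect_equal(hausdorff_mm(a2, b2), s * hd, tolerance = 1e-12)
    expect_equal(mda_mm(a2, b2), s * md, tolerance = 1e-12)
    expect_equal(dice(a2, b2), d)
  }
})

test_that("missed volume is the truth outside the candidate", {
  truth <- cube_mask(c(14, 12, 12), c(1, 1, 1), c(10, 10, 10))
  covering <- cube_mask(c(14, 12, 12), c(1, 1, 1), c(12, 12, 12))
  expect_equal(missed_volume(truth, covering),
               list(ml = 0, percent = 0))
  disjoint <- cube_mask(c(14, 12, 12), c(12, 1, 1), c(14, 5, 5))
  expect_equal(missed_volume(truth, disjoint), list(ml = 1, percent = 100))
  half <- cube_mask(c(14, 12, 12), c(1, 1, 1), c(5, 10, 10))
  expect_equal(missed_volume(truth, half), list(ml = 0.5, percent = 50))
  expect_error(missed_volume(binary_mask(array(FALSE, c(3, 3, 3))),
                             binary_mask(array(TRUE, c(3, 3, 3)))), "empty")
})

test_that("similarity_report assembles all metrics consistently", {
  big <- c(20, 12, 12)
  c1 <- cube_mask(big, c(1, 1, 1), c(10, 10, 10))
  c2 <- cube_mask(big, c(6, 1, 1), c(15, 10, 10))
  r <- similarity_report(c1, c2)
  expect_equal(r$dice, 0.5)
  expect_equal(r$jaccard, 1 / 3)
  expect_equal(r$missed_percent, 50)
  expect_equal(r$truth_volume_ml, 1.0)
  ident <- similarity_report(c1, c1)
  expect_equal(ident$dice, 1)
  expect_equal(ident$hd_mm, 0)
  expect_equal(ident$mda_mm, 0)
  expect_equal(ident$missed_volume_ml, 0)
  set.seed(5)
  for (i in 1:8) {
    a <- random_mask(c(9, 9, 9), p = 0.3)
    b <- random_mask(c(9, 9, 9), p = 0.3)
    rr <- similarity_report(a, b)
    expect_lte(rr$jaccard, rr$dice + 1e-15)
    expect_lte(rr$mda_mm, rr$hd_mm + 1e-12)
  }
})
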