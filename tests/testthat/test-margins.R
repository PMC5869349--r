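test_that("expansion matches lattice-point ball enumeration", {
  one <- binary_mask(array(FALSE, c(13, 13, 13)))
  one$data[7, 7, 7] <- TRUE
  ex5 <- expand_mask(one, 5)
  co <- (-6:6)
  enum <- sum(outer(outer(co^2, co^2, "+"), co^2, "+") <= 25 + 1e-9)
  expect_equal(mask_count(ex5), enum)
  expect_identical(expand_mask(one, 0)$data, one$data)
  expect_error(expand_mask(one, -1), "non-negative")
  expect_error(expand_mask(binary_mask(array(FALSE, c(5, 5, 5))), 1),
               "empty")
})

test_that("expansion is extensive, monotone in margin, and warns on clipping", {
  set.seed(12)
  m <- random_mask(c(16, 16, 16), p = 0.05)
  e2 <- suppressWarnings(expand_mask(m, 2))
  e4 <- suppressWarnings(expand_mask(m, 4))
  expect_true(all(e2$data[m$data]))
  expect_true(all(e4$data[e2$data]))
  tight <- binary_mask(array(TRUE, c(3, 3, 3)))
  expect_warning(expand_mask(tight, 2), "clipped")
  # anatomy-style allowed-region truncation
  allowed <- cube_mask(c(13, 13, 13), c(1, 1, 1), c(7, 13, 13))
  one <- binary_mask(array(FALSE, c(13, 13, 13)))
  one$data[7, 7, 7] <- TRUE
  ex <- expand_mask(one, 5, allowed_region = allowed)
  expect_true(all(which(ex$data, arr.ind = TRUE)[, 1] <= 7))
})

test_that("minimum coverage margin equals the brute-force directed maximum", {
  big <- c(20, 12, 12)
  cand <- cube_mask(big, c(1, 1, 1), c(5, 5, 5))
  covering <- cube_mask(big, c(1, 1, 1), c(6, 6, 6))
  expect_equal(min_coverage_margin(cand, covering), 0)
  # single truth voxel 7 mm beyond the candidate along x
  truth <- binary_mask(array(FALSE, big)); truth$data[12, 1, 1] <- TRUE
  expect_equal(min_coverage_margin(truth, cand), 7)
  set.seed(314)
  for (i in 1:10) {
    sp <- sample(list(c(1, 1, 1), c(0.7, 0.9, 3.0)), 1)[[1]]
    t <- random_mask(c(10, 9, 8), p = 0.2, spacing = sp)
    c <- random_mask(c(10, 9, 8), p = 0.2, spacing = sp)
    expect_equal(min_coverage_margin(t, c), oracle_min_margin(t, c),
                 tolerance = 1e-9)
  }
})

test_that("dilation by the minimum coverage margin achieves zero missed volume", {
  set.seed(2718)
  vox_diag <- sqrt(3)
  for (i in 1:10) {
    t <- random_mask(c(12, 12, 12), p = 0.1)
    c <- random_mask(c(12, 12, 12), p = 0.1)
    m <- min_coverage_margin(t, c)
    ex <- suppressWarnings(expand_mask(c, m))
    expect_equal(missed_volume(t, ex)$ml, 0)
    if (m > vox_diag) {
      under <- suppressWarnings(expand_mask(c, m - vox_diag))
      expect_gt(missed_volume(t, under)$ml, 0)
    }
  }
})

test_that("margin report is monotone and consistent with its inputs", {
  truth <- ball_mask(6, c(31, 31, 31))
  # eroded, decentred candidate
  cand <- ball_mask(3.5, c(31, 31, 31), centre_idx = c(14, 16, 16))
  rep <- margin_report(truth, cand, margins_mm = c(1, 2, 3, 5, 10))
  expect_true(all(diff(rep$missed_volume_ml) <= 1e-12))
  expect_true(all(diff(rep$expanded_volume_ml) >= -1e-12))
  covered <- rep$margins_mm >= rep$min_coverage_margin_mm
  expect_true(all(rep$missed_volume_ml[covered] == 0))
  expect_true(all(rep$missed_volume_ml[!covered] > 0))
  ident <- margin_report(truth, truth)
  expect_equal(ident$min_coverage_margin_mm, 0)
  expect_true(all(ident$missed_volume_ml == 0))
  expect_error(margin_report(truth, cand, margins_mm = c(10, 5)),
               "ascending")
})

test_that("the union dominates its parts in coverage", {
  set.seed(55)
  for (i in 1:6) {
    truth <- ball_mask(5, c(25, 25, 25))
    parts <- lapply(1:3, function(k)
      ball_mask(2.5, c(25, 25, 25),
                centre_idx = c(13, 13, 13) + sample(-3:3, 3, TRUE)))
    u <- union_masks(parts)
    missed_u <- missed_volume(truth, u)$ml
    margin_u <- min_coverage_margin(truth, u)
    for (p in parts) {
      expect_lte(missed_u, missed_volume(truth, p)$ml + 1e-12)
      expect_lte(margin_u, min_coverage_margin(truth, p) + 1e-12)
    }
  }
})
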