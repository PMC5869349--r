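test_that("simulated truth hits its target volume and is reproducible", {
  cfg <- cohort_config(seed = 5)
  set.seed(21)
  t1 <- simulate_truth(cfg, target_volume_ml = 2.0)
  expect_lt(abs(mask_volume_ml(t1) - 2.0) / 2.0, 0.02)
  set.seed(21)
  t2 <- simulate_truth(cfg, target_volume_ml = 2.0)
  expect_identical(t1$data, t2$data)
  # zero irregularity gives a smooth ellipsoid-like blob
  cfg0 <- cohort_config(irregularity = 0, seed = 5)
  set.seed(4)
  e <- simulate_truth(cfg0, target_volume_ml = 1.0)
  expect_lt(abs(mask_volume_ml(e) - 1.0), 0.02)
  # ellipsoid formula ~ matches voxel volume for the unperturbed case
  ratio <- ellipsoid_volume_ml(max_extents(e)) / mask_volume_ml(e)
  expect_lt(abs(ratio - 1), 0.15)
  expect_error(simulate_truth(cohort_config(grid_shape = c(16, 16, 16)),
                              target_volume_ml = 6), "too large")
})

test_that("drawn tumor volumes follow the configured lognormal law", {
  cfg <- cohort_config(seed = 5)
  set.seed(99)
  vols <- replicate(60, attr(simulate_truth(cfg), "target_volume_ml"))
  expect_true(all(vols >= cfg$volume_range_ml[1]))
  expect_true(all(vols <= cfg$volume_range_ml[2]))
  # median of the law is ~1.37 mL; loose band at this sample size
  expect_gt(median(vols), 0.8)
  expect_lt(median(vols), 2.2)
})

test_that("reader simulation calibrates coverage and emulates under-segmentation", {
  cfg <- cohort_config(seed = 5)
  set.seed(31)
  truth <- simulate_truth(cfg, target_volume_ml = 2.5)
  rd <- simulate_reader(truth, 0.21)
  cov <- attr(rd, "achieved_coverage")
  expect_lt(abs(cov - 0.21), 0.03)
  miss <- missed_volume(truth, rd)
  expect_lt(abs(miss$percent - 79), 3.5)
  expect_gt(mask_count(rd), 0)
  # full coverage, no decentring, no noise reproduces the truth
  set.seed(32)
  full <- simulate_reader(truth, 1.0, offset_sd_mm = 0,
                          boundary_noise_mm = 0)
  expect_gte(attr(full, "achieved_coverage"), 0.97)
  expect_error(simulate_reader(truth, 1.5), "coverage_target")
})

test_that("simulated PET has the expected plateau and limiting behaviour", {
  truth <- ball_mask(8, c(41, 41, 41))
  set.seed(6)
  pet0 <- simulate_pet(truth, background_suv = 2, tumor_suv = 8,
                       fwhm_mm = 0, noise_sd_fraction = 0)
  expect_equal(pet0$data[truth$data], rep(8, mask_count(truth)))
  expect_equal(pet0$data[!truth$data],
               rep(2, sum(!truth$data)))
  pet <- simulate_pet(truth, background_suv = 2, tumor_suv = 8,
                      fwhm_mm = 4.1, noise_sd_fraction = 0)
  # 16 mm lesion: PSF small vs lesion, centre stays within 2% of tumor SUV
  expect_lt(abs(pet$data[21, 21, 21] - 8) / 8, 0.02)
  expect_error(simulate_pet(truth, background_suv = -1), "positive")
})

test_that("PET segmentation of a simulated lesion recovers its volume", {
  truth <- ball_mask(8, c(41, 41, 41))
  pet <- simulate_pet(truth, background_suv = 2, tumor_suv = 8,
                      fwhm_mm = 4.1, noise_sd_fraction = 0)
  seg <- petedge_segment(pet, c(20, 20, 20))
  err <- abs(mask_volume_ml(seg) - mask_volume_ml(truth)) /
    mask_volume_ml(truth)
  expect_lt(err, 0.15)
})

test_that("cohorts are reproducible and stable under size extension", {
  cfg3 <- cohort_config(n_cases = 3, seed = 42)
  co_a <- simulate_cohort(cfg3)
  co_b <- simulate_cohort(cfg3)
  expect_identical(co_a$manifest, co_b$manifest)
  expect_identical(co_a$cases[[2]]$truth$data, co_b$cases[[2]]$truth$data)
  expect_identical(co_a$pet_images[[1]]$data, co_b$pet_images[[1]]$data)
  # extending the cohort leaves earlier cases untouched
  co_c <- simulate_cohort(cohort_config(n_cases = 4, seed = 42))
  expect_identical(co_c$cases[[3]]$truth$data, co_a$cases[[3]]$truth$data)
  # structure: truth + seg1/seg2/seg3 per case
  expect_named(co_a$cases[[1]]$candidates, c("seg1", "seg2", "seg3"))
  expect_equal(nrow(co_a$manifest), 3)
})

test_that("a written cohort can be read back from NIfTI", {
  co <- simulate_cohort(cohort_config(n_cases = 1, seed = 9,
                                      grid_shape = c(48, 48, 48)))
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  truth <- read_mask(file.path(dir, "case001", "truth.nii.gz"))
  expect_identical(truth$data, co$cases[[1]]$truth$data)
  seg1 <- read_mask(file.path(dir, "case001", "seg1.nii.gz"))
  expect_identical(seg1$data, co$cases[[1]]$candidates$seg1$data)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$case_id, "case001")
})
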