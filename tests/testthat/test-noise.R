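cuboid_mask <- function(d, spacing) {
  arr <- array(TRUE, dim = d)
  binary_mask(arr, spacing)
}

test_that("a constant volume has zero raw and normalized noise", {
  vol <- ct_volume(array(40, dim = c(10, 10, 10)), c(1, 1, 1))
  nr <- compute_noise(vol, cuboid_mask(c(10, 10, 10), c(1, 1, 1)))
  expect_equal(nr$sigma_raw, 0)
  expect_equal(nr$sigma_norm, 0)
  expect_equal(nr$mu_raw, 40)
  expect_equal(nr$n_voxels, 1000L)
})

test_that("normalization is the identity at 1 mm^3 and sqrt(v_raw) otherwise", {
  set.seed(5)
  arr <- array(rnorm(1000, 40, 20), dim = c(10, 10, 10))
  iso <- ct_volume(arr, c(1, 1, 1))
  nr <- compute_noise(iso, cuboid_mask(c(10, 10, 10), c(1, 1, 1)))
  expect_equal(nr$sigma_norm, nr$sigma_raw)
  expect_equal(nr$v_raw, 1)
  # same values on a 0.5 mm^3 voxel grid: sigma_norm = sigma_raw * sqrt(0.5)
  half <- ct_volume(arr, c(0.5, 0.5, 2.0))
  nh <- compute_noise(half, cuboid_mask(c(10, 10, 10), c(0.5, 0.5, 2.0)))
  expect_equal(nh$v_raw, 0.5)
  expect_equal(nh$sigma_norm, nh$sigma_raw * sqrt(0.5))
})

test_that("sigma_raw is the sample (n-1) standard deviation of masked voxels", {
  # two lumen voxels at 40 +/- 20/sqrt(2) have sample SD exactly 20
  arr <- array(0, dim = c(4, 4, 1))
  x <- 20 / sqrt(2)
  arr[1, 1, 1] <- 40 + x
  arr[2, 1, 1] <- 40 - x
  vol <- ct_volume(arr, c(0.5, 0.5, 2.0))
  lum <- mask_from_indices(c(4, 4, 1), c(1, 2), spacing = c(0.5, 0.5, 2.0))
  nr <- compute_noise(vol, lum, min_voxels = 2)
  expect_equal(nr$sigma_raw, 20)
  expect_equal(nr$sigma_norm, 20 * sqrt(0.5))
  expect_equal(round(nr$sigma_norm, 4), 14.1421)
})

test_that("too few lumen voxels reports noise as unavailable", {
  vol <- ct_volume(array(0, dim = c(5, 5, 5)), c(1, 1, 1))
  lum <- mask_from_indices(c(5, 5, 5), 1:50)
  expect_error(compute_noise(vol, lum, min_voxels = 100),
               class = "ldctqa_noise_unavailable")
  expect_silent(compute_noise(vol, lum, min_voxels = 50))
})

test_that("effective mAs is mAs over pitch", {
  expect_equal(effective_mas(40, 1.0), 40)
  expect_equal(effective_mas(100, 2.0), 50)
  expect_error(effective_mas(100, 0), class = "ldctqa_invalid_input")
  expect_error(effective_mas(-10, 1), class = "ldctqa_invalid_input")
})

test_that("injected noise is recovered on a mid-size phantom", {
  ph <- generate_phantom(small_phantom_spec(seed = 71, noise_sigma = 25))
  lung <- merge_lobes(ph$truth$lobes)
  lx <- extract_lumen(ph$truth$aorta, lung)
  nr <- compute_noise(ph$volume, lx$lumen)
  expect_gt(lx$n_voxels, 1000)
  expect_lt(abs(nr$sigma_raw - 25) / 25, 0.05)
  expect_lt(abs(nr$mu_raw - 40), 2)
})

test_that("halving the exposure scales noise by sqrt(2) through the pipeline", {
  sigma_full <- 20
  sigma_half <- noise_sigma_from_mas(mas = 20, sigma_ref = sigma_full,
                                     mas_ref = 40)
  expect_equal(sigma_half, sigma_full * sqrt(2))
  nrs <- lapply(c(40, 20), function(mas) {
    sig <- noise_sigma_from_mas(mas, sigma_ref = sigma_full, mas_ref = 40)
    ph <- generate_phantom(small_phantom_spec(seed = 72, noise_sigma = sig,
                                              mas = mas))
    lung <- merge_lobes(ph$truth$lobes)
    lx <- extract_lumen(ph$truth$aorta, lung)
    compute_noise(ph$volume, lx$lumen)
  })
  ratio <- nrs[[2]]$sigma_norm / nrs[[1]]$sigma_norm
  expect_lt(abs(ratio - sqrt(2)), 0.05 * sqrt(2))
})

test_that("pitch enters the dose law through effective mAs", {
  # doubling pitch at fixed mAs halves effective mAs: noise times sqrt(2)
  s1 <- noise_sigma_from_mas(100, pitch = 1, sigma_ref = 30, mas_ref = 100)
  s2 <- noise_sigma_from_mas(100, pitch = 2, sigma_ref = 30, mas_ref = 100)
  expect_equal(s1, 30)
  expect_equal(s2, 30 * sqrt(2))
})
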