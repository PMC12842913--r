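test_that("phantom generation is deterministic given a seed", {
  a <- generate_phantom(small_phantom_spec(seed = 81))
  b <- generate_phantom(small_phantom_spec(seed = 81))
  expect_identical(a$volume$voxels, b$volume$voxels)
  c <- generate_phantom(small_phantom_spec(seed = 82))
  expect_false(identical(a$volume$voxels, c$volume$voxels))
})

test_that("truth margins follow gap slices times dz by construction", {
  ph <- generate_phantom(phantom_spec(shape = c(64, 64, 60),
                                      spacing = c(1.8, 1.8, 2.0),
                                      caudal_gap_slices = 10,
                                      cranial_gap_slices = 20,
                                      noise_sigma = 0))
  expect_equal(ph$truth$margins_mm[["caudal"]], 20.0)
  expect_equal(ph$truth$margins_mm[["cranial"]], 40.0)
  expect_false(any(ph$truth$underscan))
})

test_that("truth masks are consistent: lobes partition the lung, wall excludes blood", {
  ph <- generate_phantom(small_phantom_spec(seed = 83))
  tr <- ph$truth
  union <- Reduce(`|`, lapply(tr$lobes, `[[`, "voxels"))
  expect_identical(union, tr$lung$voxels)
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(sum(tr$lobes[[i]]$voxels & tr$lobes[[j]]$voxels), 0)
  expect_equal(sum(tr$lumen$voxels & tr$wall$voxels), 0)
  expect_true(all(!tr$lumen$voxels | tr$aorta$voxels))
  expect_equal(sum(tr$descending$voxels & tr$ascending$voxels), 0)
  # tissue HU values in the noise-free map
  ph0 <- generate_phantom(small_phantom_spec(seed = 83, noise_sigma = 0))
  expect_true(all(ph0$volume$voxels[ph0$truth$lumen$voxels] == 40))
  expect_true(all(ph0$volume$voxels[ph0$truth$wall$voxels] == 50))
  expect_true(all(ph0$volume$voxels[ph0$truth$lung$voxels] == -800))
})

test_that("injected noise has the specified standard deviation", {
  ph <- generate_phantom(small_phantom_spec(seed = 84, noise_sigma = 30))
  vals <- ph$volume$voxels[ph$truth$lumen$voxels]
  expect_gt(length(vals), 3000)
  expect_lt(abs(sd(vals) - 30) / 30, 0.05)
})

test_that("infeasible geometry is rejected", {
  # aorta placed inside the left lung
  expect_error(generate_phantom(small_phantom_spec(
    aorta = list(x_mm = 84, ascending_y_mm = 40, descending_y_mm = 60))),
    class = "ldctqa_infeasible_geometry")
  # arch with no cranial headroom
  expect_error(generate_phantom(small_phantom_spec(cranial_gap_slices = 6)),
               class = "ldctqa_infeasible_geometry")
  # gaps leaving no lung
  expect_error(phantom_spec(shape = c(16, 16, 20), caudal_gap_slices = 10,
                            cranial_gap_slices = 12),
               class = "ldctqa_invalid_input")
})

test_that("cohorts are reproducible and force the stated underscan count", {
  a <- generate_cohort(10, seed = 5, underscan_fraction = 0.2)
  b <- generate_cohort(10, seed = 5, underscan_fraction = 0.2)
  flags_a <- vapply(a, function(p) any(p$truth$underscan), logical(1))
  expect_equal(sum(flags_a), 2L)
  for (i in seq_along(a)) {
    expect_identical(a[[i]]$volume$voxels, b[[i]]$volume$voxels)
    expect_identical(a[[i]]$truth$margins_mm, b[[i]]$truth$margins_mm)
  }
})

test_that("phantom export writes loadable volume, masks and truth record", {
  ph <- generate_phantom(small_phantom_spec(seed = 85))
  dir <- tempfile("phantom")
  paths <- write_phantom(ph, dir)
  expect_true(all(file.exists(paths)))
  vol <- load_volume(paths[["volume"]])
  expect_equal(as.vector(vol$voxels), as.vector(ph$volume$voxels))
  m <- read_mask(paths[["aorta"]])
  expect_identical(m$voxels, ph$truth$aorta$voxels)
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$margins_mm$caudal, ph$truth$margins_mm[["caudal"]])
})
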