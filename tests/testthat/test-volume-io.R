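test_that("NIfTI write/load round-trips voxels bitwise and spacing to 1e-6 mm", {
  ph <- generate_phantom(small_phantom_spec(seed = 11))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(ph$volume, f)
  vol <- load_volume(f)
  expect_identical(dim(vol$voxels), dim(ph$volume$voxels))
  expect_identical(as.vector(vol$voxels), as.vector(ph$volume$voxels))
  expect_lt(max(abs(vol$spacing - ph$volume$spacing)), 1e-6)
  expect_identical(vol$orientation, "LPS")
  expect_length(check_integrity(vol), 0)
})

test_that("a single-slice isotropic NIfTI loads with dz = 1 mm", {
  arr <- array(rnorm(25, -500, 100), dim = c(5, 5, 1))
  vol0 <- ct_volume(arr, c(1, 1, 1))
  f <- tempfile(fileext = ".nii")
  write_volume(vol0, f)
  vol <- load_volume(f)
  expect_equal(vol$spacing[3], 1)
  expect_equal(as.vector(vol$voxels), as.vector(arr))
})

test_that("load_volume distinguishes missing from corrupt input", {
  expect_error(load_volume(tempfile(fileext = ".nii")),
               class = "ldctqa_missing_input")
  bad <- tempfile(fileext = ".nii")
  writeLines("this is not a nifti file", bad)
  expect_error(load_volume(bad), class = "ldctqa_corrupt_input")
})

test_that("volumes stored in a non-canonical layout are reoriented on load", {
  ph <- generate_phantom(small_phantom_spec(seed = 12))
  vox <- ph$volume$voxels
  sp <- ph$volume$spacing
  # store the same scene flipped in x and y (an RAS-layout file)
  flipped <- vox[dim(vox)[1]:1, dim(vox)[2]:1, , drop = FALSE]
  img <- RNifti::asNifti(flipped)
  RNifti::qform(img) <- structure(
    rbind(c(sp[1], 0, 0, -sp[1] * dim(vox)[1]),
          c(0, sp[2], 0, -sp[2] * dim(vox)[2]),
          c(0, 0, sp[3], 0), c(0, 0, 0, 1)), code = 2L)
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f)
  vol <- load_volume(f)
  expect_identical(vol$orientation, "LPS")
  expect_equal(as.vector(vol$voxels), as.vector(vox))
})

test_that("check_integrity flags implausible HU and is pure", {
  arr <- array(0, dim = c(4, 4, 4))
  arr[1, 1, 1] <- -20000
  vol <- ct_volume(arr, c(1, 1, 1))
  flags <- check_integrity(vol)
  expect_true("HU_IMPLAUSIBLE" %in% vapply(flags, `[[`, character(1), "code"))
  # the floor is configurable; at -25000 the same volume is clean
  expect_length(check_integrity(vol, hu_floor = -25000), 0)
  # idempotent and side-effect free
  flags2 <- check_integrity(vol)
  expect_identical(flags, flags2)
  expect_identical(vol$voxels[1, 1, 1], -20000)
})

test_that("check_integrity flags inconsistent slice spacing", {
  arr <- array(0, dim = c(4, 4, 6))
  good <- ct_volume(arr, c(1, 1, 2.5),
                    slice_positions = c(0, 2.5, 5, 7.5, 10, 12.5))
  expect_length(check_integrity(good), 0)
  # one doubled gap (missing slice)
  bad <- ct_volume(arr, c(1, 1, 2.5),
                   slice_positions = c(0, 2.5, 5, 10, 12.5, 15))
  codes <- vapply(check_integrity(bad), `[[`, character(1), "code")
  expect_true("SPACING_INCONSISTENT" %in% codes)
})

test_that("unresolved orientation and missing rescale are flagged", {
  arr <- array(0, dim = c(4, 4, 4))
  vol <- ct_volume(arr, c(1, 1, 1), orientation = "unknown",
                   acquisition = acquisition_meta(rescale_present = FALSE))
  codes <- vapply(check_integrity(vol), `[[`, character(1), "code")
  expect_setequal(codes, c("ORIENTATION_UNRESOLVED", "RESCALE_MISSING"))
})

test_that("constructors reject invalid volumes and metadata", {
  expect_error(ct_volume(array(0, c(2, 2)), c(1, 1, 1)),
               class = "ldctqa_invalid_input")
  expect_error(ct_volume(array(0, c(2, 2, 2)), c(1, -1, 1)),
               class = "ldctqa_invalid_input")
  expect_error(acquisition_meta(mas = -5), class = "ldctqa_invalid_input")
  expect_error(acquisition_meta(pitch = 0), class = "ldctqa_invalid_input")
})
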