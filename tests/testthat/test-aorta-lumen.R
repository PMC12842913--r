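straight_tube <- function(d = c(20, 20, 30), center = c(10, 14), r = 4,
                          zr = 3:28, spacing = c(1, 1, 1)) {
  arr <- array(FALSE, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    if ((i - center[1])^2 + (j - center[2])^2 <= r^2) arr[i, j, zr] <- TRUE
  binary_mask(arr, spacing)
}

test_that("a straight tube never splits and is returned unchanged", {
  tube <- straight_tube()
  res <- split_descending(tube)
  expect_false(res$split_found)
  expect_equal(res$n_slices_removed, 0L)
  expect_identical(res$mask$voxels, tube$voxels)
})

test_that("two separate tubes split at k = 0 and the posterior one wins", {
  ant <- straight_tube(center = c(10, 4), r = 3)$voxels
  post <- straight_tube(center = c(10, 14), r = 3)$voxels
  m <- binary_mask(ant | post, c(1, 1, 1))
  res <- split_descending(m)
  expect_true(res$split_found)
  expect_equal(res$n_slices_removed, 0L)
  expect_identical(res$mask$voxels, post)
})

test_that("the candy-cane aorta splits below the arch keeping the dorsal limb", {
  ph <- generate_phantom(small_phantom_spec(seed = 51))
  er <- erode_inplane_margin(largest_component(ph$truth$aorta), 3)
  res <- split_descending(er)
  expect_true(res$split_found)
  expect_gt(res$n_slices_removed, 0)
  kept <- res$mask$voxels
  expect_false(any(kept & ph$truth$ascending$voxels))
  expect_gt(sum(kept & ph$truth$descending$voxels), 0)
  # dorsal selection: kept centroid strictly posterior to the discarded one
  disc <- er$voxels & !kept
  disc[, , (dim(er$voxels)[3] - res$n_slices_removed + 1):dim(er$voxels)[3]] <- FALSE
  cy <- function(v) mean(arrayInd(which(v), dim(v))[, 2])
  expect_gt(cy(kept), cy(disc))
})

test_that("trimming restricts the lumen to the lung slice interval", {
  lumen <- straight_tube(d = c(20, 20, 100), zr = 1:100)
  lung <- slab_lung(nz = 100, lo = 11, hi = 90, nx = 20, ny = 20)
  tr <- trim_to_lung_extent(lumen, lung)
  pres <- apply(tr$voxels, 3, any)
  expect_equal(range(which(pres)), c(11, 90))
  # lumen already inside the lung extent is unchanged
  inner <- straight_tube(d = c(20, 20, 100), zr = 30:60)
  expect_identical(trim_to_lung_extent(inner, lung)$voxels, inner$voxels)
  # lumen entirely below the lung is unusable
  below <- straight_tube(d = c(20, 20, 100), zr = 1:5)
  expect_error(trim_to_lung_extent(below, lung), class = "ldctqa_empty_mask")
})

test_that("extract_lumen yields pure blood on wall phantoms", {
  for (seed in c(61, 62)) {
    ph <- generate_phantom(small_phantom_spec(seed = seed))
    lung <- merge_lobes(ph$truth$lobes)
    lx <- extract_lumen(ph$truth$aorta, lung, margin_mm = 3.0)
    expect_s3_class(lx, "lumen_extraction")
    expect_gt(lx$n_voxels, 0)
    # purity: nothing from the wall, nothing from outside the aorta blood
    expect_equal(sum(lx$lumen$voxels & ph$truth$wall$voxels), 0)
    expect_equal(sum(lx$lumen$voxels & !ph$truth$lumen$voxels), 0)
    expect_true(lx$split_found)
    expect_equal(length(lx$provenance), 4L)
  }
})

test_that("extraction works without an arch and reports no split", {
  ph <- generate_phantom(small_phantom_spec(seed = 63,
                                            aorta = list(arch = FALSE)))
  lung <- merge_lobes(ph$truth$lobes)
  lx <- extract_lumen(ph$truth$aorta, lung)
  expect_false(lx$split_found)
  expect_equal(sum(lx$lumen$voxels & !ph$truth$lumen$voxels), 0)
})

test_that("with margin 0 and no wall the chain reduces to component + trim", {
  ph <- generate_phantom(noise_phantom_spec(noise_sigma = 0, seed = 64))
  lung <- merge_lobes(ph$truth$lobes)
  lx <- extract_lumen(ph$truth$aorta, lung, margin_mm = 0)
  manual <- trim_to_lung_extent(largest_component(ph$truth$aorta), lung)
  expect_identical(lx$lumen$voxels, manual$voxels)
})

test_that("lumen shrinks monotonically with the margin", {
  ph <- generate_phantom(small_phantom_spec(seed = 65))
  lung <- merge_lobes(ph$truth$lobes)
  l3 <- extract_lumen(ph$truth$aorta, lung, margin_mm = 3)
  l5 <- extract_lumen(ph$truth$aorta, lung, margin_mm = 5)
  expect_true(all(!l5$lumen$voxels | l3$lumen$voxels))
  expect_lt(l5$n_voxels, l3$n_voxels)
})

test_that("an over-aggressive margin fails loudly with the step name", {
  ph <- generate_phantom(small_phantom_spec(seed = 66))
  lung <- merge_lobes(ph$truth$lobes)
  err <- tryCatch(extract_lumen(ph$truth$aorta, lung, margin_mm = 60),
                  error = identity)
  expect_s3_class(err, "ldctqa_empty_mask")
  expect_match(conditionMessage(err), "erosion")
  expect_error(split_descending(binary_mask(array(FALSE, c(4, 4, 4)),
                                            c(1, 1, 1))),
               class = "ldctqa_empty_mask")
})
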