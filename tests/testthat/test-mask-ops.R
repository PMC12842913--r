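test_that("largest_component keeps the biggest blob and is idempotent", {
  d <- c(20, 20, 10)
  arr <- array(FALSE, dim = d)
  arr[2:6, 2:6, 2:5] <- TRUE        # 100 voxels
  arr[15:15, 15:19, 3] <- TRUE      # 5 voxels
  m <- binary_mask(arr, c(1, 1, 1))
  lc <- largest_component(m)
  expect_equal(mask_count(lc), 100)
  expect_false(any(lc$voxels[15, , ]))
  # identity on a single blob, idempotent in general
  expect_identical(largest_component(lc)$voxels, lc$voxels)
  expect_error(largest_component(binary_mask(array(FALSE, d), c(1, 1, 1))),
               class = "ldctqa_empty_mask")
})

test_that("component labelling matches a brute-force oracle", {
  set.seed(41)
  for (conn in c(6, 26)) {
    for (rep in 1:5) {
      arr <- array(runif(8 * 8 * 6) < 0.35, dim = c(8, 8, 6))
      m <- binary_mask(arr, c(1, 1, 1))
      lab <- label_components(m, connectivity = conn)
      ora <- oracle_label(arr, connectivity = conn)
      expect_equal(max(lab), max(ora))
      # same partition: component of each voxel agrees up to renumbering
      for (l in seq_len(max(lab)))
        expect_true(length(unique(ora[lab == l])) == 1)
    }
  }
})

test_that("equal-size components tie-break on the smallest linear index", {
  arr <- array(FALSE, dim = c(30, 10, 5))
  arr[20:24, 2:6, 1:2] <- TRUE  # 50 voxels, but larger linear indices
  arr[2:6, 5:9, 3:4] <- TRUE    # 50 voxels; first voxel has smaller index
  m <- binary_mask(arr, c(1, 1, 1))
  lab <- label_components(m)
  expect_equal(max(lab), 2)
  expect_equal(min(which(arr)), min(which(lab == 1)))
  lc <- largest_component(m)
  expect_true(all(which(lc$voxels) == which(lab == 1)))
})

test_that("merge_lobes removes satellites and unions overlapping lobes", {
  ph <- generate_phantom(small_phantom_spec(seed = 21))
  lobes <- ph$truth$lobes
  # add a one-voxel satellite to one lobe: must not survive the merge
  sat <- lobes$right_upper
  sat$voxels[1, 1, 1] <- TRUE
  lobes$right_upper <- sat
  lung <- merge_lobes(lobes)
  expect_false(lung$voxels[1, 1, 1])
  expect_identical(lung$voxels, ph$truth$lung$voxels)
  # boolean union: overlapping lobes do not double count
  lobes2 <- ph$truth$lobes
  lobes2$right_middle <- ph$truth$lobes$right_upper
  lung2 <- merge_lobes(lobes2)
  expect_lte(mask_count(lung2), mask_count(lung))
})

test_that("merge_lobes warns on an empty lobe and errors when all are empty", {
  ph <- generate_phantom(small_phantom_spec(seed = 22))
  lobes <- ph$truth$lobes
  empty <- binary_mask(array(FALSE, dim = dim(lobes[[1]]$voxels)),
                       lobes[[1]]$spacing)
  lobes$left_upper <- empty
  expect_warning(lung <- merge_lobes(lobes), "left_upper")
  expect_gt(mask_count(lung), 0)
  all_empty <- setNames(rep(list(empty), 5), names(ph$truth$lobes))
  expect_error(suppressWarnings(merge_lobes(all_empty)),
               class = "ldctqa_empty_mask")
})

test_that("in-plane erosion guarantees the metric margin (distance-transform oracle)", {
  # disk of radius 10 voxels at 1 mm spacing, margin 3 mm
  arr <- array(FALSE, dim = c(32, 32, 3))
  for (i in 1:32) for (j in 1:32)
    if ((i - 16)^2 + (j - 16)^2 <= 100) arr[i, j, 2] <- TRUE
  m <- binary_mask(arr, c(1, 1, 1))
  er <- erode_inplane_margin(m, 3.0)
  expect_gt(mask_count(er), 0)
  dm <- EBImage::distmap(arr[, , 2] * 1)
  expect_true(all(dm[er$voxels[, , 2]] >= 3.0))
  # erosion must act only in-plane: the untouched slices stay empty
  expect_false(any(er$voxels[, , c(1, 3)]))
})

test_that("erosion output is a subset, monotone in margin, with identity at 0", {
  set.seed(7)
  ph <- generate_phantom(small_phantom_spec(seed = 23))
  m <- ph$truth$aorta
  expect_identical(erode_inplane_margin(m, 0)$voxels, m$voxels)
  e2 <- erode_inplane_margin(m, 2)
  e4 <- erode_inplane_margin(m, 4)
  expect_true(all(!e2$voxels | m$voxels))   # e2 subset of m
  expect_true(all(!e4$voxels | e2$voxels))  # e4 subset of e2
})

test_that("a ribbon thinner than the margin erodes to nothing", {
  arr <- array(FALSE, dim = c(20, 20, 2))
  arr[5:7, , ] <- TRUE  # 3 voxels wide at 1 mm
  m <- binary_mask(arr, c(1, 1, 1))
  expect_equal(mask_count(erode_inplane_margin(m, 3.0)), 0)
})

test_that("the erosion margin holds on randomized phantom aortas", {
  set.seed(99)
  for (rep in 1:8) {
    r <- runif(1, 7, 11)
    ph <- generate_phantom(phantom_spec(
      shape = c(64, 64, 40), spacing = c(1.25, 1.25, 2),
      caudal_gap_slices = 4, cranial_gap_slices = 16,
      lung = list(center_right = c(22, 26), center_left = c(56, 26),
                  radius_mm = 12),
      aorta = list(x_mm = 39, ascending_y_mm = 42, descending_y_mm = 62,
                   lumen_radius_mm = r, wall_thickness_mm = 1.9,
                   arch = FALSE, descending_caudal_slice = 2),
      body = list(center = c(39, 40), semi = c(38, 38)),
      noise_sigma = 0, seed = rep))
    m <- ph$truth$aorta
    margin <- sample(c(2, 3, 4.5), 1)
    er <- erode_inplane_margin(m, margin)
    for (z in which(apply(er$voxels, 3, any))) {
      dm <- EBImage::distmap(m$voxels[, , z] * 1) * m$spacing[1]
      expect_true(all(dm[er$voxels[, , z]] >= margin))
    }
  }
})

test_that("block averaging reduces grids and conserves means", {
  arr <- array(rnorm(16 * 16 * 8), dim = c(16, 16, 8))
  vol <- ct_volume(arr, c(0.5, 0.5, 2))
  bav <- block_average(vol, c(2, 2, 1))
  expect_equal(dim(bav$voxels), c(8, 8, 8))
  expect_equal(bav$spacing, c(1, 1, 2))
  expect_equal(mean(bav$voxels), mean(arr))
  expect_equal(bav$voxels[1, 1, 1], mean(arr[1:2, 1:2, 1]))
  m <- binary_mask(array(TRUE, dim = c(16, 16, 8)), c(0.5, 0.5, 2))
  m$voxels[1, 1, 1] <- FALSE
  bm <- block_reduce_mask(m, c(2, 2, 1))
  expect_false(bm$voxels[1, 1, 1])  # partial block dropped
  expect_true(all(bm$voxels[-1, , ]))
})
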