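# Shared phantom specifications used across test files.

# Small, fast phantom with default anatomy on a coarse grid.
small_phantom_spec <- function(..., seed = 1) {
  args <- utils::modifyList(
    list(shape = c(64, 64, 80), spacing = c(1.8, 1.8, 1.5),
         caudal_gap_slices = 8, cranial_gap_slices = 20, seed = seed),
    list(...))
  do.call(phantom_spec, args)
}

# Wide straight-tube phantom sized so the trimmed blood mask exceeds 1e5
# voxels: lumen radius 16 mm, no wall, no arch, fine in-plane grid.
noise_phantom_spec <- function(noise_sigma, seed) {
  phantom_spec(shape = c(96, 96, 90), spacing = c(0.7, 0.7, 1.0),
               caudal_gap_slices = 10, cranial_gap_slices = 14,
               lung = list(center_right = c(17, 20), center_left = c(50, 20),
                           radius_mm = 13),
               aorta = list(x_mm = 33, ascending_y_mm = 25,
                            descending_y_mm = 47, lumen_radius_mm = 16,
                            wall_thickness_mm = 0, arch = FALSE,
                            descending_caudal_slice = 5),
               body = list(center = c(33.5, 33.5), semi = c(35, 35)),
               noise_sigma = noise_sigma, seed = seed)
}

# Build a binary mask directly from voxel index predicates.
mask_from_indices <- function(dim, idx, spacing = c(1, 1, 1)) {
  arr <- array(FALSE, dim = dim)
  arr[idx] <- TRUE
  binary_mask(arr, spacing)
}

# A lung-like mask occupying a full in-plane block on slices lo..hi.
slab_lung <- function(nz, lo, hi, dz = 1, nx = 8, ny = 8) {
  arr <- array(FALSE, dim = c(nx, ny, nz))
  arr[3:6, 3:6, lo:hi] <- TRUE
  binary_mask(arr, c(1, 1, dz))
}
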