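#' Construct a 3D binary mask
#'
#' A `binary_mask` is a logical 3D array aligned to a [ct_volume()] grid,
#' carrying the same voxel spacing. Masks represent the lung lobes, the
#' aorta, and the extracted aortic-blood volume.
#'
#' @param voxels Logical 3D array (numeric arrays of 0/1 are coerced).
#' @param spacing Numeric length-3 vector `(dx, dy, dz)` in mm.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L || length(voxels) == 0L)
    stop_ldctqa("'voxels' must be a non-empty 3D array", "ldctqa_invalid_input")
  if (!is.logical(voxels)) {
    u <- unique(as.vector(voxels))
    if (!all(u %in% c(0, 1)))
      stop_ldctqa("mask values must be logical or 0/1", "ldctqa_invalid_input")
    storage.mode(voxels) <- "logical"
  }
  if (anyNA(voxels))
    stop_ldctqa("mask must not contain NA", "ldctqa_invalid_input")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_ldctqa("'spacing' must be three positive numbers (mm)",
                "ldctqa_invalid_input")
  structure(list(voxels = voxels, spacing = spacing), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<binary_mask> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, %d foreground\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              sum(x$voxels)))
  invisible(x)
}

#' @export
dim.binary_mask <- function(x) dim(x$voxels)

#' Number of foreground voxels in a mask
#' @param mask A [binary_mask()].
#' @return Integer count.
#' @export
mask_count <- function(mask) sum(mask$voxels)

is_empty_mask <- function(mask) !any(mask$voxels)

assert_same_grid <- function(a, b, what = "masks") {
  da <- if (inherits(a, "ct_volume")) dim(a$voxels) else dim(a$voxels)
  db <- dim(b$voxels)
  if (!identical(da, db))
    stop_ldctqa(sprintf("%s are on different grids (%s vs %s); no resampling is performed",
                        what, paste(da, collapse = "x"),
                        paste(db, collapse = "x")),
                "ldctqa_grid_mismatch")
  if (max(abs(a$spacing - b$spacing)) > 1e-6)
    stop_ldctqa(sprintf("%s differ in voxel spacing; no resampling is performed",
                        what), "ldctqa_grid_mismatch")
  invisible(TRUE)
}

#' Write a binary mask to NIfTI
#'
#' Stored as 0/1 with the canonical-orientation qform, so a round-trip
#' through [read_mask()] is lossless.
#'
#' @param mask A [binary_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  arr <- mask$voxels
  storage.mode(arr) <- "integer"
  img <- RNifti::asNifti(arr)
  sp <- mask$spacing
  RNifti::qform(img) <- structure(diag(c(-sp[1], -sp[2], sp[3], 1)), code = 2L)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a binary mask from a NIfTI label file
#'
#' The file must contain only the values 0 and 1; multi-label files are
#' rejected as ambiguous rather than silently thresholded.
#'
#' @param path Path to a NIfTI file.
#' @return A [binary_mask()] in canonical orientation.
#' @export
read_mask <- function(path) {
  vol <- load_nifti_volume(path)
  u <- unique(as.vector(vol$voxels))
  if (!all(u %in% c(0, 1)))
    stop_ldctqa(sprintf("'%s' is not a binary mask (values: %s)", path,
                        paste(sort(u)[seq_len(min(5, length(u)))], collapse = ", ")),
                "ldctqa_invalid_input")
  arr <- vol$voxels == 1
  binary_mask(arr, vol$spacing)
}
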