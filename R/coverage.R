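#' Quantify cranial/caudal over- and underscanning
#'
#' Given the cleaned whole-lung mask in canonical orientation, counts the
#' slices strictly caudal and strictly cranial to the lung and converts them
#' to millimetres with the cranio-caudal voxel spacing `dz`. A zero-margin
#' convention is used: every slice beyond the lung parenchyma counts as
#' overscan, with no tolerance subtracted, giving a continuous, maximally
#' sensitive measure; operational alerting should apply site-specific
#' thresholds to these distances (see [flag_exceptions()]).
#'
#' Underscanning -- lung tissue reaching the caudal-most or cranial-most
#' slice, indicating possible truncation -- is flagged per direction; a
#' flagged direction necessarily has overscan 0 mm.
#'
#' @param lung A non-empty [binary_mask()] of the whole lung.
#' @return An object of class `coverage_result` with fields
#'   `caudal_overscan_mm`, `cranial_overscan_mm`, `underscan_caudal`,
#'   `underscan_cranial`, `lung_slice_range` (1-based inclusive indices
#'   along the cranio-caudal axis), `n_slices_total`, and
#'   `fraction_nonlung_slices`.
#' @export
measure_coverage <- function(lung) {
  stopifnot(inherits(lung, "binary_mask"))
  if (is_empty_mask(lung))
    stop_ldctqa("lung mask is empty; cannot measure coverage",
                "ldctqa_empty_mask")
  presence <- slice_presence(lung)
  nz <- length(presence)
  first <- which(presence)[1]
  last <- nz + 1L - which(rev(presence))[1]
  dz <- lung$spacing[3]
  structure(list(
    caudal_overscan_mm = (first - 1L) * dz,
    cranial_overscan_mm = (nz - last) * dz,
    underscan_caudal = first == 1L,
    underscan_cranial = last == nz,
    lung_slice_range = c(first, last),
    n_slices_total = nz,
    fraction_nonlung_slices = mean(!presence)
  ), class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  fmt_dir <- function(us, mm) if (us) "UNDERSCAN" else sprintf("%.2f mm overscan", mm)
  cat("<coverage_result>\n")
  cat(sprintf("  caudal:  %s\n", fmt_dir(x$underscan_caudal, x$caudal_overscan_mm)))
  cat(sprintf("  cranial: %s\n", fmt_dir(x$underscan_cranial, x$cranial_overscan_mm)))
  cat(sprintf("  lung slices %d-%d of %d (%.2f%% of slices without lung)\n",
              x$lung_slice_range[1], x$lung_slice_range[2], x$n_slices_total,
              100 * x$fraction_nonlung_slices))
  invisible(x)
}

# TRUE for every slice containing at least one foreground voxel
slice_presence <- function(mask) {
  d <- dim(mask$voxels)
  m <- mask$voxels
  dim(m) <- c(d[1] * d[2], d[3])
  colSums(m) > 0
}

#' Fraction of slices containing no lung tissue
#'
#' @param lung A [binary_mask()] of the whole lung.
#' @return Proportion in \[0, 1\] of slices with zero lung voxels.
#' @export
fraction_nonlung_slices <- function(lung) {
  stopifnot(inherits(lung, "binary_mask"))
  mean(!slice_presence(lung))
}
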