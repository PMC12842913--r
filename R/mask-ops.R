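# Morphological building blocks shared by the lung-coverage and
# aortic-lumen stages.

#' Label connected components of a mask
#'
#' @param mask A [binary_mask()].
#' @param connectivity 26 (default; voxels sharing a face, edge or corner)
#'   or 6 (face neighbours only).
#' @return Integer array of the mask's dimensions; 0 is background,
#'   components are numbered from 1 in raster-scan order of their first
#'   voxel.
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!connectivity %in% c(6, 26))
    stop_ldctqa("'connectivity' must be 6 or 26", "ldctqa_invalid_input")
  label_components_cpp(mask$voxels, dim(mask$voxels), as.integer(connectivity))
}

#' Retain only the largest connected component
#'
#' Minor segmentation imperfections -- isolated voxels and small satellite
#' blobs -- are removed by keeping the single largest connected component of
#' the mask. When two components tie in size, the one containing the
#' smallest linear voxel index is kept, making the result deterministic.
#'
#' @inheritParams label_components
#' @return A [binary_mask()] containing exactly one connected component.
#' @export
largest_component <- function(mask, connectivity = 26) {
  stopifnot(inherits(mask, "binary_mask"))
  if (is_empty_mask(mask))
    stop_ldctqa("mask is empty; upstream segmentation failed",
                "ldctqa_empty_mask")
  lab <- label_components(mask, connectivity)
  counts <- tabulate(lab[lab > 0L])
  keep <- which.max(counts)  # first maximum = smallest seed index
  binary_mask(lab == keep, mask$spacing)
}

#' Merge the five lung-lobe masks into one lung mask
#'
#' Each lobe is first cleaned by [largest_component()], then the five are
#' unioned. An individual empty lobe raises a warning (a lobe can be
#' genuinely absent, e.g. post-lobectomy) and is skipped; all five empty is
#' an error.
#'
#' @param lobes List of five [binary_mask()] objects on a shared grid.
#' @param connectivity Passed to [largest_component()].
#' @return A [binary_mask()]: the cleaned whole-lung mask.
#' @export
merge_lobes <- function(lobes, connectivity = 26) {
  if (!is.list(lobes) || length(lobes) != 5L)
    stop_ldctqa("'lobes' must be a list of five masks", "ldctqa_invalid_input")
  for (l in lobes) stopifnot(inherits(l, "binary_mask"))
  for (l in lobes[-1]) assert_same_grid(lobes[[1]], l, "lobe masks")
  nonempty <- !vapply(lobes, is_empty_mask, logical(1))
  if (!any(nonempty))
    stop_ldctqa("all five lobe masks are empty", "ldctqa_empty_mask")
  if (!all(nonempty)) {
    nm <- names(lobes) %||% as.character(seq_along(lobes))
    warning(sprintf("empty lobe mask(s): %s",
                    paste(nm[!nonempty], collapse = ", ")), call. = FALSE)
  }
  acc <- array(FALSE, dim = dim(lobes[[1]]$voxels))
  for (l in lobes[nonempty])
    acc <- acc | largest_component(l, connectivity)$voxels
  binary_mask(acc, lobes[[1]]$spacing)
}

#' In-plane binary erosion to a metric margin
#'
#' Erodes the mask slice-by-slice (no coupling along the cranio-caudal axis)
#' so that every retained voxel lies at an in-plane Euclidean distance of at
#' least `margin_mm` from the nearest background voxel of the input. The
#' erosion runs `n = ceiling(margin_mm / min(dx, dy))` iterations of a 3x3
#' structuring element -- the minimal iteration count whose Chebyshev
#' guarantee implies the Euclidean margin in every in-plane direction, at
#' the cost of slight over-erosion. An all-false result is legal; callers
#' decide whether that is an error.
#'
#' @param mask A [binary_mask()].
#' @param margin_mm Non-negative margin in mm; 0 returns the mask unchanged.
#' @return The eroded [binary_mask()].
#' @export
erode_inplane_margin <- function(mask, margin_mm = 3.0) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!is.numeric(margin_mm) || length(margin_mm) != 1L || margin_mm < 0)
    stop_ldctqa("'margin_mm' must be a single non-negative number",
                "ldctqa_invalid_input")
  if (margin_mm == 0) return(mask)
  n_iter <- ceiling(margin_mm / min(mask$spacing[1:2]))
  out <- erode_inplane_cpp(mask$voxels, dim(mask$voxels), as.integer(n_iter))
  binary_mask(out, mask$spacing)
}

# Bounding box of the foreground, as index ranges per axis (NULL if empty).
mask_bbox <- function(voxels) {
  idx <- which(voxels)
  if (length(idx) == 0L) return(NULL)
  d <- dim(voxels)
  co <- arrayInd(idx, d)
  lapply(1:3, function(a) range(co[, a]))
}

#' Block-average a CT volume
#'
#' Downsamples by averaging non-overlapping blocks of `factors` voxels
#' (trailing voxels that do not fill a block are dropped). Used to study the
#' resolution dependence of the raw noise estimate: averaging k independent
#' voxels divides the noise standard deviation by sqrt(k) while multiplying
#' the voxel volume by k, which is exactly the dependence the normalized
#' noise removes.
#'
#' @param vol A [ct_volume()].
#' @param factors Integer length-3 block size, e.g. `c(2, 2, 1)`.
#' @return A [ct_volume()] on the coarser grid.
#' @export
block_average <- function(vol, factors = c(2, 2, 1)) {
  stopifnot(inherits(vol, "ct_volume"))
  factors <- as.integer(factors)
  if (length(factors) != 3L || any(factors < 1L))
    stop_ldctqa("'factors' must be three positive integers",
                "ldctqa_invalid_input")
  arr <- block_reduce(vol$voxels, factors, "mean")
  ct_volume(arr, vol$spacing * factors, acquisition = vol$acquisition,
            orientation = vol$orientation)
}

#' Block-reduce a binary mask conservatively
#'
#' A coarse voxel is foreground only when every fine voxel in its block is
#' foreground, so the reduced mask never includes partial-volume blocks.
#'
#' @param mask A [binary_mask()].
#' @param factors Integer length-3 block size.
#' @return A [binary_mask()] on the coarser grid.
#' @export
block_reduce_mask <- function(mask, factors = c(2, 2, 1)) {
  stopifnot(inherits(mask, "binary_mask"))
  factors <- as.integer(factors)
  arr <- block_reduce(mask$voxels * 1, factors, "all")
  binary_mask(arr, mask$spacing * factors)
}

block_reduce <- function(arr, factors, stat = c("mean", "all")) {
  stat <- match.arg(stat)
  d <- dim(arr)
  nd <- d %/% factors
  if (any(nd < 1L))
    stop_ldctqa("array smaller than one block", "ldctqa_invalid_input")
  arr <- arr[seq_len(nd[1] * factors[1]),
             seq_len(nd[2] * factors[2]),
             seq_len(nd[3] * factors[3]), drop = FALSE]
  # gather the within-block axes first, then reduce columnwise in C
  dim(arr) <- c(factors[1], nd[1], factors[2], nd[2], factors[3], nd[3])
  arr <- aperm(arr, c(1, 3, 5, 2, 4, 6))
  dim(arr) <- c(prod(factors), prod(nd))
  out <- if (stat == "mean") colMeans(arr) else
    colSums(arr != 0) == prod(factors)
  dim(out) <- nd
  out
}
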