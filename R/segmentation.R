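# Adapter between the pipeline and whatever produces the organ masks: an
# external neural segmenter, precomputed NIfTI label files, or phantom
# ground truth. The pipeline itself only ever sees a segmentation_set.

#' Bundle of organ masks on a shared grid
#'
#' @param lobes Named list of five [binary_mask()] objects with names
#'   `right_upper`, `right_middle`, `right_lower`, `left_upper`,
#'   `left_lower`.
#' @param aorta A [binary_mask()] of the aorta (including its wall).
#' @param reference Optional [ct_volume()] whose grid all masks must match.
#' @param backend Identifier of the mask source, recorded in reports.
#' @param backend_version Version string of the mask source, if known.
#' @return An object of class `segmentation_set`.
#' @export
segmentation_set <- function(lobes, aorta, reference = NULL,
                             backend = "precomputed",
                             backend_version = NULL) {
  if (!is.list(lobes) || is.null(names(lobes)) ||
      !setequal(names(lobes), LOBE_LABELS))
    stop_ldctqa(sprintf("'lobes' must be a named list with labels: %s",
                        paste(LOBE_LABELS, collapse = ", ")),
                "ldctqa_invalid_input")
  lobes <- lobes[LOBE_LABELS]
  for (l in lobes) stopifnot(inherits(l, "binary_mask"))
  stopifnot(inherits(aorta, "binary_mask"))
  ref <- reference %||% lobes[[1]]
  for (nm in LOBE_LABELS)
    assert_same_grid(ref, lobes[[nm]], sprintf("volume and lobe '%s'", nm))
  assert_same_grid(ref, aorta, "volume and aorta mask")
  structure(list(lobes = lobes, aorta = aorta, backend = backend,
                 backend_version = backend_version),
            class = "segmentation_set")
}

#' @export
print.segmentation_set <- function(x, ...) {
  cat(sprintf("<segmentation_set> backend: %s%s\n", x$backend,
              if (is.null(x$backend_version)) "" else
                paste0(" (", x$backend_version, ")")))
  for (nm in names(x$lobes))
    cat(sprintf("  %-13s %d voxels\n", nm, mask_count(x$lobes[[nm]])))
  cat(sprintf("  %-13s %d voxels\n", "aorta", mask_count(x$aorta)))
  invisible(x)
}

#' Load organ masks from NIfTI label files
#'
#' Each file must be binary (values 0/1) and on exactly the grid of `vol`;
#' any mismatch is an error -- masks are never resampled, because silent
#' interpolation would corrupt both the coverage boundary slices and the
#' partial-volume behaviour of the noise mask.
#'
#' @param paths Named character vector or list mapping the labels
#'   `right_upper`, `right_middle`, `right_lower`, `left_upper`,
#'   `left_lower`, `aorta` to file paths.
#' @param vol The [ct_volume()] the masks belong to.
#' @return A [segmentation_set()].
#' @export
load_masks <- function(paths, vol) {
  stopifnot(inherits(vol, "ct_volume"))
  paths <- as.list(paths)
  wanted <- c(LOBE_LABELS, "aorta")
  missing_labels <- setdiff(wanted, names(paths))
  if (length(missing_labels) > 0)
    stop_ldctqa(sprintf("missing mask label(s): %s",
                        paste(missing_labels, collapse = ", ")),
                "ldctqa_missing_input")
  masks <- lapply(wanted, function(nm) {
    p <- paths[[nm]]
    if (!file.exists(p))
      stop_ldctqa(sprintf("mask file for '%s' not found: %s", nm, p),
                  "ldctqa_missing_input")
    read_mask(p)
  })
  names(masks) <- wanted
  segmentation_set(masks[LOBE_LABELS], masks$aorta, reference = vol,
                   backend = "precomputed")
}

#' Obtain organ masks for a volume via a named backend
#'
#' Dispatches to one of three mask sources:
#' \describe{
#'   \item{`"precomputed"`}{reads NIfTI label files via [load_masks()];
#'     supply `masks`.}
#'   \item{`"phantom-truth"`}{uses the ground-truth masks of a generated
#'     phantom; supply `truth`.}
#'   \item{`"totalsegmentator"`}{placeholder for an external neural
#'     segmenter; not bundled, so this errors with instructions to run the
#'     tool externally and pass its output as precomputed masks.}
#' }
#'
#' @param vol A [ct_volume()].
#' @param backend One of `"precomputed"`, `"phantom-truth"`,
#'   `"totalsegmentator"`.
#' @param masks Named paths for the `"precomputed"` backend.
#' @param truth A `phantom_truth` object for the `"phantom-truth"` backend.
#' @return A [segmentation_set()].
#' @export
segment <- function(vol, backend = c("precomputed", "phantom-truth",
                                     "totalsegmentator"),
                    masks = NULL, truth = NULL) {
  backend <- match.arg(backend)
  switch(backend,
    "precomputed" = {
      if (is.null(masks))
        stop_ldctqa("backend 'precomputed' requires 'masks' paths",
                    "ldctqa_invalid_input")
      load_masks(masks, vol)
    },
    "phantom-truth" = {
      if (!inherits(truth, "phantom_truth"))
        stop_ldctqa("backend 'phantom-truth' requires a phantom_truth object",
                    "ldctqa_invalid_input")
      segmentation_set(truth$lobes, truth$aorta, reference = vol,
                       backend = "phantom-truth",
                       backend_version = as.character(packageVersion("ldctqa")))
    },
    "totalsegmentator" =
      stop_ldctqa(paste("the external neural segmenter is not bundled with",
                        "this package; run it separately and supply its",
                        "NIfTI masks via backend = 'precomputed'"),
                  "ldctqa_backend_unavailable")
  )
}
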