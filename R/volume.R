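#' Acquisition metadata for a CT volume
#'
#' Holds the exposure-related parameters of a CT acquisition that the noise
#' analysis can relate to: the tube current-time product (mAs), the
#' dimensionless helical pitch, and the tube voltage (kVp). All fields are
#' optional because NIfTI files and many anonymized DICOM exports lack them.
#'
#' @param mas Tube current-time product in mAs, or `NULL`.
#' @param pitch Helical pitch (dimensionless), or `NULL`.
#' @param kvp Tube voltage in kVp, or `NULL`.
#' @param source_format `"NIfTI"`, `"DICOM-series"`, or `"synthetic"`.
#' @param rescale_present Logical; `FALSE` when a DICOM series lacked rescale
#'   slope/intercept tags, so stored values could not be calibrated to HU.
#' @return An object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(mas = NULL, pitch = NULL, kvp = NULL,
                             source_format = NA_character_,
                             rescale_present = TRUE) {
  if (!is.null(mas) && (!is.numeric(mas) || mas <= 0))
    stop_ldctqa("'mas' must be a positive number", "ldctqa_invalid_input")
  if (!is.null(pitch) && (!is.numeric(pitch) || pitch <= 0))
    stop_ldctqa("'pitch' must be a positive number", "ldctqa_invalid_input")
  structure(list(mas = mas, pitch = pitch, kvp = kvp,
                 source_format = source_format,
                 rescale_present = isTRUE(rescale_present)),
            class = "acquisition_meta")
}

#' Construct a CT volume in canonical orientation
#'
#' A `ct_volume` is a 3D grid of Hounsfield units together with its voxel
#' spacing. The package works exclusively in a canonical orientation: axis 1
#' increases toward the patient's left, axis 2 toward posterior, and axis 3
#' toward cranial, so slice 1 is the caudal-most slice. [load_volume()]
#' reorients data on input; construct directly only for already-canonical
#' arrays (e.g. phantoms).
#'
#' @param voxels 3D numeric array of HU values.
#' @param spacing Numeric length-3 vector `(dx, dy, dz)` in mm.
#' @param acquisition An [acquisition_meta()] object.
#' @param slice_positions Optional numeric vector of the original slice
#'   positions (mm) along the cranio-caudal axis, caudal to cranial; used by
#'   [check_integrity()] to test spacing plausibility.
#' @param orientation Orientation marker; `"LPS"` (canonical) unless the
#'   source file carried no usable direction metadata.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, acquisition = acquisition_meta(),
                      slice_positions = NULL,
                      orientation = CANONICAL_ORIENTATION) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L || length(voxels) == 0L)
    stop_ldctqa("'voxels' must be a non-empty 3D array", "ldctqa_invalid_input")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_ldctqa("'spacing' must be three positive numbers (mm)",
                "ldctqa_invalid_input")
  if (!is.null(slice_positions) &&
      length(slice_positions) != dim(voxels)[3])
    stop_ldctqa("'slice_positions' must have one entry per slice",
                "ldctqa_invalid_input")
  structure(list(voxels = voxels, spacing = spacing,
                 orientation = orientation, acquisition = acquisition,
                 slice_positions = slice_positions),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, orientation %s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$orientation))
  cat(sprintf("  HU range: [%.1f, %.1f]; source: %s\n",
              min(x$voxels), max(x$voxels),
              x$acquisition$source_format))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

nifti_spacing <- function(img) {
  x <- RNifti::xform(img)
  sp <- sqrt(colSums(x[1:3, 1:3, drop = FALSE]^2))
  if (any(!is.finite(sp)) || any(sp <= 0)) sp <- abs(RNifti::pixdim(img))[1:3]
  as.numeric(sp)
}

load_nifti_volume <- function(path) {
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
    stop_ldctqa(sprintf("corrupt or unreadable NIfTI file '%s': %s",
                        path, conditionMessage(e)), "ldctqa_corrupt_input"))
  if (length(dim(img)) > 3L)
    stop_ldctqa(sprintf("'%s' is not a 3D volume", path),
                "ldctqa_corrupt_input")
  orient <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  resolved <- FALSE
  if (!is.na(orient)) {
    reoriented <- withCallingHandlers(
      tryCatch({ RNifti::orientation(img) <- CANONICAL_ORIENTATION; TRUE },
               error = function(e) FALSE),
      warning = function(w) invokeRestart("muffleWarning"))
    resolved <- reoriented &&
      identical(RNifti::orientation(img), CANONICAL_ORIENTATION)
  }
  vox <- as.array(img)
  attributes(vox) <- list(dim = dim(vox))
  if (length(dim(vox)) == 2L) dim(vox) <- c(dim(vox), 1L)
  sp <- nifti_spacing(img)
  sp[!is.finite(sp) | sp <= 0] <- 1
  ct_volume(vox, sp,
            acquisition = acquisition_meta(source_format = "NIfTI"),
            orientation = if (resolved) CANONICAL_ORIENTATION else "unknown")
}

#' Load a CT volume from NIfTI or a DICOM series
#'
#' Reads a chest CT volume, calibrates voxel values to HU (DICOM rescale
#' slope/intercept), and reorients the array into the package's canonical
#' orientation (axis 1 left, axis 2 posterior, axis 3 cranial). For DICOM
#' series the cranio-caudal voxel spacing `dz` is derived from the modal
#' inter-slice distance of the slice positions, not from the slice-thickness
#' tag; the thickness tag is used only when positions are absent.
#'
#' @param path Path to a `.nii`/`.nii.gz` file or to a directory containing a
#'   single DICOM series.
#' @param format_hint `"auto"` (default, decided by path type and extension),
#'   `"nifti"`, or `"dicom"`.
#' @return A [ct_volume()].
#' @seealso [check_integrity()], [write_volume()]
#' @export
load_volume <- function(path, format_hint = c("auto", "nifti", "dicom")) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path))
    stop_ldctqa(sprintf("input '%s' does not exist", path),
                "ldctqa_missing_input")
  fmt <- format_hint
  if (fmt == "auto")
    fmt <- if (dir.exists(path)) "dicom" else "nifti"
  if (fmt == "nifti") load_nifti_volume(path) else read_dicom_series(path)
}

#' Write a CT volume to NIfTI
#'
#' The canonical orientation is recorded in the qform so that a round-trip
#' through [load_volume()] preserves voxels and spacing.
#'
#' @param vol A [ct_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  img <- RNifti::asNifti(vol$voxels)
  sp <- vol$spacing
  RNifti::qform(img) <- structure(diag(c(-sp[1], -sp[2], sp[3], 1)), code = 2L)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

integrity_flag <- function(code, detail) {
  code <- match.arg(code, c("HU_IMPLAUSIBLE", "SPACING_INCONSISTENT",
                            "ORIENTATION_UNRESOLVED", "RESCALE_MISSING"))
  structure(list(code = code, detail = detail), class = "integrity_flag")
}

#' @export
print.integrity_flag <- function(x, ...) {
  cat(sprintf("[%s] %s\n", x$code, x$detail))
  invisible(x)
}

modal_value <- function(x, digits = 3) {
  r <- round(x, digits)
  tab <- table(r)
  as.numeric(names(tab)[which.max(tab)])
}

#' Pre-flight integrity checks for a loaded volume
#'
#' Pure checks run before any analysis, catching the failure modes that slip
#' through format conversion: implausible HU values from corrupted rescale
#' metadata, irregular inter-slice spacing, unresolvable orientation, and
#' missing rescale tags. The volume is never modified.
#'
#' Flags raised:
#' \describe{
#'   \item{`HU_IMPLAUSIBLE`}{minimum voxel value below `hu_floor`.}
#'   \item{`SPACING_INCONSISTENT`}{an inter-slice distance deviating from the
#'     modal distance by more than 10%.}
#'   \item{`ORIENTATION_UNRESOLVED`}{the source file carried no usable
#'     direction metadata, so the canonical reorientation is unverified.}
#'   \item{`RESCALE_MISSING`}{DICOM rescale slope/intercept absent; voxel
#'     values are stored values, not HU.}
#' }
#'
#' @param vol A [ct_volume()].
#' @param hu_floor HU threshold below which values are considered corrupt;
#'   defaults to -19000.
#' @return A (possibly empty) list of `integrity_flag` objects.
#' @export
check_integrity <- function(vol, hu_floor = -19000) {
  stopifnot(inherits(vol, "ct_volume"))
  flags <- list()
  mn <- min(vol$voxels)
  if (mn < hu_floor)
    flags <- c(flags, list(integrity_flag("HU_IMPLAUSIBLE",
      sprintf("minimum HU %.0f below plausibility floor %.0f", mn, hu_floor))))
  if (!is.null(vol$slice_positions) && length(vol$slice_positions) >= 3) {
    d <- diff(sort(vol$slice_positions))
    dmode <- modal_value(d)
    if (dmode > 0 && any(abs(d - dmode) / dmode > 0.10))
      flags <- c(flags, list(integrity_flag("SPACING_INCONSISTENT",
        sprintf("inter-slice distances range %.3f-%.3f mm vs modal %.3f mm",
                min(d), max(d), dmode))))
  }
  if (!identical(vol$orientation, CANONICAL_ORIENTATION))
    flags <- c(flags, list(integrity_flag("ORIENTATION_UNRESOLVED",
      "volume orientation could not be resolved from file metadata")))
  if (!isTRUE(vol$acquisition$rescale_present))
    flags <- c(flags, list(integrity_flag("RESCALE_MISSING",
      "rescale slope/intercept missing; voxel values are uncalibrated")))
  flags
}
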