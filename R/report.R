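# Per-scan orchestration: run the full pipeline with soft-fail semantics,
# serialize the QA report to JSON, flag exceptions against configured
# thresholds, and render an optional one-page PDF.

#' Pipeline configuration
#'
#' Bundles every tunable parameter of the per-scan pipeline so a report's
#' configuration snapshot fully determines a re-run. Thresholds drive
#' [flag_exceptions()] only; the measured distances themselves always use
#' the zero-margin convention. Sites should tune thresholds to their own
#' protocols.
#'
#' @param margin_mm In-plane erosion margin for the aortic lumen (mm).
#' @param hu_floor HU plausibility floor for [check_integrity()].
#' @param min_voxels Minimum lumen size for [compute_noise()].
#' @param connectivity Component connectivity (26 or 6).
#' @param max_caudal_overscan_mm,max_cranial_overscan_mm,max_sigma_norm
#'   Review thresholds for [flag_exceptions()].
#' @return A list of class `qa_config`.
#' @export
qa_config <- function(margin_mm = 3.0, hu_floor = -19000, min_voxels = 100,
                      connectivity = 26, max_caudal_overscan_mm = 50,
                      max_cranial_overscan_mm = 50, max_sigma_norm = 80) {
  structure(list(margin_mm = margin_mm, hu_floor = hu_floor,
                 min_voxels = min_voxels, connectivity = connectivity,
                 thresholds = list(
                   max_caudal_overscan_mm = max_caudal_overscan_mm,
                   max_cranial_overscan_mm = max_cranial_overscan_mm,
                   max_sigma_norm = max_sigma_norm)),
            class = "qa_config")
}

#' Read a configuration file
#'
#' Plain `key = value` text format, one pair per line; `#` starts a
#' comment. Unknown keys are an error. Keys match the arguments of
#' [qa_config()].
#'
#' @param path Path to the configuration file.
#' @return A `qa_config` object.
#' @export
read_qa_config <- function(path) {
  if (!file.exists(path))
    stop_ldctqa(sprintf("config file '%s' not found", path),
                "ldctqa_missing_input")
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop_ldctqa(sprintf("malformed config line: '%s'", ln),
                  "ldctqa_invalid_input")
    key <- trimws(kv[1])
    if (!key %in% names(formals(qa_config)))
      stop_ldctqa(sprintf("unknown config key: '%s'", key),
                  "ldctqa_invalid_input")
    args[[key]] <- as.numeric(trimws(kv[2]))
  }
  do.call(qa_config, args)
}

#' Run the full per-scan QA pipeline
#'
#' Executes load -> integrity check -> masks -> lobe merge -> coverage ->
#' lumen extraction -> noise, producing a `qa_report`. An unreadable volume
#' is a hard error; failures in later stages are captured in the report's
#' `errors` field instead of aborting, so batch runs survive individual
#' problem scans and still report the stages that succeeded.
#'
#' @param vol_path Path to the volume (NIfTI file or DICOM directory), or a
#'   [ct_volume()] directly.
#' @param masks Named mask paths for the precomputed backend (see
#'   [load_masks()]), or a [segmentation_set()].
#' @param backend Backend identifier for [segment()] when `masks` is paths.
#' @param truth Optional `phantom_truth` for the `"phantom-truth"` backend.
#' @param config A [qa_config()].
#' @param scan_id Identifier recorded in the report; defaults to the file
#'   name.
#' @return An object of class `qa_report`.
#' @export
run_scan <- function(vol_path, masks = NULL, backend = "precomputed",
                     truth = NULL, config = qa_config(), scan_id = NULL) {
  stopifnot(inherits(config, "qa_config"))
  errors <- list()
  soft <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      errors[[stage]] <<- conditionMessage(e)
      NULL
    })
  }

  if (inherits(vol_path, "ct_volume")) {
    vol <- vol_path
    scan_id <- scan_id %||% "in-memory"
  } else {
    vol <- load_volume(vol_path)  # hard error on failure
    scan_id <- scan_id %||% basename(vol_path)
  }

  integrity <- check_integrity(vol, hu_floor = config$hu_floor)

  seg <- if (inherits(masks, "segmentation_set")) masks else
    soft("segmentation", segment(vol, backend = backend, masks = masks,
                                 truth = truth))

  coverage <- NULL
  lung <- NULL
  if (!is.null(seg)) {
    lung <- soft("merge_lobes",
                 merge_lobes(seg$lobes, connectivity = config$connectivity))
    if (!is.null(lung))
      coverage <- soft("coverage", measure_coverage(lung))
  }

  lumen <- NULL
  noise <- NULL
  if (!is.null(seg) && !is.null(lung)) {
    lumen <- soft("lumen_extraction",
                  extract_lumen(seg$aorta, lung, margin_mm = config$margin_mm,
                                connectivity = config$connectivity))
    if (!is.null(lumen))
      noise <- soft("noise", compute_noise(vol, lumen$lumen,
                                           min_voxels = config$min_voxels))
  }

  structure(list(
    scan_id = scan_id,
    integrity = lapply(integrity, unclass),
    coverage = if (!is.null(coverage)) unclass(coverage),
    lumen = if (!is.null(lumen)) list(
      n_voxels = lumen$n_voxels,
      split_found = lumen$split_found,
      n_slices_removed_for_split = lumen$n_slices_removed_for_split,
      provenance = lumen$provenance),
    noise = if (!is.null(noise)) unclass(noise) else
      list(available = FALSE,
           reason = errors[["noise"]] %||% errors[["lumen_extraction"]] %||%
             "lumen mask unavailable"),
    backend = if (!is.null(seg)) seg$backend else backend,
    backend_version = if (!is.null(seg)) seg$backend_version,
    config = unclass(config),
    errors = errors,
    tool_version = as.character(packageVersion("ldctqa")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "qa_report")
}

#' @export
print.qa_report <- function(x, ...) {
  cat(sprintf("<qa_report> %s (backend: %s)\n", x$scan_id, x$backend))
  if (length(x$integrity))
    cat("  integrity flags:",
        paste(vapply(x$integrity, `[[`, character(1), "code"),
              collapse = ", "), "\n")
  if (!is.null(x$coverage)) {
    cv <- x$coverage
    cat(sprintf("  coverage: caudal %s, cranial %s\n",
                if (cv$underscan_caudal) "UNDERSCAN" else
                  sprintf("%.1f mm", cv$caudal_overscan_mm),
                if (cv$underscan_cranial) "UNDERSCAN" else
                  sprintf("%.1f mm", cv$cranial_overscan_mm)))
  }
  if (!is.null(x$noise$sigma_norm))
    cat(sprintf("  noise: sigma_norm %.2f HU over %d voxels\n",
                x$noise$sigma_norm, x$noise$n_voxels))
  else
    cat(sprintf("  noise: unavailable (%s)\n", x$noise$reason))
  if (length(x$errors))
    cat("  stage errors:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

#' Write a QA report to JSON
#'
#' Serialization is lossless for every field, so
#' `read_report(write_report(r, f))` reproduces `r`.
#'
#' @param report A `qa_report`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "qa_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a QA report from JSON
#'
#' @param path Path to a report written by [write_report()].
#' @return A `qa_report`.
#' @export
read_report <- function(path) {
  if (!file.exists(path))
    stop_ldctqa(sprintf("report '%s' not found", path), "ldctqa_missing_input")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  structure(obj, class = "qa_report")
}

#' Decide whether a scan needs human review
#'
#' Returns `"review"` when any underscan flag or integrity flag is set, an
#' overscan distance exceeds its threshold, or the normalized noise exceeds
#' its threshold; `"pass"` otherwise. A missing noise value also triggers
#' review, since it means the noise stage could not complete.
#'
#' @param report A `qa_report`.
#' @param thresholds Threshold list, defaulting to the thresholds recorded
#'   in the report's configuration snapshot.
#' @return `"pass"` or `"review"`.
#' @export
flag_exceptions <- function(report, thresholds = NULL) {
  stopifnot(inherits(report, "qa_report"))
  th <- thresholds %||% report$config$thresholds
  cv <- report$coverage
  review <- length(report$integrity) > 0 || length(report$errors) > 0 ||
    is.null(cv) ||
    isTRUE(as.logical(cv$underscan_caudal)) ||
    isTRUE(as.logical(cv$underscan_cranial)) ||
    cv$caudal_overscan_mm > th$max_caudal_overscan_mm ||
    cv$cranial_overscan_mm > th$max_cranial_overscan_mm ||
    is.null(report$noise$sigma_norm) ||
    report$noise$sigma_norm > th$max_sigma_norm
  if (review) "review" else "pass"
}

#' Render a one-page PDF summary of a QA report
#'
#' A minimal human-readable rendering of the key values and flags, with
#' mid-volume thumbnails when the volume and lung mask are supplied.
#'
#' @param report A `qa_report`.
#' @param out_path Output `.pdf` path.
#' @param volume Optional [ct_volume()] for thumbnails.
#' @param lung Optional lung [binary_mask()] overlaid on the thumbnail.
#' @return `out_path`, invisibly.
#' @export
render_pdf <- function(report, out_path, volume = NULL, lung = NULL) {
  stopifnot(inherits(report, "qa_report"))
  grDevices::pdf(out_path, width = 8.27, height = 11.69)  # A4 portrait
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(1, 1, 2, 1))
  has_thumb <- !is.null(volume)
  if (has_thumb) graphics::layout(matrix(c(1, 1, 2, 3), 2, 2, byrow = TRUE),
                                  heights = c(1.2, 1))
  graphics::plot.new()
  graphics::title(main = sprintf("LDCT quality assurance report - %s",
                                 report$scan_id))
  lines <- c(
    sprintf("Generated: %s  (tool %s, backend %s)", report$timestamp,
            report$tool_version, report$backend),
    "",
    if (length(report$integrity))
      paste("Integrity flags:", paste(vapply(report$integrity, `[[`,
            character(1), "code"), collapse = ", "))
    else "Integrity flags: none",
    if (!is.null(report$coverage)) c(
      sprintf("Caudal:  %s", if (isTRUE(as.logical(report$coverage$underscan_caudal)))
        "UNDERSCAN (lung reaches caudal edge)" else
        sprintf("overscan %.2f mm", report$coverage$caudal_overscan_mm)),
      sprintf("Cranial: %s", if (isTRUE(as.logical(report$coverage$underscan_cranial)))
        "UNDERSCAN (lung reaches cranial edge)" else
        sprintf("overscan %.2f mm", report$coverage$cranial_overscan_mm)),
      sprintf("Slices without lung: %.2f%%",
              100 * report$coverage$fraction_nonlung_slices))
    else "Coverage: unavailable",
    if (!is.null(report$noise$sigma_norm)) c(
      sprintf("Noise: sigma_raw %.2f HU, sigma_norm %.2f HU (v_raw %.3f mm^3, n = %d)",
              report$noise$sigma_raw, report$noise$sigma_norm,
              report$noise$v_raw, report$noise$n_voxels),
      sprintf("Lumen mean HU: %.1f", report$noise$mu_raw))
    else sprintf("Noise: unavailable (%s)", report$noise$reason),
    "",
    sprintf("Disposition: %s", toupper(flag_exceptions(report))),
    if (length(report$errors))
      sprintf("Stage errors: %s", paste(names(report$errors), collapse = ", "))
  )
  graphics::text(0, seq(0.95, by = -0.055, length.out = length(lines)),
                 lines, adj = c(0, 1), cex = 0.9, family = "mono")
  if (has_thumb) {
    mid <- dim(volume$voxels)[3] %/% 2L
    sl <- volume$voxels[, , mid]
    graphics::image(sl, col = grDevices::gray.colors(128), axes = FALSE,
                    main = sprintf("axial slice %d", mid), useRaster = TRUE)
    cor <- dim(volume$voxels)[2] %/% 2L
    slc <- volume$voxels[, cor, ]
    graphics::image(slc, col = grDevices::gray.colors(128), axes = FALSE,
                    main = "coronal mid-plane", useRaster = TRUE)
    if (!is.null(lung)) {
      lsl <- lung$voxels[, cor, ]
      if (any(lsl))
        graphics::contour(seq(0, 1, length.out = nrow(lsl)),
                          seq(0, 1, length.out = ncol(lsl)),
                          lsl * 1, levels = 0.5, add = TRUE, col = "red",
                          drawlabels = FALSE)
    }
  }
  invisible(out_path)
}
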