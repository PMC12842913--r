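# Minimal reader for uncompressed single-frame CT DICOM series (explicit or
# implicit VR, little endian). No R DICOM package is available in the
# dependency set, and the subset of the format needed here -- a handful of
# numeric tags plus 16-bit pixel data -- is small enough to parse directly.

dcm_u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}

dcm_u32 <- function(raw, pos) {
  as.numeric(raw[pos]) + 256 * as.numeric(raw[pos + 1L]) +
    65536 * as.numeric(raw[pos + 2L]) + 16777216 * as.numeric(raw[pos + 3L])
}

dcm_string <- function(val) {
  s <- rawToChar(val[val != as.raw(0)])
  trimws(s)
}

dcm_numbers <- function(val) {
  as.numeric(strsplit(dcm_string(val), "\\\\")[[1]])
}

# VRs whose explicit encoding uses a 2-byte reserved field + 4-byte length
DCM_LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

dcm_wanted_tags <- c(
  series_uid   = "0020,000E",
  position     = "0020,0032",
  orientation  = "0020,0037",
  pixel_spacing = "0028,0030",
  rows         = "0028,0010",
  cols         = "0028,0011",
  bits_alloc   = "0028,0100",
  pixel_rep    = "0028,0103",
  intercept    = "0028,1052",
  slope        = "0028,1053",
  thickness    = "0018,0050",
  exposure_mas = "0018,1152",
  pitch        = "0018,9311",
  kvp          = "0018,0060",
  pixel_data   = "7FE0,0010"
)

parse_dicom_file <- function(path) {
  sz <- file.size(path)
  if (is.na(sz) || sz < 140)
    stop_ldctqa(sprintf("'%s' is too small to be a DICOM file", path),
                "ldctqa_corrupt_input")
  raw <- readBin(path, "raw", n = sz)
  if (rawToChar(raw[129:132]) != "DICM")
    stop_ldctqa(sprintf("'%s' lacks the DICM magic marker", path),
                "ldctqa_corrupt_input")
  n <- length(raw)
  pos <- 133L
  explicit_meta <- TRUE
  transfer_syntax <- NULL
  elems <- list()

  read_element <- function(pos, explicit) {
    if (pos + 7L > n + 1L) return(NULL)
    group <- dcm_u16(raw, pos)
    elem <- dcm_u16(raw, pos + 2L)
    pos <- pos + 4L
    if (explicit) {
      vr <- rawToChar(raw[pos:(pos + 1L)])
      if (vr %in% DCM_LONG_VRS) {
        len <- dcm_u32(raw, pos + 4L)
        pos <- pos + 8L
      } else {
        len <- dcm_u16(raw, pos + 2L)
        pos <- pos + 4L
      }
    } else {
      vr <- NA_character_
      len <- dcm_u32(raw, pos)
      pos <- pos + 4L
    }
    if (len == 4294967295)  # undefined length (sequences) unsupported
      stop_ldctqa(sprintf("'%s': undefined-length elements are not supported",
                          path), "ldctqa_corrupt_input")
    if (pos + len - 1L > n)
      stop_ldctqa(sprintf("'%s': truncated DICOM element (%04X,%04X)",
                          path, group, elem), "ldctqa_corrupt_input")
    value <- if (len > 0) raw[pos:(pos + len - 1L)] else raw(0)
    list(group = group, elem = elem, vr = vr, value = value,
         next_pos = pos + as.integer(len))
  }

  # file meta group (0002,xxxx) is always explicit VR little endian
  repeat {
    if (pos + 7L > n + 1L) break
    if (dcm_u16(raw, pos) != 2L) break
    el <- read_element(pos, TRUE)
    if (is.null(el)) break
    if (el$elem == 0x0010) transfer_syntax <- dcm_string(el$value)
    pos <- el$next_pos
  }
  explicit <- TRUE
  if (!is.null(transfer_syntax)) {
    if (transfer_syntax == "1.2.840.10008.1.2") {
      explicit <- FALSE
    } else if (transfer_syntax != "1.2.840.10008.1.2.1") {
      stop_ldctqa(sprintf("'%s': unsupported transfer syntax %s",
                          path, transfer_syntax), "ldctqa_corrupt_input")
    }
  }

  repeat {
    el <- tryCatch(read_element(pos, explicit), error = function(e) stop(e))
    if (is.null(el)) break
    key <- sprintf("%04X,%04X", el$group, el$elem)
    if (key %in% dcm_wanted_tags) elems[[key]] <- el
    pos <- el$next_pos
    if (el$group == 0x7FE0 && el$elem == 0x0010) break
  }

  get <- function(name) elems[[dcm_wanted_tags[[name]]]]
  need <- function(name) {
    el <- get(name)
    if (is.null(el))
      stop_ldctqa(sprintf("'%s': required DICOM tag %s (%s) missing",
                          path, dcm_wanted_tags[[name]], name),
                  "ldctqa_corrupt_input")
    el
  }

  rows <- dcm_u16(need("rows")$value, 1L)
  cols <- dcm_u16(need("cols")$value, 1L)
  bits <- if (!is.null(get("bits_alloc"))) dcm_u16(get("bits_alloc")$value, 1L) else 16L
  if (bits != 16L)
    stop_ldctqa(sprintf("'%s': only 16-bit pixel data is supported", path),
                "ldctqa_corrupt_input")
  pixel_rep <- if (!is.null(get("pixel_rep"))) dcm_u16(get("pixel_rep")$value, 1L) else 0L
  pd <- need("pixel_data")$value
  if (length(pd) < 2L * rows * cols)
    stop_ldctqa(sprintf("'%s': pixel data shorter than Rows x Columns", path),
                "ldctqa_corrupt_input")
  stored <- readBin(pd, "integer", n = rows * cols, size = 2L,
                    signed = pixel_rep == 1L, endian = "little")
  # pixel order is row-major (row 1 left to right first), so filling a
  # matrix with nrow = cols yields [column, row] indexing
  frame <- matrix(as.double(stored), nrow = cols, ncol = rows)

  slope_el <- get("slope"); intercept_el <- get("intercept")
  rescale_present <- !is.null(slope_el) && !is.null(intercept_el)
  slope <- if (rescale_present) dcm_numbers(slope_el$value)[1] else 1
  intercept <- if (rescale_present) dcm_numbers(intercept_el$value)[1] else 0
  frame <- frame * slope + intercept

  orientation <- dcm_numbers(need("orientation")$value)
  position <- dcm_numbers(need("position")$value)
  if (length(orientation) != 6L || length(position) != 3L)
    stop_ldctqa(sprintf("'%s': malformed orientation/position tags", path),
                "ldctqa_corrupt_input")
  ps <- dcm_numbers(need("pixel_spacing")$value)  # (row spacing, col spacing)

  list(frame = frame,
       series_uid = dcm_string(need("series_uid")$value),
       row_dir = orientation[1:3], col_dir = orientation[4:6],
       position = position,
       spacing_inplane = c(ps[2], ps[1]),  # (along columns, along rows)
       thickness = if (!is.null(get("thickness"))) dcm_numbers(get("thickness")$value)[1] else NA_real_,
       mas = if (!is.null(get("exposure_mas"))) dcm_numbers(get("exposure_mas")$value)[1] else NULL,
       pitch = if (!is.null(get("pitch"))) readBin(get("pitch")$value, "double", 1, endian = "little") else NULL,
       kvp = if (!is.null(get("kvp"))) dcm_numbers(get("kvp")$value)[1] else NULL,
       rescale_present = rescale_present)
}

# Reorient an axis-aligned [col, row, slice] stack (direction matrix `dirs`,
# columns = patient-space LPS direction of each array axis) into the
# canonical LPS array layout.
reorient_axis_aligned <- function(arr, dirs, spacing, positions_z) {
  perm <- integer(3)
  flip <- logical(3)
  for (target in 1:3) {
    hit <- which(abs(abs(dirs[target, ]) - 1) < 1e-3)
    if (length(hit) != 1L)
      stop_ldctqa("oblique DICOM orientations are not supported",
                  "ldctqa_corrupt_input")
    perm[target] <- hit
    flip[target] <- dirs[target, hit] < 0
  }
  if (anyDuplicated(perm))
    stop_ldctqa("degenerate DICOM orientation matrix", "ldctqa_corrupt_input")
  arr <- aperm(arr, perm)
  if (flip[1]) arr <- arr[dim(arr)[1]:1, , , drop = FALSE]
  if (flip[2]) arr <- arr[, dim(arr)[2]:1, , drop = FALSE]
  if (flip[3]) arr <- arr[, , dim(arr)[3]:1, drop = FALSE]
  sp <- spacing[perm]
  pos_z <- NULL
  if (perm[3] == 3L) {
    pos_z <- if (flip[3]) rev(-positions_z) else positions_z
  }
  list(arr = arr, spacing = sp, positions_z = pos_z)
}

read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L)
    stop_ldctqa(sprintf("no files found in DICOM directory '%s'", dir),
                "ldctqa_missing_input")
  slices <- lapply(sort(files), parse_dicom_file)

  uids <- vapply(slices, `[[`, character(1), "series_uid")
  if (length(unique(uids)) != 1L)
    stop_ldctqa("directory contains more than one DICOM series",
                "ldctqa_corrupt_input")
  dirs_ok <- vapply(slices, function(s)
    max(abs(s$row_dir - slices[[1]]$row_dir),
        abs(s$col_dir - slices[[1]]$col_dir)) < 1e-4, logical(1))
  if (!all(dirs_ok))
    stop_ldctqa("mixed image orientations within the DICOM series",
                "ldctqa_corrupt_input")

  row_dir <- slices[[1]]$row_dir
  col_dir <- slices[[1]]$col_dir
  normal <- c(row_dir[2] * col_dir[3] - row_dir[3] * col_dir[2],
              row_dir[3] * col_dir[1] - row_dir[1] * col_dir[3],
              row_dir[1] * col_dir[2] - row_dir[2] * col_dir[1])
  proj <- vapply(slices, function(s) sum(s$position * normal), numeric(1))
  ord <- order(proj)
  slices <- slices[ord]
  proj <- proj[ord]

  shp <- dim(slices[[1]]$frame)
  arr <- array(0, dim = c(shp[1], shp[2], length(slices)))
  for (i in seq_along(slices)) {
    if (!identical(dim(slices[[i]]$frame), shp))
      stop_ldctqa("slices in the series differ in matrix size",
                  "ldctqa_corrupt_input")
    arr[, , i] <- slices[[i]]$frame
  }

  dz <- if (length(proj) >= 2) modal_value(diff(proj)) else
    (slices[[1]]$thickness %||% 1)
  if (!is.finite(dz) || dz <= 0) dz <- slices[[1]]$thickness %||% 1
  spacing <- c(slices[[1]]$spacing_inplane, dz)

  dirs <- cbind(row_dir, col_dir, normal)  # columns = array-axis directions
  canon <- reorient_axis_aligned(arr, dirs, spacing, proj)

  rescale_present <- all(vapply(slices, `[[`, logical(1), "rescale_present"))
  ct_volume(canon$arr, canon$spacing,
            acquisition = acquisition_meta(
              mas = slices[[1]]$mas, pitch = slices[[1]]$pitch,
              kvp = slices[[1]]$kvp, source_format = "DICOM-series",
              rescale_present = rescale_present),
            slice_positions = canon$positions_z)
}
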