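# Writer for tiny synthetic DICOM CT series (explicit VR little endian,
# uncompressed), used to exercise the series reader. Frames are HU
# matrices indexed [column, row]; stored values use slope 1 / intercept
# -1024 with unsigned 16-bit pixels.

raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
raw_u32 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

dcm_element <- function(group, elem, vr, value) {
  if (is.character(value)) {
    value <- charToRaw(value)
    if (length(value) %% 2 == 1)
      value <- c(value, if (vr == "UI") as.raw(0) else charToRaw(" "))
  }
  stopifnot(is.raw(value), length(value) %% 2 == 0)
  long <- vr %in% c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")
  c(raw_u16(group), raw_u16(elem), charToRaw(vr),
    if (long) c(as.raw(c(0, 0)), raw_u32(length(value)))
    else raw_u16(length(value)),
    value)
}

ds <- function(...) paste(vapply(list(...), function(x)
  format(x, trim = TRUE, scientific = FALSE), character(1)), collapse = "\\")

write_test_dicom_file <- function(path, frame_hu, z_pos,
                                  pixel_spacing = c(1, 1),
                                  series_uid = "1.2.826.0.1.3680043.9999.1",
                                  orientation = c(1, 0, 0, 0, 1, 0),
                                  thickness = NULL,
                                  rescale = TRUE,
                                  origin_xy = c(0, 0)) {
  ncols <- nrow(frame_hu)  # [column, row] indexing
  nrows <- ncol(frame_hu)
  stored <- as.integer(round(as.vector(frame_hu) + 1024))
  stopifnot(all(stored >= 0), all(stored <= 65535))

  meta_body <- c(
    dcm_element(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    dcm_element(0x0002, 0x0003, "UI", paste0(series_uid, ".", round(z_pos * 100))),
    dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", raw_u32(length(meta_body))),
            meta_body)

  body <- c(
    dcm_element(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    dcm_element(0x0008, 0x0018, "UI", paste0(series_uid, ".", round(z_pos * 100))),
    if (!is.null(thickness)) dcm_element(0x0018, 0x0050, "DS", ds(thickness)),
    dcm_element(0x0020, 0x000D, "UI", paste0(series_uid, ".0")),
    dcm_element(0x0020, 0x000E, "UI", series_uid),
    dcm_element(0x0020, 0x0032, "DS", ds(origin_xy[1], origin_xy[2], z_pos)),
    dcm_element(0x0020, 0x0037, "DS", do.call(ds, as.list(orientation))),
    dcm_element(0x0028, 0x0002, "US", raw_u16(1)),
    dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_element(0x0028, 0x0010, "US", raw_u16(nrows)),
    dcm_element(0x0028, 0x0011, "US", raw_u16(ncols)),
    dcm_element(0x0028, 0x0030, "DS", ds(pixel_spacing[2], pixel_spacing[1])),
    dcm_element(0x0028, 0x0100, "US", raw_u16(16)),
    dcm_element(0x0028, 0x0101, "US", raw_u16(16)),
    dcm_element(0x0028, 0x0102, "US", raw_u16(15)),
    dcm_element(0x0028, 0x0103, "US", raw_u16(0)),
    if (rescale) c(dcm_element(0x0028, 0x1052, "DS", ds(-1024)),
                   dcm_element(0x0028, 0x1053, "DS", ds(1))),
    dcm_element(0x7FE0, 0x0010, "OW",
                writeBin(stored, raw(), size = 2, endian = "little"))
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0), 128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

write_test_dicom_series <- function(dir, frames, z_positions,
                                    pixel_spacing = c(1, 1), ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(frames))
    write_test_dicom_file(file.path(dir, sprintf("slice%03d.dcm", i)),
                          frames[[i]], z_positions[i],
                          pixel_spacing = pixel_spacing, ...)
  invisible(dir)
}
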