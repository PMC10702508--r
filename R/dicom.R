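# Minimal DICOM CT series reader/writer (explicit VR little endian only).
# Supports exactly the CT tags the pipeline needs: geometry, rescale
# slope/intercept and 16-bit pixel data.  No DICOM package exists in the
# deployment environment; anything beyond this subset raises an error
# rather than guessing.

.DCM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.DCM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.dcm_element <- function(group, elem, vr, value) {
  tag <- writeBin(c(as.integer(group), as.integer(elem)), raw(),
                  size = 2, endian = "little")
  if (vr %in% c("UI", "CS", "DS", "IS", "LO", "SH")) {
    val <- charToRaw(value)
    if (length(val) %% 2 == 1) {
      pad <- if (vr == "UI") as.raw(0) else charToRaw(" ")
      val <- c(val, pad)
    }
  } else if (vr == "US") {
    val <- writeBin(as.integer(value), raw(), size = 2, endian = "little")
  } else if (vr == "UL") {
    val <- writeBin(as.integer(value), raw(), size = 4, endian = "little")
  } else if (vr == "OW") {
    val <- writeBin(as.integer(value), raw(), size = 2, endian = "little")
  } else {
    stop("unsupported VR for writing: ", vr)
  }
  if (vr %in% .DCM_LONG_VRS) {
    c(tag, charToRaw(vr), raw(2),
      writeBin(length(val), raw(), size = 4, endian = "little"), val)
  } else {
    c(tag, charToRaw(vr),
      writeBin(length(val), raw(), size = 2, endian = "little"), val)
  }
}

.dcm_ds <- function(x) {
  paste(format(x, trim = TRUE, digits = 10, scientific = FALSE),
        collapse = "\\")
}

#' Write a volume as a DICOM CT series
#'
#' One explicit-VR little-endian file per axial slice, with pixel data
#' stored as signed 16-bit integers under the given rescale slope and
#' intercept (`stored = (HU - intercept) / slope`).
#'
#' @param hu 3D array of CT numbers.
#' @param dir Output directory (created if needed).
#' @param spacing_mm Voxel spacing, length 3.
#' @param slope,intercept Rescale slope/intercept written to each file.
#' @param series_uid Series instance UID (any unique string).
#' @return Character vector of written file paths, invisibly.
#' @export
write_dicom_series <- function(hu, dir, spacing_mm = c(1, 1, 1),
                               slope = 1, intercept = -1024,
                               series_uid = "1.2.826.0.1.3680043.9999.1") {
  stopifnot(length(dim(hu)) == 3)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(hu)
  paths <- character(d[3])
  for (z in seq_len(d[3])) {
    stored <- round((hu[, , z] - intercept) / slope)
    if (any(stored < -32768 | stored > 32767)) {
      stop("stored pixel values exceed int16 range; adjust slope/intercept")
    }
    sop_uid <- paste0(series_uid, ".", z)
    meta <- c(
      .dcm_element(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.2"),
      .dcm_element(0x0002, 0x0003, "UI", sop_uid),
      .dcm_element(0x0002, 0x0010, "UI", .DCM_TS_EXPLICIT_LE))
    meta <- c(.dcm_element(0x0002, 0x0000, "UL", length(meta)), meta)
    # pixel data: within each image row (fixed y) the column index x runs
    # fastest, matching our column-major (x, y) matrix layout
    pix <- as.integer(stored)
    body <- c(
      .dcm_element(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
      .dcm_element(0x0008, 0x0018, "UI", sop_uid),
      .dcm_element(0x0008, 0x0060, "CS", "CT"),
      .dcm_element(0x0020, 0x000E, "UI", series_uid),
      .dcm_element(0x0020, 0x0013, "IS", as.character(z)),
      .dcm_element(0x0020, 0x0032, "DS",
                   .dcm_ds(c(0, 0, (z - 1) * spacing_mm[3]))),
      .dcm_element(0x0020, 0x0037, "DS", .dcm_ds(c(1, 0, 0, 0, 1, 0))),
      .dcm_element(0x0028, 0x0002, "US", 1L),
      .dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      .dcm_element(0x0028, 0x0010, "US", d[2]),      # Rows    (y)
      .dcm_element(0x0028, 0x0011, "US", d[1]),      # Columns (x)
      .dcm_element(0x0028, 0x0030, "DS", .dcm_ds(spacing_mm[1:2])),
      .dcm_element(0x0018, 0x0050, "DS", .dcm_ds(spacing_mm[3])),
      .dcm_element(0x0028, 0x0100, "US", 16L),
      .dcm_element(0x0028, 0x0101, "US", 16L),
      .dcm_element(0x0028, 0x0102, "US", 15L),
      .dcm_element(0x0028, 0x0103, "US", 1L),
      .dcm_element(0x0028, 0x1052, "DS", .dcm_ds(intercept)),
      .dcm_element(0x0028, 0x1053, "DS", .dcm_ds(slope)),
      .dcm_element(0x7FE0, 0x0010, "OW", pix))
    paths[z] <- file.path(dir, sprintf("slice_%04d.dcm", z))
    con <- file(paths[z], "wb")
    writeBin(raw(128), con)
    writeBin(charToRaw("DICM"), con)
    writeBin(c(meta, body), con)
    close(con)
  }
  invisible(paths)
}

# parse one explicit-VR-LE DICOM file into a named list of needed elements
.read_dicom_file <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (length(bytes) < 132 || rawToChar(bytes[129:132]) != "DICM") {
    stop("not a DICOM file (missing DICM marker): ", path)
  }
  pos <- 133L
  u16 <- function(p) as.integer(bytes[p]) + 256L * as.integer(bytes[p + 1L])
  u32 <- function(p) u16(p) + 65536 * u16(p + 2L)
  out <- list()
  ts <- NULL
  while (pos + 7L <= length(bytes)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stop("unsupported transfer syntax (implicit VR?) in ", path,
           "; only explicit VR little endian (", .DCM_TS_EXPLICIT_LE,
           ") is supported")
    }
    if (vr %in% .DCM_LONG_VRS) {
      len <- u32(pos + 8L)
      vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      vstart <- pos + 8L
    }
    if (len == 4294967295) stop("undefined-length elements not supported: ", path)
    vbytes <- if (len > 0) bytes[vstart:(vstart + len - 1L)] else raw(0)
    key <- sprintf("%04X,%04X", group, elem)
    out[[key]] <- list(vr = vr, bytes = vbytes)
    if (key == "0002,0010") ts <- .dcm_rawstr(vbytes)
    pos <- vstart + len
  }
  if (!is.null(ts) && ts != .DCM_TS_EXPLICIT_LE) {
    stop("unsupported transfer syntax '", ts, "' in ", path,
         "; only explicit VR little endian is supported")
  }
  out
}

# strings may be padded with trailing spaces (text VRs) or nul bytes (UI)
.dcm_rawstr <- function(bytes) {
  sub("\\s+$", "", rawToChar(bytes[bytes != as.raw(0)]))
}
.dcm_str <- function(el) .dcm_rawstr(el$bytes)
.dcm_num <- function(el) as.numeric(strsplit(.dcm_str(el), "\\\\")[[1]])
.dcm_us <- function(el) readBin(el$bytes, "integer", 1, size = 2,
                                endian = "little", signed = FALSE)

.dcm_required <- function(elements, key, name, path) {
  if (is.null(elements[[key]])) {
    stop("missing required DICOM tag (", key, ") ", name, " in ", path)
  }
  elements[[key]]
}

#' Read a DICOM CT series
#'
#' Reads every `.dcm` file in a directory, checks a consistent orientation,
#' sorts slices by position along the normal, and applies each file's
#' rescale slope/intercept to obtain HU.  Only explicit-VR little-endian
#' single-frame CT files are supported.
#'
#' @param dir Directory containing the series.
#' @return List with `hu` (3D array, x fastest), `spacing_mm`.
#' @export
read_dicom_series <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.dcm$", full.names = TRUE))
  if (length(files) == 0) stop("no .dcm files found in ", dir)
  slices <- lapply(files, function(f) {
    el <- .read_dicom_file(f)
    rows <- .dcm_us(.dcm_required(el, "0028,0010", "Rows", f))
    cols <- .dcm_us(.dcm_required(el, "0028,0011", "Columns", f))
    slope <- .dcm_num(.dcm_required(el, "0028,1053", "RescaleSlope", f))
    inter <- .dcm_num(.dcm_required(el, "0028,1052", "RescaleIntercept", f))
    ipp <- .dcm_num(.dcm_required(el, "0020,0032", "ImagePositionPatient", f))
    iop <- .dcm_num(.dcm_required(el, "0020,0037", "ImageOrientationPatient", f))
    ps <- .dcm_num(.dcm_required(el, "0028,0030", "PixelSpacing", f))
    thick <- if (!is.null(el[["0018,0050"]])) .dcm_num(el[["0018,0050"]]) else NA
    pd <- .dcm_required(el, "7FE0,0010", "PixelData", f)
    stored <- readBin(pd$bytes, "integer", rows * cols, size = 2,
                      endian = "little", signed = TRUE)
    hu <- matrix(stored * slope + inter, nrow = cols, ncol = rows)  # x fastest
    list(hu = hu, ipp = ipp, iop = iop, ps = ps, thick = thick)
  })
  iop0 <- slices[[1]]$iop
  same <- vapply(slices, function(s) max(abs(s$iop - iop0)) < 1e-6, logical(1))
  if (!all(same)) stop("mixed-orientation DICOM series in ", dir)
  z <- vapply(slices, function(s) s$ipp[3], numeric(1))
  ord <- order(z)
  slices <- slices[ord]
  z <- z[ord]
  d1 <- dim(slices[[1]]$hu)
  hu <- array(NA_real_, dim = c(d1[1], d1[2], length(slices)))
  for (i in seq_along(slices)) hu[, , i] <- slices[[i]]$hu
  dz <- if (length(z) > 1) stats::median(diff(z)) else
    ifelse(is.na(slices[[1]]$thick), 1, slices[[1]]$thick)
  list(hu = hu, spacing_mm = c(slices[[1]]$ps[2], slices[[1]]$ps[1], dz))
}
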