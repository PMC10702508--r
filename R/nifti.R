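# Minimal NIfTI-1 single-file (.nii, uncompressed) reader/writer.
# Covers exactly what the simulator and evaluation pipeline need: 3D
# volumes, voxel spacing, scale slope/intercept, little/big endian input.
# No R NIfTI package is available in the deployment environment, and the
# NIfTI-1 fixed 348-byte header is simple enough to handle directly.

.NIFTI_DT <- c(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L, float64 = 64L)

#' Write a 3D volume as NIfTI-1
#'
#' Integer arrays are stored as int32, doubles as float64 (lossless
#' round-trip of HU values).  Axis order is x fastest, then y, axial slices
#' along z; the affine is diagonal with the voxel spacing.
#'
#' @param data 3D numeric or integer array.
#' @param path Output path (`.nii`).
#' @param spacing_mm Voxel spacing, length 3.
#' @param datatype `"auto"`, or one of `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, spacing_mm = c(1, 1, 1),
                        datatype = "auto") {
  stopifnot(length(dim(data)) == 3, length(spacing_mm) == 3)
  if (datatype == "auto") {
    datatype <- if (is.integer(data)) "int32" else "float64"
  }
  dt <- .NIFTI_DT[[datatype]]
  bitpix <- c(uint8 = 8L, int16 = 16L, int32 = 32L,
              float32 = 32L, float64 = 64L)[[datatype]]
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(n) writeBin(raw(n), con)

  wi(348L, 4)                     # sizeof_hdr
  wc(36)                          # data_type..dim_info
  wi(c(3L, dim(data), 1L, 1L, 1L, 1L), 2)   # dim[8]
  wf(c(0, 0, 0))                  # intent_p1..p3
  wi(0L, 2)                       # intent_code
  wi(dt, 2)                       # datatype
  wi(bitpix, 2)                   # bitpix
  wi(0L, 2)                       # slice_start
  wf(c(1, spacing_mm, 1, 1, 1, 1))  # pixdim[8] (qfac = 1)
  wf(352)                         # vox_offset
  wf(1); wf(0)                    # scl_slope, scl_inter
  wi(0L, 2); wc(2)                # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))               # cal_max..toffset
  wi(c(0L, 0L), 4)                # glmax, glmin
  wc(80 + 24)                     # descrip, aux_file
  wi(c(0L, 1L), 2)                # qform_code, sform_code
  wf(c(0, 0, 0, 0, 0, 0))         # quatern, qoffset
  wf(c(spacing_mm[1], 0, 0, 0))   # srow_x
  wf(c(0, spacing_mm[2], 0, 0))   # srow_y
  wf(c(0, 0, spacing_mm[3], 0))   # srow_z
  wc(16)                          # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)   # magic
  wc(4)                           # extension flag
  if (datatype %in% c("float32", "float64")) {
    writeBin(as.numeric(data), con, size = bitpix / 8, endian = "little")
  } else {
    writeBin(as.integer(data), con, size = bitpix / 8, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Supports uncompressed single-file `.nii` with datatypes uint8, int16,
#' int32, float32 and float64, either endianness.  Scale slope/intercept
#' are applied when set.
#'
#' @param path `.nii` file.
#' @return List with `data` (array), `spacing_mm` (length-3) and
#'   `datatype`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (hdr_size != 348L) {
    endian <- "big"
    if (.swap_int(hdr_size) != 348L) stop("not a NIfTI-1 file: ", path)
  }
  ri <- function(n, size) readBin(con, "integer", n, size = size, endian = endian,
                                  signed = size > 1)
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = endian)
  seek(con, 40)
  dims <- ri(8, 2)
  ndim <- dims[1]
  shape <- dims[2:(1 + max(ndim, 3))]
  if (ndim > 3 && any(dims[(2 + 3):(1 + ndim)] > 1)) {
    stop("only 3D NIfTI volumes are supported")
  }
  shape <- pmax(shape[1:3], 1L)
  seek(con, 70)
  dt <- ri(1, 2)
  seek(con, 76)
  pixdim <- rf(8)
  vox_offset <- rf(1)
  scl_slope <- rf(1)
  scl_inter <- rf(1)
  seek(con, 344)
  magic <- rawToChar(readBin(con, "raw", 3))
  if (!magic %in% c("n+1", "ni1")) stop("bad NIfTI magic in ", path)
  type <- names(.NIFTI_DT)[match(dt, .NIFTI_DT)]
  if (is.na(type)) stop("unsupported NIfTI datatype code ", dt)
  n <- prod(shape)
  seek(con, vox_offset)
  data <- switch(type,
    uint8 = as.integer(readBin(con, "integer", n, size = 1, signed = FALSE)),
    int16 = readBin(con, "integer", n, size = 2, endian = endian),
    int32 = readBin(con, "integer", n, size = 4, endian = endian),
    float32 = readBin(con, "numeric", n, size = 4, endian = endian),
    float64 = readBin(con, "numeric", n, size = 8, endian = endian))
  if (length(data) < n) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    data <- data * scl_slope + scl_inter
  }
  dim(data) <- shape
  list(data = data, spacing_mm = pixdim[2:4], datatype = type)
}

.swap_int <- function(x) {
  sum(as.integer(rev(packBits(intToBits(x), "raw"))) * 256^(3:0))
}
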