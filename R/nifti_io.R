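# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Only what the package needs: 3-D volumes, sform affine, the common numeric
# datatypes, little- or big-endian input, little-endian output.  No R NIfTI
# package is assumed to be available at run time; correctness is checked in
# the test suite against an independent reference implementation.

NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1, signed = FALSE),
  `4`  = list(what = "integer", size = 2, signed = TRUE),
  `8`  = list(what = "integer", size = 4, signed = TRUE),
  `16` = list(what = "double",  size = 4, signed = TRUE),
  `64` = list(what = "double",  size = 8, signed = TRUE)
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (optionally gzip-compressed) into an
#' array plus its 4x4 world-from-voxel affine.  The sform is used when
#' present (`sform_code > 0`); otherwise a diagonal affine is built from
#' `pixdim`.  Data are scaled by `scl_slope`/`scl_inter` when set.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return list with `data` (numeric array), `affine` (4x4 matrix mapping
#'   0-based voxel indices to mm), `dim` (integer dimensions).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348) stop("truncated NIfTI header in ", path)
  rd <- function(off, what, n, size, endian, signed = TRUE) {
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = signed)
  }
  endian <- "little"
  if (rd(0, "integer", 1, 4, "little") != 348L) {
    endian <- "big"
    if (rd(0, "integer", 1, 4, "big") != 348L)
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("not a NIfTI-1 file (bad magic): ", path)

  dim_field  <- rd(40, "integer", 8, 2, endian)
  datatype   <- rd(70, "integer", 1, 2, endian)
  pixdim     <- rd(76, "double", 8, 4, endian)
  vox_offset <- rd(108, "double", 1, 4, endian)
  scl_slope  <- rd(112, "double", 1, 4, endian)
  scl_inter  <- rd(116, "double", 1, 4, endian)
  qform_code <- rd(252, "integer", 1, 2, endian)
  sform_code <- rd(254, "integer", 1, 2, endian)
  srow <- rbind(rd(280, "double", 4, 4, endian),
                rd(296, "double", 4, 4, endian),
                rd(312, "double", 4, 4, endian))

  ndim <- dim_field[1]
  if (ndim < 1) stop("invalid NIfTI dim[0]: ", ndim)
  dims <- dim_field[seq_len(ndim) + 1]
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)

  skip <- round(vox_offset) - 348L              # extension bytes, if any
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(dims)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n) stop("truncated NIfTI data in ", path)
  if (!is.na(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  data <- array(as.double(vals), dim = dims)

  affine <- diag(4)
  if (!is.na(sform_code) && sform_code > 0) {
    affine[1:3, ] <- srow
  } else {
    diag(affine)[1:3] <- pixdim[2:4]
  }
  list(data = data, affine = affine, dim = as.integer(dims))
}

#' Write a NIfTI-1 volume
#'
#' Writes a 3-D numeric array as a single-file little-endian NIfTI-1 image
#' with the given sform affine (`sform_code = 2`, mm units).
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 world-from-voxel affine (0-based voxel convention).
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param datatype `"float32"` (default) or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, affine, path, datatype = c("float32", "float64")) {
  datatype <- match.arg(datatype)
  if (length(dim(data)) != 3L) stop("write_nifti expects a 3-D array")
  stopifnot(is.matrix(affine), all(dim(affine) == c(4, 4)))
  code <- if (datatype == "float32") 16L else 64L
  size <- if (datatype == "float32") 4L else 8L

  hcon <- rawConnection(raw(0), "wb")
  w_i32 <- function(x) writeBin(as.integer(x), hcon, size = 4, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), hcon, size = 2, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), hcon, size = 4, endian = "little")
  w_pad <- function(n) writeBin(raw(n), hcon)

  w_i32(348)                                    # 0   sizeof_hdr
  w_pad(36)                                     # 4   data_type .. dim_info
  w_i16(c(3, dim(data), 1, 1, 1, 1))            # 40  dim[8]
  w_pad(14)                                     # 56  intent_p* , intent_code
  w_i16(code)                                   # 70  datatype
  w_i16(8L * size)                              # 72  bitpix
  w_i16(0)                                      # 74  slice_start
  voxdim <- sqrt(colSums(affine[1:3, 1:3]^2))
  w_f32(c(1, voxdim, 1, 1, 1, 1))               # 76  pixdim[8]
  w_f32(352)                                    # 108 vox_offset
  w_f32(c(1, 0))                                # 112 scl_slope, scl_inter
  w_pad(3)                                      # 120 slice_end, slice_code
  writeBin(as.raw(2L), hcon)                    # 123 xyzt_units = mm
  w_f32(c(0, 0, 0, 0))                          # 124 cal_max..toffset
  w_i32(c(0, 0))                                # 140 glmax, glmin
  w_pad(104)                                    # 148 descrip, aux_file
  w_i16(c(0, 2))                                # 252 qform_code, sform_code
  w_f32(rep(0, 6))                              # 256 quaternion, qoffset
  w_f32(t(affine[1:3, ]))                       # 280 srow_x / srow_y / srow_z
  w_pad(16)                                     # 328 intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), hcon)   # 344 magic
  w_pad(4)                                      # 348 pad to vox_offset 352
  header <- rawConnectionValue(hcon)
  close(hcon)
  stopifnot(length(header) == 352L)

  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  writeBin(header, con)
  writeBin(as.double(data), con, size = size, endian = "little")
  invisible(path)
}
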