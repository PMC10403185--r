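#' Minimal NIfTI-1 volume I/O
#'
#' Self-contained reader/writer for single-file NIfTI-1 (`.nii`, `.nii.gz`)
#' 3D scalar volumes. Only the fields the pipeline needs are interpreted:
#' grid dimensions, voxel spacing (`pixdim`), data type, scaling slope /
#' intercept and byte order. Orientation information (qform/sform rotations)
#' is ignored: all volumes of one case are assumed co-registered, axis
#' aligned and sharing a physical origin, which holds for the phantom
#' generator and is the working assumption for input data.
#'
#' @param path File path ending in `.nii` or `.nii.gz`.
#' @return `read_nifti()`: a list with `voxels` (3D numeric array),
#'   `spacing` (numeric length 3, mm per axis) and `datatype` (NIfTI code).
#' @name nifti_io
NULL

.nifti_datatypes <- list(
  `2`   = list(what = "integer", size = 1, signed = FALSE),
  `4`   = list(what = "integer", size = 2, signed = TRUE),
  `8`   = list(what = "integer", size = 4, signed = TRUE),
  `16`  = list(what = "numeric", size = 4, signed = TRUE),
  `64`  = list(what = "numeric", size = 8, signed = TRUE),
  `256` = list(what = "integer", size = 1, signed = TRUE),
  `512` = list(what = "integer", size = 2, signed = FALSE)
)

#' @rdname nifti_io
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rb")  # reads plain files transparently too
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("not a NIfTI-1 file (truncated header): ", path)

  endian <- .Platform$endian
  sizeof_hdr <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- if (endian == "little") "big" else "little"
    sizeof_hdr <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
    if (sizeof_hdr != 348L) stop("unreadable header (bad sizeof_hdr): ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("unreadable header (bad magic): ", path)

  rd <- function(off, what, n, size) {
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian)
  }
  dim0 <- rd(40, "integer", 8, 2)
  ndim <- dim0[1]
  # accept 3D images, tolerating trailing singleton dimensions
  trailing <- if (ndim > 3) dim0[5:(ndim + 1)] else integer(0)
  if (ndim < 3 || any(trailing > 1))
    stop("non-3D image: ", path, " (dim = ",
         paste(dim0[2:(1 + max(ndim, 1L))], collapse = "x"), ")")
  dims <- dim0[2:4]

  datatype <- rd(70, "integer", 1, 2)
  spec <- .nifti_datatypes[[as.character(datatype)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype code: ", datatype)
  pixdim <- rd(76, "numeric", 8, 4)
  vox_offset <- rd(108, "numeric", 1, 4)
  scl_slope <- rd(112, "numeric", 1, 4)
  scl_inter <- rd(116, "numeric", 1, 4)

  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  n_vox <- prod(dims)
  vox <- readBin(con, spec$what, n = n_vox, size = spec$size,
                 signed = spec$signed, endian = endian)
  if (length(vox) < n_vox) stop("truncated voxel data: ", path)
  vox <- as.double(vox)
  if (!is.na(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vox <- vox * scl_slope + scl_inter
  dim(vox) <- dims
  list(voxels = vox, spacing = abs(pixdim[2:4]), datatype = datatype)
}

#' @rdname nifti_io
#' @param voxels 3D numeric array.
#' @param spacing Numeric length 3: voxel size in mm per axis.
#' @param datatype NIfTI datatype code to store; 64 (float64, lossless for R
#'   doubles) or 16 (float32).
#' @export
write_nifti <- function(voxels, path, spacing = c(1, 1, 1), datatype = 64L) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3,
            length(spacing) == 3, all(spacing > 0),
            datatype %in% c(16L, 64L))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4)
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2)
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4)
  w_raw <- function(n) writeBin(raw(n), con)

  d <- dim(voxels)
  w_i32(348)                      # sizeof_hdr
  w_raw(36)                       # data_type..dim_info (unused)
  w_i16(c(3, d, 1, 1, 1, 1))      # dim[8]
  w_f32(c(0, 0, 0))               # intent_p1..p3
  w_i16(0)                        # intent_code
  w_i16(datatype)                 # datatype
  w_i16(if (datatype == 64L) 64 else 32)  # bitpix
  w_i16(0)                        # slice_start
  w_f32(c(1, spacing, 1, 1, 1, 1))  # pixdim[8]
  w_f32(352)                      # vox_offset
  w_f32(1); w_f32(0)              # scl_slope, scl_inter
  w_i16(0); w_raw(2)              # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))            # cal_max..toffset
  w_i32(c(0, 0))                  # glmax, glmin
  w_raw(104)                      # descrip[80] + aux_file[24]
  w_i16(c(0, 1))                  # qform_code, sform_code
  w_f32(c(0, 0, 0, 0, 0, 0))      # quatern + qoffset
  w_f32(c(spacing[1], 0, 0, 0))   # srow_x
  w_f32(c(0, spacing[2], 0, 0))   # srow_y
  w_f32(c(0, 0, spacing[3], 0))   # srow_z
  w_raw(16)                       # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  w_raw(4)                        # extender
  writeBin(as.double(voxels), con, size = if (datatype == 64L) 8 else 4)
  invisible(path)
}
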