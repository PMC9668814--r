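# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O.
# Little-endian only on write; reads either byte order.  Supports the data
# types that registered research volumes actually use.  All volumes handled
# by this package are 3D scalar images.

NIFTI_TYPES <- list(
  `2`   = list(what = "integer", size = 1, signed = FALSE, name = "uint8"),
  `4`   = list(what = "integer", size = 2, signed = TRUE,  name = "int16"),
  `8`   = list(what = "integer", size = 4, signed = TRUE,  name = "int32"),
  `16`  = list(what = "double",  size = 4, signed = TRUE,  name = "float32"),
  `64`  = list(what = "double",  size = 8, signed = TRUE,  name = "float64"),
  `512` = list(what = "integer", size = 2, signed = FALSE, name = "uint16")
)

nifti_connection <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (optionally gzip-compressed) into a 3D
#' numeric array.  Scaling (`scl_slope`/`scl_inter`) is applied when set.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A 3D array with attributes `voxel_size` (numeric length-3, mm)
#'   and `datatype` (NIfTI type name).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header in ", path)
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4, endian = "little")
  endian <- "little"
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file: ", path)
  }
  rb <- function(off, what, n, size) {
    readBin(hdr_raw[(off + 1):(off + n * size)], what,
            n = n, size = size, endian = endian)
  }
  dim8 <- rb(40, "integer", 8, 2)
  datatype <- rb(70, "integer", 1, 2)
  pixdim <- rb(76, "double", 8, 4)
  vox_offset <- rb(108, "double", 1, 4)
  scl_slope <- rb(112, "double", 1, 4)
  scl_inter <- rb(116, "double", 1, 4)
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("bad NIfTI magic in ", path)
  ndim <- dim8[1]
  if (ndim < 3L) stop("expected a 3D volume: ", path)
  shape <- dim8[2:(ndim + 1)]
  if (ndim > 3L && any(shape[4:length(shape)] > 1L))
    stop("only 3D volumes are supported: ", path)
  shape <- shape[1:3]
  tinfo <- NIFTI_TYPES[[as.character(datatype)]]
  if (is.null(tinfo)) stop("unsupported NIfTI datatype code ", datatype)
  # skip the gap between the header and the data (extensions)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n_vox <- prod(shape)
  vals <- readBin(con, tinfo$what, n = n_vox, size = tinfo$size,
                  signed = tinfo$signed, endian = endian)
  if (length(vals) != n_vox) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  img <- array(as.numeric(vals), dim = shape)
  attr(img, "voxel_size") <- pixdim[2:4]
  attr(img, "datatype") <- tinfo$name
  img
}

#' Write a NIfTI-1 volume
#'
#' Writes a 3D numeric array as a little-endian single-file NIfTI-1 image.
#' The affine is a diagonal scaling by the voxel size (sform code 1), which
#' is sufficient for template-space volumes sharing one grid.
#'
#' @param img 3D numeric array.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param voxel_size Isotropic voxel edge in mm, or a length-3 vector.
#' @param datatype One of `"float32"`, `"float64"`, `"int16"`, `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, path, voxel_size = 1,
                        datatype = c("float32", "float64", "int16", "uint8")) {
  if (length(dim(img)) != 3L) stop("img must be a 3D array")
  datatype <- match.arg(datatype)
  code <- switch(datatype, uint8 = 2L, int16 = 4L, float32 = 16L, float64 = 64L)
  tinfo <- NIFTI_TYPES[[as.character(code)]]
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wd <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)
  wi(348L, 4)                      # sizeof_hdr
  wraw(36)                         # data_type..dim_info (unused)
  wi(c(3L, dim(img), 1L, 1L, 1L, 1L), 2)   # dim[8]
  wraw(14)                         # intent params + intent_code
  wi(code, 2)                      # datatype
  wi(8L * tinfo$size, 2)           # bitpix
  wi(0L, 2)                        # slice_start
  wd(c(0, voxel_size, 1, 1, 1, 1)) # pixdim[8] (qfac 0 -> treated as 1)
  wd(352)                          # vox_offset
  wd(1); wd(0)                     # scl_slope, scl_inter
  wraw(4)                          # slice_end, slice_code, xyzt_units
  wd(c(0, 0, 0, 0))                # cal_max, cal_min, slice_duration, toffset
  wi(0L, 4); wi(0L, 4)             # glmax, glmin
  wraw(80 + 24)                    # descrip, aux_file
  wi(0L, 2); wi(1L, 2)             # qform_code 0, sform_code 1
  wd(rep(0, 6))                    # quaternions b,c,d + offsets x,y,z
  wd(c(voxel_size[1], 0, 0, 0))    # srow_x
  wd(c(0, voxel_size[2], 0, 0))    # srow_y
  wd(c(0, 0, voxel_size[3], 0))    # srow_z
  wraw(16)                         # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  wraw(4)                          # extension flag
  if (datatype %in% c("float32", "float64")) {
    writeBin(as.numeric(img), con, size = tinfo$size, endian = "little")
  } else {
    writeBin(as.integer(round(img)), con, size = tinfo$size, endian = "little")
  }
  invisible(path)
}
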