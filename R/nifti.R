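# Minimal NIfTI-1 reader/writer.
#
# No NIfTI package is available in the deployment environment, and the format
# reduces here to a fixed 348-byte little-endian header plus a raw voxel
# block, so the small subset needed (single-file .nii/.nii.gz, datatypes
# uint8/int16/int32/float32/float64, pixdim spacing, no orientation handling)
# is implemented directly. Axial slice order follows the package convention:
# index increases superior to inferior.

nifti_datatypes <- list(
  `2`  = list(what = "integer", size = 1, signed = FALSE),
  `4`  = list(what = "integer", size = 2, signed = TRUE),
  `8`  = list(what = "integer", size = 4, signed = TRUE),
  `16` = list(what = "double",  size = 4, signed = TRUE),
  `64` = list(what = "double",  size = 8, signed = TRUE))

nifti_connection <- function(path, open) {
  if (grepl("\\.nii\\.gz$", path, ignore.case = TRUE)) gzfile(path, open)
  else if (grepl("\\.nii$", path, ignore.case = TRUE)) file(path, open)
  else stop("unsupported image format (expected .nii or .nii.gz): ", path)
}

# values: matrix or 3-D array; spacing c(row_mm, col_mm); datatype NIfTI code.
# NA spacing is stored as pixdim 0 and refused by the reader (no silent
# default), per the I/O contract.
write_nifti <- function(values, path, spacing, thickness, datatype = 16L) {
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)
  d <- dim(values)
  nd <- length(d)
  dims <- c(nd, d, rep(1L, 7 - nd))
  if (any(is.na(spacing))) spacing <- c(0, 0)
  if (is.na(thickness)) thickness <- 0
  pixdim <- c(1, spacing[1], spacing[2], thickness, rep(0, 4))

  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)

  wi(348L, 4)                            # 0   sizeof_hdr
  wraw(35)                               # 4   data_type .. dim_info
  wi(dims, 2)                            # 40  dim[8]
  wf(c(0, 0, 0))                         # 56  intent_p1..p3
  wi(0L, 2)                              # 68  intent_code
  wi(datatype, 2)                        # 70  datatype
  wi(dt$size * 8L, 2)                    # 72  bitpix
  wi(0L, 2)                              # 74  slice_start
  wf(pixdim)                             # 76  pixdim[8]
  wf(352)                                # 108 vox_offset
  wf(1); wf(0)                           # 112 scl_slope, scl_inter
  wi(0L, 2)                              # 120 slice_end
  wraw(1)                                # 122 slice_code
  writeBin(as.raw(2L), con)              # 123 xyzt_units: mm
  wf(c(0, 0, 0, 0))                      # 124 cal_max..toffset
  wi(c(0L, 0L), 4)                       # 140 glmax, glmin
  wraw(80); wraw(24)                     # 148 descrip, aux_file
  wi(c(0L, 0L), 2)                       # 252 qform_code, sform_code
  wf(rep(0, 6))                          # 256 quatern/qoffset
  wf(rep(0, 12))                         # 280 srow
  wraw(16)                               # 328 intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # 344 magic
  wraw(4)                                # 348 extension flag

  if (dt$what == "integer") {
    writeBin(as.integer(round(values)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(values), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

# returns list(values, spacing, thickness)
read_nifti <- function(path) {
  if (!grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
    stop("unsupported image format (expected .nii or .nii.gz): ", path)
  if (!file.exists(path)) stop("file not found: ", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  ri <- function(n, size, signed = TRUE)
    readBin(con, "integer", n = n, size = size, signed = signed,
            endian = "little")
  rf <- function(n) readBin(con, "double", n = n, size = 4, endian = "little")
  skip <- function(n) invisible(readBin(con, "raw", n = n))

  if (!identical(ri(1, 4), 348L)) stop("not a NIfTI-1 file: ", path)
  skip(35)
  dims <- ri(8, 2)                       # 40
  skip(12); skip(2)                      # intent_p*, intent_code
  datatype <- ri(1, 2)                   # 70
  skip(2); skip(2)                       # bitpix, slice_start
  pixdim <- rf(8)                        # 76
  vox_offset <- rf(1)                    # 108
  scl_slope <- rf(1); scl_inter <- rf(1) # 112, 116
  skip(344 - 120)                        # slice_end .. intent_name
  magic <- rawToChar(readBin(con, "raw", 3)); skip(1)
  if (!magic %in% c("n+1", "ni1")) stop("bad NIfTI magic in ", path)
  if (vox_offset < 348) vox_offset <- 352
  skip(vox_offset - 348)

  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)
  nd <- dims[1]
  if (!nd %in% c(2L, 3L)) stop("only 2-D/3-D NIfTI volumes are supported")
  d <- dims[2:(1 + nd)]
  n <- prod(d)
  v <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
               endian = "little")
  if (length(v) != n) stop("truncated NIfTI data in ", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    v <- v * scl_slope + scl_inter
  dim(v) <- d

  spacing <- pixdim[2:3]
  thickness <- pixdim[4]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("no pixel spacing metadata in ", path,
         " (refusing to assume a default)")
  if (!is.finite(thickness) || thickness <= 0) thickness <- NA_real_
  list(values = v, spacing = spacing, thickness = thickness)
}

#' Read a CT image
#'
#' Supported format: NIfTI-1 (`.nii`, `.nii.gz`), HU stored as float32 or any
#' integer type, pixel spacing taken from `pixdim`. Files without spacing
#' metadata are rejected rather than silently defaulted.
#'
#' @param path File path.
#' @return A [ct_image()].
#' @export
read_image <- function(path) {
  nf <- read_nifti(path)
  ct_image(nf$values, nf$spacing,
           if (is.na(nf$thickness)) 3 else nf$thickness,
           origin = path)
}

#' Write a CT image
#'
#' HU are stored as float32 (lossless well beyond the 0.5 HU quantization
#' bound of the clinical range).
#'
#' @param image A [ct_image()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "ct_image"))
  write_nifti(image$values, path, image$pixel_spacing, image$slice_thickness,
              datatype = 16L)
}

#' Read a label mask
#' @param path File path (`.nii` / `.nii.gz`, integer voxels).
#' @return A [label_mask()].
#' @export
read_mask <- function(path) {
  nf <- read_nifti(path)
  label_mask(nf$values, nf$spacing,
             if (is.na(nf$thickness)) 3 else nf$thickness)
}

#' Write a label mask (int16 NIfTI, lossless)
#' @param mask A [label_mask()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  write_nifti(mask$classes, path, mask$pixel_spacing, mask$slice_thickness,
              datatype = 4L)
}
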