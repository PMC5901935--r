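#' Minimal NIfTI-1 input/output
#'
#' The environment this package targets ships no R NIfTI library, so a small
#' self-contained NIfTI-1 reader/writer is provided. It supports the subset of
#' the format the pipeline needs: single-file `.nii` (optionally gzipped as
#' `.nii.gz`), little-endian, `float32` or `int16`/`int32`/`float64` data,
#' 3D or 4D volumes, and an sform affine. It is not a general-purpose NIfTI
#' implementation.
#'
#' @name nifti-io
#' @keywords internal
NULL

.nifti_datatypes <- c(`2` = "uint8", `4` = "int16", `8` = "int32",
                      `16` = "float32", `64` = "float64")

.nifti_con <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a 3D or 4D array as a NIfTI-1 file
#'
#' @param x numeric array with 3 or 4 dimensions.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param affine 4x4 voxel-index-to-mm matrix (NIfTI convention: indices are
#'   zero-based). Written as the sform.
#' @param tr repetition time in seconds, stored in `pixdim[5]` for 4D images.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, affine = diag(4), tr = 1) {
  nd <- length(dim(x))
  stopifnot(nd %in% c(3L, 4L), is.matrix(affine), all(dim(affine) == 4L))
  dm <- dim(x)
  con <- .nifti_con(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wc <- function(n) writeBin(raw(n), con)

  wi(348L, 4)                       # sizeof_hdr
  wc(35)                            # data_type, db_name, extents, session_error, regular
  writeBin(as.raw(0L), con)         # dim_info
  dim8 <- c(nd, dm, rep(1L, 7L - length(dm)))
  wi(dim8, 2)                       # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)         # intent_p1..3, intent_code
  wi(16L, 2); wi(32L, 2); wi(0L, 2) # datatype float32, bitpix, slice_start
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  wf(c(1, vox, tr, 0, 0, 0))        # pixdim[8] (qfac = 1)
  wf(352)                           # vox_offset
  wf(1); wf(0)                      # scl_slope, scl_inter
  wi(0L, 2); wc(1)                  # slice_end, slice_code
  writeBin(as.raw(10L), con)        # xyzt_units: mm | sec
  wf(c(0, 0, 0, 0))                 # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                  # glmax, glmin
  wc(80); wc(24)                    # descrip, aux_file
  wi(0L, 2); wi(2L, 2)              # qform_code = 0, sform_code = 2 (aligned)
  wf(rep(0, 6))                     # quatern b,c,d + qoffset x,y,z
  wf(affine[1, ]); wf(affine[2, ]); wf(affine[3, ])
  wc(16)                            # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  writeBin(raw(4), con)             # extension flag
  writeBin(as.numeric(x), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 file written by this package (or any simple single-file
#' little-endian NIfTI-1 image)
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a list with elements `data` (array), `affine` (4x4 sform, or the
#'   pixdim-scaled identity when no sform is set) and `tr` (seconds).
#' @export
read_nifti <- function(path) {
  con <- .nifti_con(path, "rb")
  on.exit(close(con))
  ri <- function(n, size) readBin(con, "integer", n = n, size = size, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4L, endian = "little")
  hdr_size <- ri(1, 4)
  if (!identical(hdr_size, 348L)) {
    stop("not a little-endian NIfTI-1 file (sizeof_hdr = ", hdr_size, ")")
  }
  readBin(con, "raw", n = 36)
  dim8 <- ri(8, 2)
  rf(3); ri(1, 2)
  datatype <- ri(1, 2); ri(1, 2); ri(1, 2)
  pixdim <- rf(8)
  vox_offset <- rf(1)
  scl_slope <- rf(1); scl_inter <- rf(1)
  ri(1, 2); readBin(con, "raw", n = 2)
  rf(4); ri(2, 4)
  readBin(con, "raw", n = 104)
  ri(1, 2); sform_code <- ri(1, 2)
  rf(6)
  srow <- rbind(rf(4), rf(4), rf(4), c(0, 0, 0, 1))
  readBin(con, "raw", n = 16)
  magic <- readBin(con, "raw", n = 4)
  if (!identical(rawToChar(magic[1:3]), "n+1")) stop("unsupported NIfTI magic")
  readBin(con, "raw", n = as.integer(vox_offset) - 348L)
  nd <- dim8[1L]
  dm <- dim8[2:(1L + nd)]
  n <- prod(dm)
  type <- .nifti_datatypes[as.character(datatype)]
  if (is.na(type)) stop("unsupported NIfTI datatype code ", datatype)
  dat <- switch(type,
    uint8   = as.numeric(readBin(con, "integer", n = n, size = 1L, signed = FALSE)),
    int16   = as.numeric(readBin(con, "integer", n = n, size = 2L, endian = "little")),
    int32   = as.numeric(readBin(con, "integer", n = n, size = 4L, endian = "little")),
    float32 = readBin(con, "numeric", n = n, size = 4L, endian = "little"),
    float64 = readBin(con, "numeric", n = n, size = 8L, endian = "little"))
  if (length(dat) < n) stop("truncated NIfTI data section in ", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    dat <- dat * scl_slope + scl_inter
  }
  affine <- if (sform_code > 0L) srow else diag(c(pixdim[2:4], 1))
  list(data = array(dat, dim = dm), affine = affine,
       tr = if (nd >= 4L) pixdim[5L] else NA_real_)
}
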