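#' BOLD time-series container
#'
#' A `bold_series` holds one subject's masked 4D BOLD data as a voxels-by-time
#' matrix together with the grid metadata needed to map rows back into 3D
#' space: the boolean brain mask, the 4x4 affine (zero-based voxel index to
#' mm, NIfTI convention) and the integer grid coordinates (1-based, R
#' convention) of each masked voxel.
#'
#' @param data numeric matrix, `n_voxels x n_timepoints`.
#' @param tr repetition time in seconds.
#' @param mask 3D logical array; must contain at least one `TRUE` voxel.
#' @param affine 4x4 invertible voxel-to-mm matrix.
#' @param voxel_coords integer matrix `n_voxels x 3` of 1-based grid indices;
#'   defaults to `which(mask, arr.ind = TRUE)` in column-major order, which is
#'   the row order every function in this package uses.
#' @param subject_id optional subject identifier carried through the pipeline.
#' @return an object of class `bold_series`.
#' @export
bold_series <- function(data, tr, mask, affine,
                        voxel_coords = NULL, subject_id = NULL) {
  data <- as.matrix(data)
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask)) {
    stop("`mask` must be a 3D logical array")
  }
  if (!any(mask)) stop("`mask` is empty")
  if (is.null(voxel_coords)) voxel_coords <- which(mask, arr.ind = TRUE)
  storage.mode(voxel_coords) <- "integer"
  if (nrow(data) != nrow(voxel_coords) || nrow(data) != sum(mask)) {
    stop("`data` must have one row per masked voxel (",
         sum(mask), " masked, ", nrow(data), " rows)")
  }
  if (ncol(data) < 2L) stop("need at least 2 timepoints")
  if (!is.matrix(affine) || any(dim(affine) != 4L) ||
      abs(det(affine)) < .Machine$double.eps) {
    stop("`affine` must be an invertible 4x4 matrix")
  }
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0) {
    stop("`tr` must be a positive scalar (seconds)")
  }
  structure(
    list(data = data, tr = tr, mask = mask, affine = affine,
         voxel_coords = voxel_coords, subject_id = subject_id),
    class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat("<bold_series>",
      if (!is.null(x$subject_id)) paste0(" subject ", x$subject_id), "\n",
      "  ", nrow(x$data), " masked voxels x ", ncol(x$data),
      " timepoints, TR = ", x$tr, " s, grid ",
      paste(dim(x$mask), collapse = "x"), "\n", sep = "")
  invisible(x)
}

#' @export
dim.bold_series <- function(x) dim(x$data)

#' Number of timepoints in a BOLD series
#' @param series a `bold_series`.
#' @return integer scalar.
#' @export
n_timepoints <- function(series) ncol(series$data)

#' Map 1-based grid indices to mm coordinates
#'
#' Applies the NIfTI affine (which acts on zero-based indices) to 1-based R
#' grid coordinates.
#'
#' @param coords integer matrix `n x 3` or length-3 vector of 1-based indices.
#' @param affine 4x4 voxel-to-mm matrix.
#' @return numeric matrix `n x 3` of mm coordinates.
#' @export
voxel_to_mm <- function(coords, affine) {
  if (is.null(dim(coords))) coords <- matrix(coords, nrow = 1L)
  h <- cbind(coords - 1, 1)        # zero-based homogeneous
  out <- h %*% t(affine)
  out[, 1:3, drop = FALSE]
}

#' Embed masked-voxel values into a full 3D volume
#'
#' @param values numeric vector, one value per masked voxel.
#' @param mask 3D logical array.
#' @param fill value used outside the mask (default `NA`).
#' @return 3D numeric array with `dim(mask)`.
#' @export
unmask <- function(values, mask, fill = NA_real_) {
  stopifnot(length(values) == sum(mask))
  vol <- array(fill, dim = dim(mask))
  vol[mask] <- values
  vol
}

#' Write a BOLD series as a 4D NIfTI image
#'
#' Unmasked voxels are written as zero.
#'
#' @param series a `bold_series`.
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(series, path) {
  dm <- dim(series$mask)
  nt <- ncol(series$data)
  vol4 <- array(0, dim = c(dm, nt))
  idx <- which(series$mask)
  for (t in seq_len(nt)) {
    vol3 <- array(0, dim = dm)
    vol3[idx] <- series$data[, t]
    vol4[, , , t] <- vol3
  }
  write_nifti(vol4, path, affine = series$affine, tr = series$tr)
}

#' Read a 4D NIfTI image into a BOLD series
#'
#' @param path a `.nii` or `.nii.gz` file with 4 dimensions.
#' @param mask optional 3D logical array; when `NULL`, voxels with nonzero
#'   temporal variance form the mask.
#' @param subject_id optional identifier.
#' @return a `bold_series`.
#' @export
read_bold_nifti <- function(path, mask = NULL, subject_id = NULL) {
  img <- read_nifti(path)
  if (length(dim(img$data)) != 4L) stop(path, " is not a 4D image")
  dm <- dim(img$data)[1:3]
  nt <- dim(img$data)[4L]
  flat <- matrix(img$data, nrow = prod(dm), ncol = nt)
  if (is.null(mask)) {
    v <- apply(flat, 1L, stats::var)
    mask <- array(v > 0 & !is.na(v), dim = dm)
  }
  bold_series(flat[which(mask), , drop = FALSE], tr = img$tr, mask = mask,
              affine = img$affine, subject_id = subject_id)
}
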