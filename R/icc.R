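#' Intrinsic connectivity contrast (ICC)
#'
#' The ICC of voxel i summarizes its connectivity with the whole brain:
#' the mean, over all other masked voxels j, of the squared Pearson
#' correlation r_ij^2 retained only when r_ij is positive (a unit step
#' weight). It is a threshold-free voxel-to-brain centrality, so no seed or
#' atlas choice is required. For group statistics the raw map is
#' z-normalized over the mask.
#'
#' @name icc
NULL

# row-standardize so that tcrossprod gives Pearson correlations;
# zero-variance rows become all-zero (their r is defined as 0)
.standardize_rows <- function(x) {
  m <- rowMeans(x)
  xc <- x - m
  ss <- sqrt(rowSums(xc^2))
  zero <- ss == 0
  ss[zero] <- 1
  out <- xc / ss
  out[zero, ] <- 0
  list(x = out, zero = zero)
}

#' Compute the raw ICC map of one subject
#'
#' For each masked voxel i,
#' `raw_i = (1 / (N - 1)) * sum_{j != i} r_ij^2 * u(r_ij)` with `u(r) = 1`
#' when `r > 0`, else 0. Computed in chunks of the row-standardized data
#' matrix so the full N x N correlation matrix is never materialized.
#' Zero-variance voxels get `raw = 0` and contribute `r = 0` to every pair.
#'
#' @param series a preprocessed [bold_series()] with at least 3 timepoints.
#' @param chunk_size voxels per chunk (memory/speed trade-off; the result is
#'   identical for any value).
#' @return an object of class `icc_map`: fields `raw` (per masked voxel),
#'   `z` (`NULL` until [normalize_icc()]), `mask`, `affine`, `voxel_coords`,
#'   `subject_id`.
#' @export
compute_icc <- function(series, chunk_size = 512L) {
  stopifnot(inherits(series, "bold_series"))
  if (ncol(series$data) < 3L) stop("need >= 3 timepoints")
  chunk_size <- as.integer(chunk_size)
  if (chunk_size < 1L) stop("`chunk_size` must be >= 1")
  st <- .standardize_rows(series$data)
  xs <- st$x
  N <- nrow(xs)
  raw <- numeric(N)
  if (all(st$zero)) {
    warning("all voxels constant; ICC map is identically zero")
  } else {
    starts <- seq.int(1L, N, by = chunk_size)
    for (s in starts) {
      idx <- s:min(s + chunk_size - 1L, N)
      r <- tcrossprod(xs[idx, , drop = FALSE], xs)
      r[r < 0] <- 0
      sums <- rowSums(r^2)
      self <- r[cbind(seq_along(idx), idx)]       # r_ii (1, or 0 if constant)
      raw[idx] <- pmax(sums - self^2, 0) / (N - 1)
    }
    raw[st$zero] <- 0
  }
  structure(list(raw = raw, z = NULL, mask = series$mask,
                 affine = series$affine, voxel_coords = series$voxel_coords,
                 subject_id = series$subject_id),
            class = "icc_map")
}

#' z-normalize an ICC map over the brain mask
#'
#' Centres and scales the raw map to zero mean and unit variance across
#' masked voxels, the form used for all group statistics. Because this is an
#' affine transform, the mean and bare-sum conventions for the raw ICC give
#' identical z maps.
#'
#' @param x an `icc_map` from [compute_icc()], or a bare numeric vector of
#'   raw values over the mask.
#' @return the `icc_map` with `z` filled in (or, for numeric input, the z
#'   vector).
#' @export
normalize_icc <- function(x) {
  raw <- if (inherits(x, "icc_map")) x$raw else as.numeric(x)
  if (length(raw) < 2L) stop("need >= 2 masked voxels")
  s <- stats::sd(raw)
  if (s == 0) stop("degenerate ICC map: zero variance across the mask")
  z <- (raw - mean(raw)) / s
  if (inherits(x, "icc_map")) {
    x$z <- z
    x
  } else {
    z
  }
}

#' @export
print.icc_map <- function(x, ...) {
  cat("<icc_map>", if (!is.null(x$subject_id)) paste0(" subject ", x$subject_id),
      "\n  ", length(x$raw), " masked voxels; raw in [",
      signif(min(x$raw), 3), ", ", signif(max(x$raw), 3), "]",
      if (!is.null(x$z)) "; z-normalized", "\n", sep = "")
  invisible(x)
}

#' Write an ICC map (raw or z) as a 3D NIfTI image
#'
#' @param map an `icc_map`.
#' @param path output path.
#' @param which `"z"` (default; requires [normalize_icc()]) or `"raw"`.
#' @return `path`, invisibly.
#' @export
write_icc_nifti <- function(map, path, which = c("z", "raw")) {
  which <- match.arg(which)
  vals <- map[[which]]
  if (is.null(vals)) stop("map has no '", which, "' values")
  write_nifti(unmask(vals, map$mask, fill = 0), path, affine = map$affine)
  invisible(path)
}
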