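#' Seed-based connectivity (second step of the two-step procedure)
#'
#' Voxel-wise analysis yields significant clusters with no a-priori
#' anatomical constraint; each cluster is then used as a seed, and the map
#' of Fisher-z-transformed correlations between the seed's mean time series
#' and every brain voxel describes *where* the cluster's connectivity
#' differs. Seed voxels are retained in the map, so local (within-seed)
#' connectivity findings are representable.
#'
#' @name seedconn
NULL

#' Mean time series over a seed region
#'
#' @param series a [bold_series()].
#' @param seed_mask 3D logical array (must intersect the brain mask), or a
#'   logical/integer vector indexing masked-voxel rows.
#' @return numeric vector of length `n_timepoints`: the unweighted mean of
#'   the seed voxels' series.
#' @export
extract_seed_timeseries <- function(series, seed_mask) {
  stopifnot(inherits(series, "bold_series"))
  rows <- .seed_rows(series, seed_mask)
  if (length(rows) == 0L) stop("seed contains no in-brain voxel")
  colMeans(series$data[rows, , drop = FALSE])
}

.seed_rows <- function(series, seed_mask) {
  if (is.array(seed_mask)) {
    stopifnot(identical(dim(seed_mask), dim(series$mask)))
    which(which(series$mask) %in% which(seed_mask))
  } else if (is.logical(seed_mask)) {
    which(seed_mask)
  } else {
    as.integer(seed_mask)
  }
}

#' Seed-to-brain Fisher-z correlation map
#'
#' Pearson correlation between the seed time series and every masked voxel,
#' Fisher z transformed (`atanh`) after clipping `|r|` at `1 - 1e-7` so the
#' map stays finite. Zero-variance voxels get z = 0.
#'
#' @param series a [bold_series()].
#' @param seed_ts seed time series (length `n_timepoints`), typically from
#'   [extract_seed_timeseries()].
#' @param seed_mask optional 3D logical recorded in the result.
#' @return an object of class `seed_map`: fields `z` (per masked voxel),
#'   `seed_mask`, `mask`, `affine`, `voxel_coords`, `subject_id`.
#' @export
seed_correlation_map <- function(series, seed_ts, seed_mask = NULL) {
  stopifnot(inherits(series, "bold_series"))
  seed_ts <- as.numeric(seed_ts)
  if (length(seed_ts) != ncol(series$data)) {
    stop("seed series length ", length(seed_ts), " != n_timepoints ",
         ncol(series$data))
  }
  if (stats::sd(seed_ts) == 0) stop("seed time series is constant")
  st <- .standardize_rows(series$data)
  sc <- (seed_ts - mean(seed_ts))
  sc <- sc / sqrt(sum(sc^2))
  r <- drop(st$x %*% sc)
  r[st$zero] <- 0
  clip <- 1 - 1e-7
  z <- atanh(pmin(pmax(r, -clip), clip))
  structure(list(z = z, seed_mask = seed_mask, mask = series$mask,
                 affine = series$affine, voxel_coords = series$voxel_coords,
                 subject_id = series$subject_id),
            class = "seed_map")
}

#' @export
print.seed_map <- function(x, ...) {
  cat("<seed_map>", if (!is.null(x$subject_id)) paste0(" subject ", x$subject_id),
      "\n  ", length(x$z), " masked voxels; z in [", signif(min(x$z), 3),
      ", ", signif(max(x$z), 3), "]\n", sep = "")
  invisible(x)
}

#' Write a seed z map as 3D NIfTI
#'
#' @param map a `seed_map`.
#' @param path output path (convention:
#'   `<subject>_<seedlabel>_z.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_seed_nifti <- function(map, path) {
  write_nifti(unmask(map$z, map$mask, fill = 0), path, affine = map$affine)
  invisible(path)
}
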