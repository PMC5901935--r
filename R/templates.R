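#' Synthetic brain geometry
#'
#' The synthetic cohort lives on a small "desk-scale" grid (default 18x18x12
#' at 3 mm isotropic) already in a common space, so no spatial normalization
#' is needed. The brain mask is a superellipsoid (exponent 4, a rounded box)
#' centred in the grid; network templates are axis-aligned blocks placed at
#' crude anatomical analogues of the networks they stand for and intersected
#' with the brain mask.
#'
#' Axis convention: x = left-right, y = posterior-anterior, z =
#' inferior-superior, all 1-based grid indices. The affine is 3 mm isotropic,
#' centred so mm coordinates are roughly symmetric about zero.
#'
#' @name synthetic-geometry
NULL

#' Brain mask for a synthetic grid
#'
#' @param grid_shape integer vector of 3 grid dimensions.
#' @return 3D logical array: a centred superellipsoid (exponent 4).
#' @export
make_brain_mask <- function(grid_shape) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 2L))
  ax <- lapply(grid_shape, function(n) {
    u <- (seq_len(n) - (n + 1) / 2) / ((n - 1) / 2)
    u^4
  })
  r <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  array(r <= 1, dim = grid_shape)
}

#' Default 3 mm isotropic affine for a synthetic grid
#'
#' @param grid_shape integer vector of 3 grid dimensions.
#' @param voxel_mm voxel edge length in mm (default 3).
#' @return 4x4 affine mapping zero-based voxel indices to mm, centred on the
#'   grid midpoint.
#' @export
make_affine <- function(grid_shape, voxel_mm = 3) {
  a <- diag(c(rep(voxel_mm, 3), 1))
  a[1:3, 4] <- -voxel_mm * (grid_shape - 1) / 2
  a
}

# fractional extents [x1,x2, y1,y2, z1,z2] per block; bilateral templates
# carry two blocks. NOISE_ROI has amplitude 0: it carries physiological
# confound, not network signal.
.template_geometry <- list(
  DMN      = list(amplitude = 1, blocks = list(c(0.34, 0.66, 0.08, 0.40, 0.64, 0.90))),
  SMA      = list(amplitude = 1, blocks = list(c(0.34, 0.66, 0.52, 0.80, 0.66, 0.94))),
  VISUAL   = list(amplitude = 1, blocks = list(c(0.18, 0.44, 0.02, 0.22, 0.28, 0.55),
                                               c(0.56, 0.82, 0.02, 0.22, 0.28, 0.55))),
  TEMPORAL = list(amplitude = 1, blocks = list(c(0.08, 0.28, 0.30, 0.55, 0.18, 0.42),
                                               c(0.72, 0.92, 0.30, 0.55, 0.18, 0.42))),
  NOISE_ROI = list(amplitude = 0, blocks = list(c(0.38, 0.62, 0.44, 0.62, 0.34, 0.58)))
)

.frac_idx <- function(f, n) {
  i1 <- round(f[1] * (n - 1)) + 1
  i2 <- round(f[2] * (n - 1)) + 1
  seq.int(i1, i2)
}

#' Build the synthetic network templates
#'
#' Produces five deterministic masks: DMN (medial posterior-superior), SMA
#' (medial anterior-superior), VISUAL (bilateral posterior), TEMPORAL
#' (bilateral lateral-inferior) and NOISE_ROI (deep central, the CompCor
#' noise region). Signal templates are pairwise disjoint and lie inside the
#' brain mask.
#'
#' @param grid_shape integer vector of 3 grid dimensions.
#' @param min_voxels smallest acceptable template size after intersection
#'   with the brain mask (default 8).
#' @return a named list of `network_template` objects, each with fields
#'   `name`, `mask` (3D logical), `amplitude`.
#' @export
make_network_templates <- function(grid_shape, min_voxels = 8L) {
  stopifnot(length(grid_shape) == 3L)
  brain <- make_brain_mask(grid_shape)
  out <- lapply(names(.template_geometry), function(nm) {
    g <- .template_geometry[[nm]]
    m <- array(FALSE, dim = grid_shape)
    for (b in g$blocks) {
      xs <- .frac_idx(b[1:2], grid_shape[1])
      ys <- .frac_idx(b[3:4], grid_shape[2])
      zs <- .frac_idx(b[5:6], grid_shape[3])
      m[xs, ys, zs] <- TRUE
    }
    m <- m & brain
    if (sum(m) < min_voxels) {
      stop("grid ", paste(grid_shape, collapse = "x"),
           " too small for template ", nm,
           " (", sum(m), " voxels after brain-mask intersection, need >= ",
           min_voxels, ")")
    }
    structure(list(name = nm, mask = m, amplitude = g$amplitude),
              class = "network_template")
  })
  names(out) <- names(.template_geometry)
  out
}

#' @export
print.network_template <- function(x, ...) {
  cat("<network_template> ", x$name, ": ", sum(x$mask), " voxels, amplitude ",
      x$amplitude, "\n", sep = "")
  invisible(x)
}
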