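# shared fixtures: everything is generated in code at test time

# grid metadata for a small synthetic brain
grid_meta <- function(shape = c(6L, 6L, 4L)) {
  mask <- make_brain_mask(shape)
  list(mask = mask, affine = make_affine(shape),
       voxel_coords = which(mask, arr.ind = TRUE))
}

# random bold_series with every masked voxel filled
tiny_series <- function(n_timepoints = 20L, shape = c(6L, 6L, 4L),
                        seed = 1L, tr = 2.5) {
  set.seed(seed)
  mask <- make_brain_mask(shape)
  bold_series(matrix(rnorm(sum(mask) * n_timepoints), sum(mask)),
              tr = tr, mask = mask, affine = make_affine(shape))
}

# explicit double-loop pairwise-Pearson ICC oracle (mean convention,
# u = positive step, zero-variance voxels contribute r = 0)
icc_oracle <- function(data) {
  N <- nrow(data)
  sds <- apply(data, 1L, sd)
  raw <- numeric(N)
  for (i in seq_len(N)) {
    if (sds[i] == 0) next
    acc <- 0
    for (j in seq_len(N)) {
      if (j == i || sds[j] == 0) next
      r <- cor(data[i, ], data[j, ])
      if (r > 0) acc <- acc + r^2
    }
    raw[i] <- acc / (N - 1)
  }
  raw
}

# per-subject spatially smooth Gaussian noise maps (n x V), for null
# calibration: white 3D noise smoothed with a separable 3-point kernel
smooth_noise_maps <- function(n_subjects, grid, passes = 2L, seed = 1L) {
  set.seed(seed)
  dm <- dim(grid$mask)
  kern <- c(0.25, 0.5, 0.25)
  smooth1 <- function(a, axis) {
    out <- a
    n <- dm[axis]
    idx <- function(i) {
      j <- pmin(pmax(i, 1L), n)
      switch(axis,
             a[j, , , drop = FALSE], a[, j, , drop = FALSE],
             a[, , j, drop = FALSE])
    }
    for (i in seq_len(n)) {
      sl <- kern[1] * idx(i - 1L) + kern[2] * idx(i) + kern[3] * idx(i + 1L)
      switch(axis,
             out[i, , ] <- sl, out[, i, ] <- sl, out[, , i] <- sl)
    }
    out
  }
  t(vapply(seq_len(n_subjects), function(s) {
    a <- array(rnorm(prod(dm)), dim = dm)
    for (p in seq_len(passes)) for (ax in 1:3) a <- smooth1(a, ax)
    a[grid$mask]
  }, numeric(sum(grid$mask))))
}
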