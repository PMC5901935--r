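test_that("discard_initial_volumes drops exactly the first columns", {
  s <- tiny_series(n_timepoints = 178L)
  out <- discard_initial_volumes(s, 3L)
  expect_equal(ncol(out$data), 175L)
  expect_identical(out$data, s$data[, -(1:3)])
  expect_identical(out$mask, s$mask)
  expect_identical(discard_initial_volumes(s, 0L), s)
  expect_error(discard_initial_volumes(s, 178L), "discard")
})

test_that("motion_qc applies strict thresholds and reports the volume", {
  m <- matrix(0.5, nrow = 10, ncol = 6)
  expect_true(motion_qc(m)$pass)
  m2 <- m; m2[7, 2] <- 1.2
  qc <- motion_qc(m2)
  expect_false(qc$pass)
  expect_equal(qc$offending_volume, 7L)
  m3 <- m; m3[4, 1] <- 1.0                       # boundary passes ("exceeded" is strict)
  expect_true(motion_qc(m3)$pass)
  m4 <- m; m4[2, 5] <- -1.01                     # rotations checked too, signed
  expect_false(motion_qc(m4)$pass)
  m5 <- m; m5[1, 1] <- NA
  expect_error(motion_qc(m5), "NaN|NA")
})

test_that("detrend removes exact lines, is idempotent and linear", {
  shape <- c(6L, 6L, 4L)
  mask <- make_brain_mask(shape)
  V <- sum(mask)
  T <- 5L
  d <- matrix(rep(1:5, each = V), V, T)          # per-voxel line 1..5
  s <- bold_series(d, tr = 2.5, mask = mask, affine = make_affine(shape))
  expect_lt(max(abs(detrend_linear(s)$data)), 1e-10)

  s2 <- tiny_series(n_timepoints = 30L, seed = 4)
  once <- detrend_linear(s2)
  twice <- detrend_linear(once)
  expect_lt(max(abs(twice$data - once$data)), 1e-10)

  # adding any line changes nothing in the output
  s3 <- s2
  s3$data <- s3$data + outer(rnorm(nrow(s3$data)), seq_len(30L)) + 5
  expect_lt(max(abs(detrend_linear(s3)$data - once$data)), 1e-8)

  # a zero-OLS-slope, zero-mean oscillation is (numerically) untouched;
  # a raw single-cycle sine is not orthogonal to a linear ramp, so project
  # the line out first to construct the probe
  T <- 40L
  x <- sin(2 * pi * (0:(T - 1)) / T)
  tc <- seq_len(T) - (T + 1) / 2
  x <- x - mean(x) - (sum(x * tc) / sum(tc^2)) * tc
  stopifnot(abs(sum(x * tc) / sum(tc^2)) < 1e-12, abs(mean(x)) < 1e-12)
  s4 <- tiny_series(n_timepoints = T, seed = 5)
  s4$data[1, ] <- x
  expect_lt(max(abs(detrend_linear(s4)$data[1, ] - x)), 1e-10)
})

test_that("bandpass meets the amplitude contracts (FFT oracle)", {
  T <- 200L; tr <- 2.5
  tt <- (0:(T - 1)) * tr
  shape <- c(6L, 6L, 4L)
  mask <- make_brain_mask(shape)
  d <- matrix(0, sum(mask), T)
  d[1, ] <- sin(2 * pi * 0.04 * tt)
  d[2, ] <- sin(2 * pi * 0.15 * tt)
  d[3, ] <- 1                                    # DC
  s <- bold_series(d, tr = tr, mask = mask, affine = make_affine(shape))
  out <- bandpass(s, 0.01, 0.08)
  amp_at <- function(v, f) Mod(fft(v))[round(f * T * tr) + 1L]
  expect_gte(amp_at(out$data[1, ], 0.04) / amp_at(d[1, ], 0.04), 0.9)
  expect_lte(amp_at(out$data[2, ], 0.15) / amp_at(d[2, ], 0.15), 0.1)
  expect_lt(max(abs(out$data[3, ])), 0.05)       # DC essentially removed

  # repeated filtering changes a pass-band probe by at most 2%
  twice <- bandpass(out, 0.01, 0.08)
  r1 <- amp_at(out$data[1, ], 0.04) / amp_at(d[1, ], 0.04)
  r2 <- amp_at(twice$data[1, ], 0.04) / amp_at(d[1, ], 0.04)
  expect_lt(abs(r2 - r1), 0.02)

  expect_error(bandpass(s, 0.01, 0.25), "Nyquist")
})

test_that("compcor removes a planted confound and is well-behaved", {
  cfg <- sim_config(13, n_timepoints = 80L, noise_sd = 0.3,
                    drift_amp = 0, physio_amp = 1.5)
  tp <- make_network_templates(cfg$grid_shape)
  co <- simulate_cohort(cfg)
  s <- simulate_subject(co[1, ], tp, cfg)

  expect_identical(compcor(s, tp$NOISE_ROI$mask, 0L), s)

  out <- compcor(s, tp$NOISE_ROI$mask, 5L)
  comps <- attr(out, "compcor_components")
  # residuals orthogonal to every retained component
  g <- abs(out$data %*% comps)
  expect_lt(max(g), 1e-8)
  # variance never increases
  expect_true(all(apply(out$data, 1, var) <= apply(s$data, 1, var) + 1e-12))
  # the planted physiological waveform is gone from signal voxels
  tsec <- (0:79) * cfg$tr
  set.seed(99)  # phases differ per subject; project onto the sin/cos pair
  conf_basis <- cbind(sin(2 * pi * 0.12 * tsec), cos(2 * pi * 0.12 * tsec),
                      sin(2 * pi * 0.18 * tsec), cos(2 * pi * 0.18 * tsec))
  rows <- which(which(s$mask) %in% which(tp$DMN$mask))[1:10]
  for (r in rows) {
    before <- summary(lm(s$data[r, ] ~ conf_basis))$r.squared
    after <- summary(lm(out$data[r, ] ~ conf_basis))$r.squared
    expect_lt(after, 0.01)                       # |corr| <= 0.1 per component
    expect_lt(after, before)
  }

  expect_error(compcor(s, tp$NOISE_ROI$mask, 10000L), "rank")
  empty <- array(FALSE, dim = cfg$grid_shape)
  expect_error(compcor(s, empty, 2L), "no in-brain voxel")
})

test_that("run_preprocess gates on motion and applies stages in order", {
  cfg <- sim_config(17, n_timepoints = 60L)
  tp <- make_network_templates(cfg$grid_shape)
  co <- simulate_cohort(cfg)
  s <- simulate_subject(co[1, ], tp, cfg)
  pc <- preproc_config(n_discard = 3L)

  bad <- matrix(0, 60, 6); bad[42, 3] <- 2.0
  excl <- run_preprocess(s, bad, pc, tp$NOISE_ROI$mask)
  expect_s3_class(excl, "icconn_exclusion")
  expect_equal(excl$offending_volume, 42L)
  expect_equal(excl$subject_id, co$subject_id[1])

  ok <- run_preprocess(s, matrix(0, 60, 6), pc, tp$NOISE_ROI$mask)
  expect_s3_class(ok, "bold_series")
  expect_equal(ncol(ok$data), 57L)

  # stage order is fixed: swapping bandpass and detrend changes the output
  manual <- compcor(bandpass(detrend_linear(discard_initial_volumes(s, 3L)),
                             pc$band_low, pc$band_high),
                    tp$NOISE_ROI$mask, pc$n_compcor)
  expect_equal(ok$data, manual$data, tolerance = 1e-12)
  swapped <- compcor(detrend_linear(bandpass(discard_initial_volumes(s, 3L),
                                             pc$band_low, pc$band_high)),
                     tp$NOISE_ROI$mask, pc$n_compcor)
  expect_false(isTRUE(all.equal(ok$data, swapped$data, tolerance = 1e-6)))
})

test_that("preprocessing preserves planted latent correlations", {
  # confound-light simulation: the pipeline must not disturb band-limited
  # network coupling by more than 0.05
  cfg <- sim_config(23, n_timepoints = 178L, noise_sd = 0,
                    drift_amp = 0.5, physio_amp = 0.5)
  tp <- make_network_templates(cfg$grid_shape)
  co <- simulate_cohort(cfg)
  ctl <- co[co$group == "control", ][1, ]
  s <- simulate_subject(ctl, tp, cfg)
  out <- run_preprocess(s, matrix(0, 178, 6), preproc_config(),
                        tp$NOISE_ROI$mask)
  rows_d <- which(which(s$mask) %in% which(tp$DMN$mask))
  rows_s <- which(which(s$mask) %in% which(tp$SMA$mask))
  before <- cor(colMeans(s$data[rows_d, ]), colMeans(s$data[rows_s, ]))
  after <- cor(colMeans(out$data[rows_d, ]), colMeans(out$data[rows_s, ]))
  expect_lt(abs(after - before), 0.05)
})
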