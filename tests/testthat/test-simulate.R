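cfg0 <- sim_config(21, n_timepoints = 60L)
tpl0 <- make_network_templates(cfg0$grid_shape)
coh0 <- simulate_cohort(cfg0)

test_that("noiseless limit: in-template voxels are scalar multiples of latents", {
  cfg <- sim_config(21, noise_sd = 0, drift_amp = 0, physio_amp = 0,
                    n_timepoints = 40L)
  s <- simulate_subject(coh0[1, ], tpl0, cfg)
  L <- attr(s, "latents")
  lin <- which(s$mask)
  for (nm in c("DMN", "SMA", "VISUAL", "TEMPORAL")) {
    rows <- which(lin %in% which(tpl0[[nm]]$mask))
    for (r in rows[c(1L, length(rows))]) {
      ratio <- s$data[r, ] / L[, nm]
      expect_lt(diff(range(ratio)), 1e-10)
    }
  }
})

test_that("control DMN-SMA latents realize the baseline coupling", {
  # the empirical correlation of band-limited series over 175 volumes has an
  # SE of roughly 0.11 (about 60 effective samples), so the 0.15 tolerance
  # is applied to the mean over 6 subjects rather than a single draw
  cfg <- sim_config(33, baseline_coupling = -0.4, n_timepoints = 175L)
  ctl <- coh0[coh0$group == "control", ][1:6, ]
  emp <- vapply(seq_len(nrow(ctl)), function(i) {
    s <- simulate_subject(ctl[i, ], tpl0, cfg)
    expect_equal(attr(s, "rho"), -0.4)
    L <- attr(s, "latents")
    cor(L[, "DMN"], L[, "SMA"])
  }, 0)
  expect_lt(abs(mean(emp) - (-0.4)), 0.15)
})

test_that("planted coupling is an exact affine, monotone map of onset", {
  cfg <- sim_config(21, n_timepoints = 40L)
  pat <- coh0[coh0$group == "patient", ]
  rho <- vapply(seq_len(nrow(pat)), function(i) {
    attr(simulate_subject(pat[i, ], tpl0, cfg), "rho")
  }, 0)
  expected <- cfg$baseline_coupling +
    cfg$coupling_slope * (cfg$onset_ref - pat$age_of_onset)
  expect_equal(rho, pmin(pmax(expected, -0.95), 0.95), tolerance = 1e-12)
  # monotone decreasing in onset wherever unclipped
  un <- abs(rho) < 0.95
  expect_true(all(diff(rho[un][order(pat$age_of_onset[un])]) <= 1e-12))
})

test_that("patients' visual latent variance is scaled by occipital_gain", {
  cfg <- sim_config(21, occipital_gain = 4, n_timepoints = 100L)
  sp <- simulate_subject(coh0[coh0$group == "patient", ][1, ], tpl0, cfg)
  sc <- simulate_subject(coh0[coh0$group == "control", ][1, ], tpl0, cfg)
  expect_equal(var(attr(sp, "latents")[, "VISUAL"]), 4, tolerance = 1e-9)
  expect_equal(var(attr(sc, "latents")[, "VISUAL"]), 1, tolerance = 1e-9)
})

test_that("subject streams are separated and reproducible", {
  a <- simulate_subject(coh0[1, ], tpl0, cfg0)
  b <- simulate_subject(coh0[1, ], tpl0, cfg0)
  expect_identical(a$data, b$data)               # bitwise determinism
  rec2 <- coh0[2, ]
  rec2$age_of_onset <- coh0$age_of_onset[1]      # same covariates, other id
  c <- simulate_subject(rec2, tpl0, cfg0)
  expect_false(identical(a$data, c$data))
})

test_that("extreme requested couplings warn and clip", {
  cfg <- sim_config(21, coupling_slope = 0.2, n_timepoints = 40L)
  rec <- coh0[coh0$group == "patient", ][1, ]
  rec$age_of_onset <- 18
  expect_warning(s <- simulate_subject(rec, tpl0, cfg), "outside")
  expect_equal(attr(s, "rho"), 0.95)
})

test_that("non-finite amplitudes are rejected", {
  cfg <- sim_config(21)
  cfg$noise_sd <- NaN
  expect_error(simulate_subject(coh0[1, ], tpl0, cfg), "amplitude")
})

test_that("planted visual hyperconnectivity is recoverable across replicates", {
  # with gain >= 2 and noise_sd <= 1, patients' within-visual correlation
  # exceeds controls' in at least 95% of seeded replicates
  hits <- 0L
  n_rep <- 20L
  for (rep in seq_len(n_rep)) {
    cfg <- sim_config(1000L + rep, n_timepoints = 60L,
                      occipital_gain = 2, noise_sd = 1)
    co <- simulate_cohort(cfg)
    tp <- make_network_templates(cfg$grid_shape)
    meanvis <- function(rec) {
      s <- simulate_subject(rec, tp, cfg)
      rows <- which(which(s$mask) %in% which(tp$VISUAL$mask))
      d <- s$data[rows[seq(1, length(rows), by = 8L)], ]
      cc <- cor(t(d))
      mean(cc[upper.tri(cc)])
    }
    p <- meanvis(co[co$group == "patient", ][1, ])
    c <- meanvis(co[co$group == "control", ][1, ])
    hits <- hits + (p > c)
  }
  expect_gte(hits / n_rep, 0.95)
})
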