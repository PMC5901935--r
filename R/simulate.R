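#' Band-limited Gaussian time courses
#'
#' Draws zero-mean, unit-variance time courses whose power is confined to a
#' frequency band, by filling the corresponding FFT bins with complex
#' Gaussian coefficients and inverting. Used as latent network signals
#' (resting-state BOLD fluctuations live in roughly 0.01-0.08 Hz).
#'
#' @param n_timepoints series length.
#' @param tr sampling interval, seconds.
#' @param n number of independent series.
#' @param f_lo,f_hi band edges, Hz.
#' @return `n_timepoints x n` matrix, columns standardized.
#' @keywords internal
.band_limited_gp <- function(n_timepoints, tr, n, f_lo = 0.01, f_hi = 0.08) {
  T <- n_timepoints
  f <- (seq_len(T) - 1) / (T * tr)
  half <- which(f > 0 & f <= 1 / (2 * tr))
  sel <- half[f[half] >= f_lo & f[half] <= f_hi]
  if (length(sel) < 2L) stop("series too short for band-limited generation")
  out <- matrix(0, T, n)
  for (j in seq_len(n)) {
    spec <- complex(real = rep(0, T), imaginary = rep(0, T))
    spec[sel] <- complex(real = stats::rnorm(length(sel)),
                         imaginary = stats::rnorm(length(sel)))
    # conjugate symmetry for a real signal
    spec[T - (sel - 1) + 1] <- Conj(spec[sel])
    x <- Re(stats::fft(spec, inverse = TRUE))
    out[, j] <- (x - mean(x)) / stats::sd(x)
  }
  out
}

.hash_string <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  h
}

.subject_seed <- function(rng_seed, subject_id) {
  as.integer((.hash_string(subject_id) + as.numeric(rng_seed) * 7919) %% 2147483647)
}

#' Simulate one subject's BOLD series with planted network structure
#'
#' Each network template carries a latent band-limited Gaussian time course.
#' The SMA latent is mixed with the DMN latent by a Cholesky construction so
#' their population correlation equals the planted coupling: for controls the
#' baseline coupling, for patients
#' `baseline_coupling + coupling_slope * (onset_ref - age_of_onset)`, clipped
#' to (-0.95, 0.95). Patients' visual latent is scaled by
#' `sqrt(occipital_gain)`, raising the shared signal variance within the
#' visual template. On top of the template-weighted latents every brain voxel
#' receives a per-voxel linear drift, two high-frequency physiological
#' sinusoids (full amplitude inside the NOISE_ROI, one fifth elsewhere) and
#' white noise. The RNG stream is derived from `(rng_seed, subject_id)` so
#' subjects are independent and any subject can be regenerated alone.
#'
#' @param record one cohort row (list or single-row `data.frame` with at
#'   least `subject_id`, `group`, and `age_of_onset` for patients).
#' @param templates result of [make_network_templates()].
#' @param config a [sim_config()].
#' @return a [bold_series()] with attributes `latents` (time x network
#'   matrix of the stored latent courses) and `rho` (the planted DMN-SMA
#'   coupling after clipping).
#' @export
simulate_subject <- function(record, templates, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(is.finite(c(config$noise_sd, config$drift_amp, config$physio_amp,
                       config$occipital_gain)))) {
    stop("non-finite amplitude in sim_config")
  }
  record <- as.list(record)
  is_patient <- as.character(record$group) == "patient"
  rho <- if (is_patient) {
    config$baseline_coupling +
      config$coupling_slope * (config$onset_ref - record$age_of_onset)
  } else {
    config$baseline_coupling
  }
  if (rho <= -1 || rho >= 1) {
    warning("requested latent DMN-SMA correlation ", signif(rho, 4),
            " outside (-1, 1); clipping")
  }
  rho <- max(min(rho, 0.95), -0.95)

  set.seed(.subject_seed(config$rng_seed, record$subject_id))
  T <- config$n_timepoints
  brain <- make_brain_mask(config$grid_shape)
  coords <- which(brain, arr.ind = TRUE)
  V <- nrow(coords)

  gp <- .band_limited_gp(T, config$tr, 4L)
  dmn <- gp[, 1L]
  sma <- rho * dmn + sqrt(1 - rho^2) * gp[, 2L]
  vis <- gp[, 3L] * if (is_patient) sqrt(config$occipital_gain) else 1
  tmp <- gp[, 4L]
  latents <- cbind(DMN = dmn, SMA = sma, VISUAL = vis, TEMPORAL = tmp)

  data <- matrix(0, V, T)
  lin <- which(brain)                      # linear index per data row
  for (nm in names(templates)) {
    tpl <- templates[[nm]]
    if (tpl$amplitude == 0 || !(nm %in% colnames(latents))) next
    rows <- which(lin %in% which(tpl$mask))
    if (length(rows)) {
      data[rows, ] <- data[rows, ] +
        tpl$amplitude * matrix(latents[, nm], length(rows), T, byrow = TRUE)
    }
  }

  # linear drift: per-voxel slope, ramp spanning [-1/2, 1/2]
  ramp <- (seq_len(T) - (T + 1) / 2) / (T - 1)
  slope <- stats::rnorm(V, 0, config$drift_amp)
  data <- data + outer(slope, ramp)

  # physiological confounds above the BOLD band, concentrated in NOISE_ROI
  tsec <- (seq_len(T) - 1) * config$tr
  physio <- sin(2 * pi * 0.12 * tsec + stats::runif(1, 0, 2 * pi)) +
            sin(2 * pi * 0.18 * tsec + stats::runif(1, 0, 2 * pi))
  w <- rep(0.2, V)
  w[lin %in% which(templates$NOISE_ROI$mask)] <- 1
  data <- data + config$physio_amp * outer(w, physio)

  if (config$noise_sd > 0) {
    data <- data + matrix(stats::rnorm(V * T, 0, config$noise_sd), V, T)
  }

  out <- bold_series(data, tr = config$tr, mask = brain,
                     affine = make_affine(config$grid_shape),
                     voxel_coords = coords, subject_id = record$subject_id)
  attr(out, "latents") <- latents
  attr(out, "rho") <- rho
  out
}
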