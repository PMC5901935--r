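#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort. Defaults restate the study
#' design the generator emulates: 17 patients and 17 controls, 178 volumes at
#' TR 2.5 s on a 3 mm grid (desk-scale 18x18x12 by default), patient clinical
#' scores drawn from the reported distributions, a control-level (baseline)
#' DMN-SMA coupling of -0.4 that patients' early onset pushes toward reversal
#' (+0.02 per year before the onset reference age of 45), and a doubling
#' (`occipital_gain = 2`) of the shared visual-network signal variance in
#' patients.
#'
#' @param rng_seed integer seed; mandatory, drives every random draw.
#' @param grid_shape 3 integers, synthetic grid dimensions.
#' @param n_patients,n_controls group sizes.
#' @param n_timepoints acquired volumes per subject.
#' @param tr repetition time, seconds.
#' @param baseline_coupling latent DMN-SMA correlation for controls.
#' @param coupling_slope change in latent DMN-SMA correlation per year of
#'   onset before the reference age (45 years, the upper end of the
#'   inclusion window): patient coupling is
#'   `baseline_coupling + coupling_slope * (45 - age_of_onset)`,
#'   clipped to (-0.95, 0.95).
#' @param occipital_gain multiplier on the shared visual-network signal
#'   variance in patients.
#' @param noise_sd white-noise standard deviation per voxel.
#' @param drift_amp scale of the per-voxel linear drift.
#' @param physio_amp amplitude of the high-frequency physiological sinusoids
#'   (concentrated in the NOISE_ROI).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(rng_seed,
                       grid_shape = c(18L, 18L, 12L),
                       n_patients = 17L, n_controls = 17L,
                       n_timepoints = 178L, tr = 2.5,
                       baseline_coupling = -0.4, coupling_slope = 0.02,
                       occipital_gain = 2, noise_sd = 1,
                       drift_amp = 1, physio_amp = 1) {
  if (missing(rng_seed) || !is.numeric(rng_seed) || length(rng_seed) != 1L) {
    stop("`rng_seed` is mandatory and must be a single integer")
  }
  if (n_patients < 1L || n_controls < 1L) {
    stop("`n_patients` and `n_controls` must be positive")
  }
  if (n_timepoints < 2L) stop("`n_timepoints` must be >= 2")
  stopifnot(length(grid_shape) == 3L, tr > 0,
            noise_sd >= 0, drift_amp >= 0, physio_amp >= 0)
  structure(
    list(rng_seed = as.integer(rng_seed), grid_shape = as.integer(grid_shape),
         n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
         n_timepoints = as.integer(n_timepoints), tr = tr,
         baseline_coupling = baseline_coupling, coupling_slope = coupling_slope,
         occipital_gain = occipital_gain, noise_sd = noise_sd,
         drift_amp = drift_amp, physio_amp = physio_amp,
         onset_ref = 45),
    class = "sim_config")
}

# clinical score generators: mean/sd from the emulated study population,
# rounded to integer and clipped to the instrument's legal range
.scale_ranges <- list(psqi = c(0L, 21L), isi = c(0L, 28L),
                      bdi = c(0L, 63L), mmse = c(0L, 30L))

.draw_score <- function(n, mean, sd, lo, hi) {
  pmin(pmax(as.integer(round(stats::rnorm(n, mean, sd))), lo), hi)
}

# exact inverse-CDF truncated normal
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Simulate a cohort's covariate table and motion traces
#'
#' Patients' age of onset is N(28.82, 10.15), PSQI N(15, 2.35), ISI
#' N(18.45, 5.16), BDI N(8, 4.52), MMSE N(28, 2); controls' BDI is
#' N(6, 3.86) and MMSE N(29, 1). Scores are rounded and clipped to each
#' instrument's range. Onset is truncated to the 18-45 inclusion window,
#' disease duration is a truncated normal with `duration = age - onset`
#' holding exactly, and gender alternates within group so the design matrix
#' stays full rank at small n. Controls get invented in-range scores (PSQI
#' 0-5, ISI 0-7) since the study reports none. Motion traces are slow
#' Gaussian random walks (step SD 0.01 mm / 0.01 degrees).
#'
#' @param config a [sim_config()].
#' @return a `data.frame` (class `icconn_cohort`) with one row per subject
#'   and columns `subject_id`, `group`, `age`, `gender`, `bdi`, `psqi`,
#'   `isi`, `mmse`, `age_of_onset`, `duration`, plus an attribute `motion`:
#'   a named list of `n_timepoints x 6` matrices (3 translations mm, 3
#'   rotations degrees).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  np <- config$n_patients
  nc <- config$n_controls

  onset <- .rtruncnorm(np, 28.82, 10.15, 18, 45)
  max_dur <- config$onset_ref - onset
  duration <- pmin(.rtruncnorm(np, 6, 4, 0.5, 27), max_dur)
  p_age <- onset + duration
  c_age <- .rtruncnorm(nc, mean(p_age), stats::sd(p_age), 18, 45)

  df <- data.frame(
    subject_id = c(sprintf("sub-P%02d", seq_len(np)),
                   sprintf("sub-C%02d", seq_len(nc))),
    group = factor(rep(c("patient", "control"), c(np, nc)),
                   levels = c("control", "patient")),
    age = round(c(p_age, c_age), 2),
    gender = factor(c(rep_len(c("F", "M"), np), rep_len(c("F", "M"), nc)),
                    levels = c("F", "M")),
    bdi = c(.draw_score(np, 8, 4.52, 0L, 63L), .draw_score(nc, 6, 3.86, 0L, 63L)),
    psqi = c(.draw_score(np, 15, 2.35, 0L, 21L), .draw_score(nc, 3, 1.5, 0L, 5L)),
    isi = c(.draw_score(np, 18.45, 5.16, 0L, 28L), .draw_score(nc, 3, 2, 0L, 7L)),
    mmse = c(.draw_score(np, 28, 2, 25L, 30L), .draw_score(nc, 29, 1, 25L, 30L)),
    age_of_onset = c(round(onset, 2), rep(NA_real_, nc)),
    stringsAsFactors = FALSE)
  df$duration <- ifelse(df$group == "patient", df$age - df$age_of_onset, NA_real_)

  motion <- lapply(df$subject_id, function(id) {
    m <- apply(matrix(stats::rnorm(config$n_timepoints * 6L, 0, 0.01),
                      ncol = 6L), 2L, cumsum)
    colnames(m) <- c("trans_x", "trans_y", "trans_z",
                     "rot_x", "rot_y", "rot_z")
    m
  })
  names(motion) <- df$subject_id
  attr(df, "motion") <- motion
  class(df) <- c("icconn_cohort", "data.frame")
  df
}

#' Write a cohort covariate table and motion traces to disk
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if missing). Writes
#'   `participants.csv` and one `<subject_id>_motion.txt` (whitespace
#'   delimited, 6 columns, one row per volume) per subject.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- as.data.frame(cohort)
  utils::write.csv(tab, file.path(dir, "participants.csv"), row.names = FALSE)
  motion <- attr(cohort, "motion")
  for (id in names(motion)) {
    utils::write.table(motion[[id]], file.path(dir, paste0(id, "_motion.txt")),
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Read a motion trace written by [write_cohort()]
#' @param path whitespace-delimited 6-column text file, one row per volume.
#' @return numeric matrix `n_volumes x 6`.
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 6L) stop("motion trace must have 6 columns, got ", ncol(m))
  dimnames(m) <- list(NULL, c("trans_x", "trans_y", "trans_z",
                              "rot_x", "rot_y", "rot_z"))
  m
}
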