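#' Clinical scale classification and summary-statistic tests
#'
#' Total-score banding for the three self-report instruments used in the
#' emulated study (PSQI for sleep quality, ISI for insomnia severity, BDI
#' for depressive symptoms) and a pooled-variance two-sample t test
#' computable from published summary statistics alone.
#'
#' @name clinical-scales
NULL

.check_score_range <- function(score, lo, hi, scale) {
  if (any(is.na(score)) || any(score < lo | score > hi)) {
    stop(scale, " score must lie in [", lo, ", ", hi, "]")
  }
  invisible(score)
}

#' Classify a PSQI total score
#'
#' Scores strictly above 5 indicate relevant sleep disturbance.
#'
#' @param score integer 0-21 (vectorized).
#' @return character: `"good_sleeper"` or `"poor_sleeper"`.
#' @export
classify_psqi <- function(score) {
  .check_score_range(score, 0, 21, "PSQI")
  ifelse(score > 5, "poor_sleeper", "good_sleeper")
}

#' Classify an ISI total score
#'
#' Bands (inclusive): 0-7 absence, 8-14 subthreshold, 15-21 moderate
#' clinical insomnia, 22-28 severe clinical insomnia.
#'
#' @param score integer 0-28 (vectorized).
#' @return character band label.
#' @export
classify_isi <- function(score) {
  .check_score_range(score, 0, 28, "ISI")
  cut(score, breaks = c(-1, 7, 14, 21, 28),
      labels = c("absence", "subthreshold", "moderate", "severe")) |>
    as.character()
}

#' Classify a BDI total score
#'
#' Mild mood disturbance from 10, clinical depression from 21.
#'
#' @param score integer 0-63 (vectorized).
#' @return character: `"minimal"`, `"mild"` or `"clinical"`.
#' @export
classify_bdi <- function(score) {
  .check_score_range(score, 0, 63, "BDI")
  ifelse(score >= 21, "clinical", ifelse(score >= 10, "mild", "minimal"))
}

#' Two-sample t test from summary statistics
#'
#' Pooled-variance Student t computed from group means, SDs and sizes (for
#' equal n this coincides with the unpooled form). Only t and df are
#' returned; turning them into a p-value is left to the caller since
#' published p-values may come from unstated test variants.
#'
#' @param mean1,sd1,n1 first group's summary statistics.
#' @param mean2,sd2,n2 second group's summary statistics.
#' @return list with `t`, `df` (`n1 + n2 - 2`), and `se`.
#' @export
summary_ttest <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) stop("zero pooled variance")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = (mean1 - mean2) / se, df = n1 + n2 - 2, se = se)
}

#' Classification report for a cohort
#'
#' @param cohort cohort `data.frame` with `psqi`, `isi`, `bdi` columns.
#' @param path optional CSV output path.
#' @return `data.frame` with one row per subject and the three band labels.
#' @export
classify_cohort <- function(cohort, path = NULL) {
  out <- data.frame(subject_id = cohort$subject_id,
                    group = as.character(cohort$group),
                    psqi = cohort$psqi,
                    psqi_class = classify_psqi(cohort$psqi),
                    isi = cohort$isi,
                    isi_class = classify_isi(cohort$isi),
                    bdi = cohort$bdi,
                    bdi_class = classify_bdi(cohort$bdi),
                    stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
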