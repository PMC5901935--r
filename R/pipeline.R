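#' Pipeline configuration
#'
#' @param rng_seed mandatory integer seed driving cohort generation and the
#'   permutation streams.
#' @param sim a [sim_config()]; defaults to `sim_config(rng_seed)`.
#' @param preproc a [preproc_config()].
#' @param alpha significance level for both correction stages.
#' @param n_perm permutations for cluster-level FWE.
#' @param regression_outcomes clinical variables regressed voxel-wise in
#'   patients (default age of onset, disease duration, ISI).
#' @param regression_covariates optional covariate column names included in
#'   the clinical regressions (default none).
#' @param second_level run the seed-based second level for every surviving
#'   group cluster (default `TRUE`; turning it off is a pure compute saving
#'   and changes no first-level or strength result).
#' @param out_dir optional output directory for [write_report()].
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(rng_seed, sim = sim_config(rng_seed),
                            preproc = preproc_config(), alpha = 0.05,
                            n_perm = 300L,
                            regression_outcomes = c("age_of_onset",
                                                    "duration", "isi"),
                            regression_covariates = NULL,
                            second_level = TRUE,
                            out_dir = NULL) {
  if (missing(rng_seed)) stop("`rng_seed` is mandatory")
  stopifnot(alpha > 0, alpha < 1)
  structure(list(rng_seed = as.integer(rng_seed), sim = sim, preproc = preproc,
                 alpha = alpha, n_perm = as.integer(n_perm),
                 regression_outcomes = regression_outcomes,
                 regression_covariates = regression_covariates,
                 second_level = isTRUE(second_level),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' Top-level keys `rng_seed` (mandatory), `alpha`, `n_perm`,
#' `regression_outcomes`, `out_dir`, and nested objects `sim` and `preproc`
#' whose keys are the arguments of [sim_config()] / [preproc_config()].
#'
#' @param path JSON file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(j$rng_seed)) stop("config must set `rng_seed`")
  sim <- do.call(sim_config, c(list(rng_seed = j$rng_seed),
                               j$sim[names(j$sim) != "rng_seed"]))
  pre <- do.call(preproc_config, as.list(j$preproc))
  args <- list(rng_seed = j$rng_seed, sim = sim, preproc = pre)
  for (k in c("alpha", "n_perm", "regression_outcomes", "out_dir")) {
    if (!is.null(j[[k]])) args[[k]] <- j[[k]]
  }
  do.call(pipeline_config, args)
}

.fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

.config_hash <- function(config) {
  .fnv1a(jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                          auto_unbox = TRUE, digits = NA, force = TRUE))
}

#' Cluster list to a reporting table
#'
#' @param clusters list of `icconn_cluster` objects.
#' @return `data.frame` with columns `x`, `y`, `z` (peak mm), `k`,
#'   `p_fdr`, `p_fwe`, `direction`, ordered by decreasing `k` then `x`.
#' @export
cluster_table <- function(clusters) {
  if (!length(clusters)) {
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      k = integer(0), p_fdr = numeric(0), p_fwe = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE))
  }
  tab <- do.call(rbind, lapply(clusters, function(cl) {
    data.frame(x = cl$peak_mm[1], y = cl$peak_mm[2], z = cl$peak_mm[3],
               k = cl$k, p_fdr = cl$p_fdr_voxelpeak,
               p_fwe = cl$p_fwe_cluster, direction = cl$direction,
               stringsAsFactors = FALSE)
  }))
  tab[order(-tab$k, tab$x), , drop = FALSE]
}

#' Write a cluster table as CSV
#'
#' @param clusters list of `icconn_cluster` objects (or a ready-made
#'   `data.frame` from [cluster_table()]).
#' @param path output CSV path.
#' @return the written `data.frame`, invisibly.
#' @export
write_cluster_table <- function(clusters, path) {
  tab <- if (is.data.frame(clusters)) clusters else cluster_table(clusters)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

.surviving <- function(clusters, alpha) {
  Filter(function(cl) !is.na(cl$p_fwe_cluster) && cl$p_fwe_cluster < alpha,
         clusters)
}

#' Run the full two-step connectivity analysis on a synthetic cohort
#'
#' Generates the cohort, preprocesses every subject (motion-excluded
#' subjects contribute no data), computes z-normalized ICC maps, compares
#' them across groups with the covariate-adjusted GLM under FDR forming and
#' permutation cluster-FWE, feeds every surviving cluster into a
#' second-level seed-based analysis at the same thresholds, runs the
#' clinical regressions in patients, and summarizes the strength of the
#' DMN-analog to SMA-template coupling against age of onset and disease
#' duration.
#'
#' @param config a [pipeline_config()].
#' @param keep_series keep preprocessed series in memory for reuse
#'   (internal; they are needed for the seed stage regardless).
#' @return an object of class `icconn_report`; see [write_report()].
#' @export
run_two_step <- function(config, keep_series = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$sim
  templates <- make_network_templates(sim$grid_shape)
  cohort <- simulate_cohort(sim)
  motion <- attr(cohort, "motion")

  series_list <- list()
  icc_z <- list()
  exclusions <- list()
  rho <- numeric(0)
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$subject_id[i]
    raw <- simulate_subject(cohort[i, ], templates, sim)
    pre <- run_preprocess(raw, motion[[id]], config$preproc,
                          noise_mask = templates$NOISE_ROI$mask)
    if (inherits(pre, "icconn_exclusion")) {
      exclusions[[length(exclusions) + 1L]] <- pre
      next
    }
    series_list[[id]] <- pre
    icc_z[[id]] <- normalize_icc(compute_icc(pre))$z
    rho[id] <- attr(raw, "rho")
  }
  included <- cohort[cohort$subject_id %in% names(series_list), , drop = FALSE]
  if (sum(included$group == "patient") < 2L ||
      sum(included$group == "control") < 2L) {
    stop("fewer than 2 subjects per group survive motion QC; aborting.\n",
         "Excluded: ", length(exclusions), " subject(s)")
  }
  Z <- do.call(rbind, icc_z[included$subject_id])
  ref <- series_list[[1L]]
  grid <- list(mask = ref$mask, affine = ref$affine,
               voxel_coords = ref$voxel_coords)

  # first level: covariate-adjusted group contrast on ICC z maps
  X <- build_design(included)
  grp <- cluster_fwe_permutation(Z, X, "group", grid,
                                 n_perm = config$n_perm,
                                 cluster_forming_alpha = config$alpha,
                                 seed = config$rng_seed + 1L)
  grp_surv <- .surviving(grp$clusters, config$alpha)

  # second level: every surviving cluster becomes a seed, same thresholds
  seed_results <- list()
  for (cl in if (config$second_level) grp_surv else list()) {
    label <- paste0("group_cluster_", cl$label)
    S <- do.call(rbind, lapply(series_list[included$subject_id], function(s) {
      seed_correlation_map(s, extract_seed_timeseries(s, cl$member_voxels))$z
    }))
    sd2 <- cluster_fwe_permutation(S, X, "group", grid,
                                   n_perm = config$n_perm,
                                   cluster_forming_alpha = config$alpha,
                                   seed = config$rng_seed + 2L + cl$label)
    seed_results[[label]] <- list(seed_cluster = cl,
                                  clusters = .surviving(sd2$clusters,
                                                        config$alpha),
                                  stat = NULL)
  }

  # clinical regressions, patients only
  pat <- included$group == "patient"
  Zp <- Z[pat, , drop = FALSE]
  pat_tab <- included[pat, , drop = FALSE]
  regressions <- list()
  for (oc in config$regression_outcomes) {
    y <- pat_tab[[oc]]
    if (is.null(y) || stats::sd(y) == 0) next
    Xr <- cbind(intercept = 1, outcome = y)
    if (!is.null(config$regression_covariates)) {
      for (cv in config$regression_covariates) {
        Xr <- cbind(Xr, as.numeric(pat_tab[[cv]]))
        colnames(Xr)[ncol(Xr)] <- cv
      }
    }
    reg <- cluster_fwe_permutation(Zp, Xr, "outcome", grid,
                                   n_perm = config$n_perm,
                                   cluster_forming_alpha = config$alpha,
                                   seed = config$rng_seed + 100L)
    regressions[[oc]] <- list(clusters = .surviving(reg$clusters,
                                                    config$alpha),
                              all_clusters = reg$clusters)
  }

  # DMN-analog seed -> SMA-template strength vs onset and duration.
  # The seed is the largest FWE-surviving onset-regression cluster when one
  # exists; at desk scale n = 17 often yields none, in which case the DMN
  # template itself is the documented fallback seed analog.
  onset_cl <- regressions[["age_of_onset"]]$clusters
  if (length(onset_cl)) {
    seed_rows <- onset_cl[[1L]]$member_voxels
    seed_source <- "onset_regression_cluster_1"
  } else {
    seed_rows <- which(which(grid$mask) %in% which(templates$DMN$mask))
    seed_source <- "dmn_template_fallback"
  }
  sma_rows <- which(which(grid$mask) %in% which(templates$SMA$mask))
  strengths <- vapply(pat_tab$subject_id, function(id) {
    s <- series_list[[id]]
    zmap <- seed_correlation_map(s, extract_seed_timeseries(s, seed_rows))$z
    mean(zmap[sma_rows])
  }, 0)
  strength <- list(
    onset = connectivity_strength_r2(strengths, pat_tab$age_of_onset),
    duration = connectivity_strength_r2(strengths, pat_tab$duration),
    strengths = strengths, planted_rho = rho[pat_tab$subject_id],
    seed_source = seed_source)

  report <- structure(list(
    group = list(clusters = grp_surv, all_clusters = grp$clusters,
                 null_max_k = grp$null_max_k),
    seed = seed_results,
    regressions = regressions,
    strength = strength,
    qc = list(exclusions = exclusions,
              n_included = nrow(included),
              n_patients = sum(pat), n_controls = sum(!pat)),
    cohort = included,
    provenance = list(rng_seed = config$rng_seed, alpha = config$alpha,
                      n_perm = config$n_perm,
                      config_hash = .config_hash(config),
                      package_version = as.character(
                        utils::packageVersion("icconn")))),
    class = "icconn_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.icconn_report <- function(x, ...) {
  cat("<icconn_report> seed ", x$provenance$rng_seed, ", ",
      x$qc$n_included, " subjects included (",
      length(x$qc$exclusions), " excluded)\n", sep = "")
  cat("  group contrast: ", length(x$group$clusters),
      " FWE-surviving cluster(s)\n", sep = "")
  for (nm in names(x$seed)) {
    cat("  seed ", nm, ": ", length(x$seed[[nm]]$clusters),
        " second-level cluster(s)\n", sep = "")
  }
  for (nm in names(x$regressions)) {
    cat("  regression on ", nm, ": ", length(x$regressions[[nm]]$clusters),
        " cluster(s)\n", sep = "")
  }
  if (!is.null(x$strength)) {
    cat("  DMN-analog/SMA strength: R2 vs onset = ",
        signif(x$strength$onset$r2, 3), ", vs duration = ",
        signif(x$strength$duration$r2, 3), "\n", sep = "")
  }
  invisible(x)
}

#' Write an analysis report to a directory
#'
#' Emits `group_clusters.csv`, one `seed_<label>_clusters.csv` per seed,
#' one `regression_<outcome>_clusters.csv` per outcome, `strength.csv`
#' (per-patient strengths and outcomes), `qc_exclusions.csv` and
#' `provenance.json`. Every cluster row has passed both correction stages.
#'
#' @param report an `icconn_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cluster_table(report$group$clusters,
                      file.path(dir, "group_clusters.csv"))
  for (nm in names(report$seed)) {
    write_cluster_table(report$seed[[nm]]$clusters,
                        file.path(dir, paste0("seed_", nm, "_clusters.csv")))
  }
  for (nm in names(report$regressions)) {
    write_cluster_table(report$regressions[[nm]]$clusters,
                        file.path(dir, paste0("regression_", nm,
                                              "_clusters.csv")))
  }
  if (!is.null(report$strength)) {
    utils::write.csv(data.frame(
      subject_id = names(report$strength$strengths),
      strength = unname(report$strength$strengths),
      age_of_onset = report$strength$onset$outcome,
      duration = report$strength$duration$outcome,
      r2_onset = report$strength$onset$r2,
      r2_duration = report$strength$duration$r2),
      file.path(dir, "strength.csv"), row.names = FALSE)
  }
  excl <- report$qc$exclusions
  utils::write.csv(
    if (length(excl)) {
      do.call(rbind, lapply(excl, function(e) {
        data.frame(subject_id = e$subject_id,
                   offending_volume = e$offending_volume,
                   max_trans = e$max_trans, max_rot = e$max_rot)
      }))
    } else {
      data.frame(subject_id = character(0), offending_volume = integer(0),
                 max_trans = numeric(0), max_rot = numeric(0))
    },
    file.path(dir, "qc_exclusions.csv"), row.names = FALSE)
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
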