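#' Covariate-adjusted group design matrix
#'
#' Builds the ANCOVA design: intercept, group indicator (patient = 1), and
#' the requested covariates (age, gender coded F = 0 / M = 1, BDI by
#' default). Errors on rank deficiency, naming the collinear columns.
#'
#' @param cohort a cohort `data.frame` (see [simulate_cohort()]).
#' @param covariates character vector of covariate column names.
#' @return numeric design matrix with named columns, one row per subject.
#' @export
build_design <- function(cohort, covariates = c("age", "gender", "bdi")) {
  X <- cbind(intercept = 1,
             group = as.numeric(cohort$group == "patient"))
  for (cv in covariates) {
    v <- cohort[[cv]]
    if (is.null(v)) stop("covariate '", cv, "' not found in cohort")
    if (is.factor(v) || is.character(v)) v <- as.numeric(factor(v)) - 1
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  .check_full_rank(X)
  X
}

.check_full_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(X)
}

#' Fit a voxel-wise linear model and test one contrast column
#'
#' Ordinary least squares at every voxel (vectorized, bit-equivalent to a
#' per-voxel fit), with a t test on a single coefficient. Two-sided p from
#' the Student t distribution with `df = n - rank(design)`; q values are
#' Benjamini-Hochberg adjusted.
#'
#' @param maps numeric matrix `n_subjects x n_voxels` of per-subject map
#'   values (e.g. ICC z maps or seed z maps stacked row-wise).
#' @param design numeric design matrix with named columns, `n_subjects`
#'   rows.
#' @param contrast name of the tested column.
#' @param grid optional list with `mask`, `affine`, `voxel_coords` carried
#'   into the result for cluster forming.
#' @return an object of class `stat_map`: `beta`, `t`, `p`, `q` (per
#'   voxel), `df`, `contrast`, plus the grid fields when supplied.
#' @export
fit_voxelwise_glm <- function(maps, design, contrast, grid = NULL) {
  maps <- as.matrix(maps)
  X <- as.matrix(design)
  if (nrow(maps) != nrow(X)) {
    stop("one map per design row required (", nrow(maps), " maps, ",
         nrow(X), " rows)")
  }
  if (!contrast %in% colnames(X)) stop("no design column named '", contrast, "'")
  .check_full_rank(X)
  ci <- match(contrast, colnames(X))
  XtXi <- chol2inv(chol(crossprod(X)))
  B <- XtXi %*% crossprod(X, maps)               # p x V
  res <- maps - X %*% B
  df <- nrow(X) - ncol(X)
  if (df < 1L) stop("no residual degrees of freedom (n = ", nrow(X),
                    ", rank = ", ncol(X), ")")
  sigma2 <- colSums(res^2) / df
  se <- sqrt(sigma2 * XtXi[ci, ci])
  tval <- ifelse(se > 0, B[ci, ] / se, 0)
  p <- 2 * stats::pt(-abs(tval), df)
  structure(list(beta = B[ci, ], t = tval, p = p, q = fdr_bh(p)$q,
                 df = df, contrast = contrast,
                 mask = grid$mask, affine = grid$affine,
                 voxel_coords = grid$voxel_coords),
            class = "stat_map")
}

#' Voxel-wise regression of a clinical variable on map values
#'
#' For each voxel, fits `outcome ~ intercept + map_value (+ covariates)` and
#' reports the t test on the map-value coefficient. This is the
#' clinical-correlation analysis (age of onset, disease duration, ISI),
#' typically run in patients only. With no covariates the t statistic
#' equals that of the symmetric model `map_value ~ outcome`, which the
#' permutation engine exploits.
#'
#' @param maps `n_subjects x n_voxels` matrix.
#' @param outcome numeric vector, length `n_subjects`; must be non-constant.
#' @param covariates optional numeric matrix of additional columns.
#' @param grid optional grid metadata (see [fit_voxelwise_glm()]).
#' @return a `stat_map` for the map-value coefficient.
#' @export
voxelwise_regression <- function(maps, outcome, covariates = NULL,
                                 grid = NULL) {
  maps <- as.matrix(maps)
  outcome <- as.numeric(outcome)
  if (length(outcome) != nrow(maps)) stop("`outcome` length must match rows of `maps`")
  if (stats::sd(outcome) == 0) stop("`outcome` is constant")
  n <- length(outcome)
  Z <- if (is.null(covariates)) matrix(1, n, 1L) else cbind(1, as.matrix(covariates))
  V <- ncol(maps)
  beta <- tval <- numeric(V)
  df <- n - ncol(Z) - 1L
  if (df < 1L) stop("no residual degrees of freedom (n = ", n, ")")
  for (v in seq_len(V)) {
    X <- cbind(Z, map_value = maps[, v])
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) { beta[v] <- 0; tval[v] <- 0; next }
    fit <- qr.coef(qrX, outcome)
    res <- outcome - X %*% fit
    s2 <- sum(res^2) / df
    XtXi <- chol2inv(qr.R(qrX))
    se <- sqrt(s2 * XtXi[ncol(X), ncol(X)])
    beta[v] <- fit[ncol(X)]
    tval[v] <- if (se > 0) beta[v] / se else 0
  }
  p <- 2 * stats::pt(-abs(tval), df)
  structure(list(beta = beta, t = tval, p = p, q = fdr_bh(p)$q, df = df,
                 contrast = "map_value",
                 mask = grid$mask, affine = grid$affine,
                 voxel_coords = grid$voxel_coords),
            class = "stat_map")
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure: with ordered p-values `p_(1) <= ... <= p_(m)`, reject
#' all hypotheses up to the largest k with `p_(k) <= k * alpha / m`.
#' q values are the monotone-enforced `m * p_(k) / k`; tied p-values share
#' the largest qualifying rank.
#'
#' @param p numeric vector of p-values in `[0, 1]`; `NA` is an error.
#' @param alpha target FDR level.
#' @return list with `reject` (logical vector) and `q` (adjusted p-values).
#' @export
fdr_bh <- function(p, alpha = 0.05) {
  if (anyNA(p)) stop("NA/NaN p-values")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(list(reject = logical(0), q = numeric(0)))
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(ranked)))           # enforce monotonicity
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  k <- which(p[o] <= seq_len(m) * alpha / m)
  reject <- logical(m)
  if (length(k)) reject[o[seq_len(max(k))]] <- TRUE
  list(reject = reject, q = q)
}

#' Strength-versus-clinical-score simple regression
#'
#' Regresses a per-subject scalar connectivity strength (e.g. mean seed-map
#' z within a target region) on a clinical variable and reports the
#' variance explained, as in the DMN-SMA coupling versus age-of-onset /
#' disease-duration analysis.
#'
#' @param strengths numeric vector of per-subject strengths.
#' @param outcome numeric clinical variable, same length.
#' @return list with `r2` (squared Pearson correlation), `slope` (of
#'   `strengths ~ outcome`), `intercept`, and the inputs `strengths`,
#'   `outcome`.
#' @export
connectivity_strength_r2 <- function(strengths, outcome) {
  strengths <- as.numeric(strengths)
  outcome <- as.numeric(outcome)
  if (length(strengths) != length(outcome)) stop("length mismatch")
  if (length(strengths) < 3L) stop("need >= 3 subjects")
  if (stats::sd(strengths) == 0 || stats::sd(outcome) == 0) {
    stop("constant input")
  }
  r <- stats::cor(strengths, outcome)
  slope <- r * stats::sd(strengths) / stats::sd(outcome)
  list(r2 = r^2, slope = slope,
       intercept = mean(strengths) - slope * mean(outcome),
       strengths = strengths, outcome = outcome)
}
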