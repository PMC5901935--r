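test_that("voxelwise GLM t equals a scalar OLS oracle", {
  set.seed(61)
  n <- 12L; V <- 5L
  X <- cbind(intercept = 1, group = rep(0:1, each = 6), age = rnorm(n))
  maps <- matrix(rnorm(n * V), n, V)
  fit <- fit_voxelwise_glm(maps, X, "group")
  for (v in seq_len(V)) {
    ref <- summary(lm(maps[, v] ~ X[, -1]))$coefficients
    expect_lt(abs(fit$t[v] - ref["X[, -1]group", "t value"]), 1e-10)
    expect_lt(abs(fit$p[v] - ref["X[, -1]group", "Pr(>|t|)"]), 1e-10)
  }
  expect_equal(fit$df, n - 3L)
})

test_that("a planted group shift produces localized positive t", {
  set.seed(62)
  n <- 34L; V <- 300L
  grp <- rep(0:1, each = 17L)
  maps <- matrix(rnorm(n * V), n, V)
  block <- 1:27
  maps[grp == 1, block] <- maps[grp == 1, block] + 1.0
  X <- cbind(intercept = 1, group = grp, age = rnorm(n), gender = rep(0:1, 17))
  fit <- fit_voxelwise_glm(maps, X, "group")
  expect_true(all(fit$t[block] > 0))
  expect_gt(mean(abs(fit$t[block])), mean(abs(fit$t[-block])))
})

test_that("rank-deficient designs fail with the collinear column named", {
  n <- 10L
  X <- cbind(intercept = 1, group = rep(0:1, 5), copy = rep(0:1, 5))
  expect_error(fit_voxelwise_glm(matrix(rnorm(n * 3), n), X, "group"),
               "collinear.*copy")
  co <- simulate_cohort(sim_config(1, n_patients = 4L, n_controls = 4L))
  co$dup <- as.numeric(co$group == "patient")
  expect_error(build_design(co, covariates = "dup"), "collinear")
})

test_that("voxelwise regression: planted association, null calibration, df", {
  set.seed(63)
  n <- 17L; V <- 60L
  onset <- rnorm(n, 29, 10)
  maps <- matrix(rnorm(n * V), n, V)
  block <- 1:8
  maps[, block] <- maps[, block] + 0.15 * onset  # strong planted relation
  fit <- voxelwise_regression(maps, onset)
  expect_true(all(fit$t[block] > 0))
  expect_true(all(fit$q[block] < 0.05))
  expect_equal(fit$df, n - 2L)

  # null calibration: outcome independent of maps
  set.seed(64)
  null_maps <- matrix(rnorm(50 * 1000L), 50)
  nf <- voxelwise_regression(null_maps, rnorm(50))
  frac <- mean(nf$p < 0.05)
  expect_lt(abs(frac - 0.05), 0.025)

  tiny <- voxelwise_regression(matrix(rnorm(9), 3), rnorm(3))
  expect_equal(tiny$df, 1L)
  expect_error(voxelwise_regression(null_maps, rep(2, 50)), "constant")
})

test_that("fdr_bh matches step-up enumeration and p.adjust", {
  res <- fdr_bh(c(0.001, 0.02, 0.03, 0.9), alpha = 0.05)
  expect_equal(sum(res$reject), 3L)
  expect_false(res$reject[4])
  expect_equal(sum(fdr_bh(rep(1, 10))$reject), 0L)
  expect_true(fdr_bh(0.04)$reject)               # m = 1 reduces to raw threshold
  set.seed(65)
  p <- runif(500)^1.5
  res2 <- fdr_bh(p)
  expect_equal(res2$q, p.adjust(p, "BH"), tolerance = 1e-12)
  expect_true(all(res2$q >= p - 1e-15))
  expect_error(fdr_bh(c(0.1, NA)), "NA")
  expect_error(fdr_bh(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("BH keeps the realized FDR at level on uniform nulls", {
  set.seed(66)
  n_rep <- 200L; m <- 2000L
  fdp <- vapply(seq_len(n_rep), function(i) {
    r <- fdr_bh(runif(m))$reject
    sum(r) > 0                                   # all-null: FDP is 0/1
  }, TRUE)
  mc_se <- sd(fdp) / sqrt(n_rep)
  expect_lte(mean(fdp), 0.05 + 2 * mc_se + 1e-12)
})

test_that("cluster formation: extents, 26-connectivity, peaks", {
  dm <- c(8L, 8L, 4L)
  sig <- array(FALSE, dim = dm)
  tmap <- array(0, dim = dm)
  sig[1:5, 1, 1] <- TRUE; tmap[1:5, 1, 1] <- c(2, 3, 5, 3, 2)   # 5-blob
  sig[7:8, 8, 4] <- TRUE; tmap[7:8, 8, 4] <- 2.5                # 2-blob
  cl <- form_clusters(sig, tmap, affine = make_affine(dm))
  expect_equal(vapply(cl, `[[`, 0L, "k"), c(5L, 2L))
  expect_equal(cl[[1]]$direction, "increase")
  expect_equal(cl[[1]]$peak_mm, voxel_to_mm(c(3, 1, 1), make_affine(dm))[1, ])

  # corner-touching voxels join under 26-connectivity
  sig2 <- array(FALSE, dim = dm); t2 <- array(1, dim = dm)
  sig2[2, 2, 2] <- TRUE; sig2[3, 3, 3] <- TRUE
  expect_length(form_clusters(sig2, t2), 1L)

  # opposite signs never merge even when adjacent
  sig3 <- array(FALSE, dim = dm); t3 <- array(0, dim = dm)
  sig3[4:5, 4, 2] <- TRUE; t3[4, 4, 2] <- 3; t3[5, 4, 2] <- -3
  cl3 <- form_clusters(sig3, t3)
  expect_length(cl3, 2L)
  expect_setequal(vapply(cl3, `[[`, "", "direction"), c("increase", "decrease"))

  single <- array(FALSE, dim = dm); single[5, 5, 2] <- TRUE
  cl4 <- form_clusters(single, t2, affine = make_affine(dm))
  expect_equal(cl4[[1]]$k, 1L)
  expect_equal(cl4[[1]]$peak_mm, voxel_to_mm(c(5, 5, 2), make_affine(dm))[1, ])

  expect_length(form_clusters(array(FALSE, dim = dm), t2), 0L)
})

test_that("cluster formation is invariant to voxel enumeration order", {
  set.seed(67)
  g <- grid_meta(c(8L, 8L, 5L))
  sig <- runif(nrow(g$voxel_coords)) < 0.2
  tv <- rnorm(nrow(g$voxel_coords))
  a <- icconn:::.form_clusters_masked(sig, tv, g$voxel_coords,
                                      dim(g$mask), g$affine)
  perm <- sample(nrow(g$voxel_coords))
  b <- icconn:::.form_clusters_masked(sig[perm], tv[perm],
                                      g$voxel_coords[perm, ],
                                      dim(g$mask), g$affine)
  ka <- sort(vapply(a, `[[`, 0L, "k"))
  kb <- sort(vapply(b, `[[`, 0L, "k"))
  expect_identical(ka, kb)
})

test_that("permutation FWE: estimator formula and planted-effect recovery", {
  set.seed(68)
  g <- grid_meta(c(6L, 6L, 4L))
  V <- nrow(g$voxel_coords)
  n <- 20L
  grp <- rep(0:1, each = 10L)
  maps <- matrix(rnorm(n * V), n, V)
  rows <- 1:12
  maps[grp == 1, rows] <- maps[grp == 1, rows] + 5  # overwhelming effect
  X <- cbind(intercept = 1, group = grp)
  res <- cluster_fwe_permutation(maps, X, "group", g, n_perm = 499L, seed = 5L)
  top <- res$clusters[[1L]]
  expect_gte(top$k, 10L)
  # the planted cluster beats every null max extent
  expect_equal(sum(res$null_max_k >= top$k), 0L)
  expect_equal(top$p_fwe_cluster, 1 / 500)
  expect_error(cluster_fwe_permutation(maps, X, "group", g, n_perm = 50L),
               ">= 100")
})

test_that("connectivity_strength_r2: exact fits, nulls, errors", {
  x <- c(20, 25, 30, 35, 40)
  expect_equal(connectivity_strength_r2(0.5 - 0.02 * x, x)$r2, 1)
  expect_lt(connectivity_strength_r2(0.5 - 0.02 * x, x)$slope, 0)
  set.seed(69)
  null <- connectivity_strength_r2(rnorm(5000), rnorm(5000))
  expect_lte(null$r2, 0.01)
  expect_error(connectivity_strength_r2(rep(1, 5), 1:5), "constant")
  expect_error(connectivity_strength_r2(1:2, 1:2), ">= 3")
})
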