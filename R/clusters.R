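#' Cluster formation and permutation-based cluster-level FWE
#'
#' Significant voxels are grouped into 26-connected components (the 3D
#' convention: faces, edges and corners all touch), split by the sign of the
#' t statistic so a cluster never mixes directions. Cluster-level
#' family-wise error is controlled by a Freedman-Lane permutation scheme:
#' residuals of the reduced model (the design without the tested column) are
#' permuted, the full model refit, clusters re-formed with the same
#' FDR-based forming rule, and the maximum null cluster extent collected.
#'
#' @name cluster-inference
NULL

# 26-neighbourhood flood fill over masked-voxel indices.
# coords: n x 3 integer grid coordinates of candidate voxels.
# Returns an integer component label per candidate.
.connected_components_26 <- function(coords, grid_dim) {
  n <- nrow(coords)
  if (n == 0L) return(integer(0))
  key <- (coords[, 1] - 1) +
    grid_dim[1] * ((coords[, 2] - 1) + grid_dim[2] * (coords[, 3] - 1))
  ord <- order(key)
  skey <- key[ord]
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  koff <- off[, 1] + grid_dim[1] * (off[, 2] + grid_dim[2] * off[, 3])
  labels <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (labels[i] > 0L) next
    cur <- cur + 1L
    stack <- i
    labels[i] <- cur
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      # neighbour keys, guarding against wrap-around at grid faces
      cx <- coords[v, 1] + off[, 1]
      cy <- coords[v, 2] + off[, 2]
      cz <- coords[v, 3] + off[, 3]
      ok <- cx >= 1 & cx <= grid_dim[1] & cy >= 1 & cy <= grid_dim[2] &
            cz >= 1 & cz <= grid_dim[3]
      nk <- key[v] + koff[ok]
      pos <- findInterval(nk, skey)
      hit <- pos > 0L & skey[pmax(pos, 1L)] == nk
      nb <- ord[pos[hit]]
      nb <- nb[labels[nb] == 0L]
      if (length(nb)) {
        labels[nb] <- cur
        stack <- c(stack, nb)
      }
    }
  }
  labels
}

# internal: clusters from a logical vector over masked voxels
.form_clusters_masked <- function(sig, tvals, voxel_coords, grid_dim, affine,
                                  qvals = NULL) {
  out <- list()
  for (dir in c("increase", "decrease")) {
    pick <- which(sig & if (dir == "increase") tvals > 0 else tvals < 0)
    if (!length(pick)) next
    lab <- .connected_components_26(voxel_coords[pick, , drop = FALSE],
                                    grid_dim)
    for (l in seq_len(max(lab))) {
      members <- pick[lab == l]
      peak <- members[which.max(abs(tvals[members]))]
      out[[length(out) + 1L]] <- structure(list(
        label = NA_integer_,
        k = length(members),
        peak_mm = drop(voxel_to_mm(voxel_coords[peak, , drop = FALSE], affine)),
        peak_voxel = voxel_coords[peak, ],
        direction = dir,
        t_peak = tvals[peak],
        p_fdr_voxelpeak = if (is.null(qvals)) NA_real_ else qvals[peak],
        p_fwe_cluster = NA_real_,
        member_voxels = members), class = "icconn_cluster")
    }
  }
  if (length(out)) {
    ord <- order(-vapply(out, `[[`, 0, "k"))
    out <- out[ord]
    for (i in seq_along(out)) out[[i]]$label <- i
  }
  out
}

#' Form 26-connected clusters from a significance mask
#'
#' @param sig_mask 3D logical array of significant voxels.
#' @param t_map 3D numeric array of t statistics (same grid); clusters are
#'   split by its sign and the peak is the maximum `|t|`.
#' @param affine 4x4 voxel-to-mm matrix for peak coordinates.
#' @param q_map optional 3D array of FDR q values (fills
#'   `p_fdr_voxelpeak`).
#' @return list of `icconn_cluster` objects ordered by decreasing extent;
#'   fields `label`, `k`, `peak_mm`, `direction`, `t_peak`,
#'   `p_fdr_voxelpeak`, `p_fwe_cluster` (`NA` until permutation),
#'   `member_voxels` (indices into the masked-voxel ordering implied by
#'   `which(sig_mask | TRUE)` -- here linear 3D indices). An empty mask
#'   yields an empty list.
#' @export
form_clusters <- function(sig_mask, t_map, affine = diag(4), q_map = NULL) {
  stopifnot(is.array(sig_mask), length(dim(sig_mask)) == 3L,
            identical(dim(sig_mask), dim(t_map)))
  idx <- which(sig_mask)
  coords <- which(sig_mask, arr.ind = TRUE)
  cl <- .form_clusters_masked(rep(TRUE, length(idx)), t_map[idx],
                              coords, dim(sig_mask), affine,
                              qvals = if (is.null(q_map)) NULL else q_map[idx])
  # re-express member indices as linear 3D indices for an array interface
  for (i in seq_along(cl)) cl[[i]]$member_voxels <- idx[cl[[i]]$member_voxels]
  cl
}

#' @export
print.icconn_cluster <- function(x, ...) {
  cat("<cluster ", x$label, "> k = ", x$k, ", ", x$direction, ", peak (",
      paste(round(x$peak_mm, 1), collapse = ", "), ") mm, p_fwe = ",
      format(x$p_fwe_cluster, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Clusters from a fitted stat map at an FDR forming threshold
#'
#' @param stat a `stat_map` with grid metadata.
#' @param alpha FDR level used as the cluster-forming threshold.
#' @return list of clusters (member indices refer to masked-voxel rows).
#' @export
clusters_from_statmap <- function(stat, alpha = 0.05) {
  stopifnot(inherits(stat, "stat_map"))
  if (is.null(stat$voxel_coords)) stop("stat map lacks grid metadata")
  sig <- fdr_bh(stat$p, alpha)$reject
  .form_clusters_masked(sig, stat$t, stat$voxel_coords, dim(stat$mask),
                        stat$affine, qvals = stat$q)
}

# one permutation's max cluster extent (over both directions)
.max_cluster_k <- function(sig, tvals, voxel_coords, grid_dim) {
  mx <- 0L
  for (s in c(1, -1)) {
    pick <- which(sig & s * tvals > 0)
    if (length(pick) <= mx) next
    lab <- .connected_components_26(voxel_coords[pick, , drop = FALSE], grid_dim)
    mx <- max(mx, tabulate(lab))
  }
  mx
}

#' Cluster-level FWE by Freedman-Lane permutation
#'
#' Observed clusters are formed from the FDR-significant mask of the full
#' model at `cluster_forming_alpha`. The null distribution of the maximum
#' cluster extent is built by permuting the residuals of the reduced model
#' (the design without the tested column), adding them back to the reduced
#' fit, refitting the full model and re-forming clusters with the identical
#' rule. Each observed cluster gets
#' `p_fwe = (1 + #{null max k >= k}) / (1 + n_perm)`.
#'
#' @param maps `n_subjects x n_voxels` matrix of per-subject maps.
#' @param design named design matrix.
#' @param contrast tested column name.
#' @param grid list with `mask`, `affine`, `voxel_coords` for the masked
#'   voxels (e.g. from any subject's `bold_series`).
#' @param n_perm number of permutations (>= 100; the tail is unstable
#'   below that).
#' @param cluster_forming_alpha FDR level of the forming threshold.
#' @param seed integer seed for the permutation stream.
#' @return list with `clusters` (observed clusters, `p_fwe_cluster`
#'   filled), `stat` (the observed `stat_map`), `null_max_k` (the
#'   permutation distribution), `n_perm`, `seed`.
#' @export
cluster_fwe_permutation <- function(maps, design, contrast, grid,
                                    n_perm = 500L,
                                    cluster_forming_alpha = 0.05,
                                    seed = 1L) {
  n_perm <- as.integer(n_perm)
  if (n_perm < 100L) stop("`n_perm` must be >= 100 (unstable tail below)")
  maps <- as.matrix(maps)
  X <- as.matrix(design)
  ci <- match(contrast, colnames(X))
  if (is.na(ci)) stop("no design column named '", contrast, "'")
  obs <- fit_voxelwise_glm(maps, X, contrast, grid)
  sig <- fdr_bh(obs$p, cluster_forming_alpha)$reject
  gd <- dim(grid$mask)
  clusters <- .form_clusters_masked(sig, obs$t, grid$voxel_coords, gd,
                                    grid$affine, qvals = obs$q)

  # reduced model fit (Freedman-Lane)
  Xr <- X[, -ci, drop = FALSE]
  Br <- chol2inv(chol(crossprod(Xr))) %*% crossprod(Xr, maps)
  fitted_r <- Xr %*% Br
  res_r <- maps - fitted_r

  XtXi <- chol2inv(chol(crossprod(X)))
  P <- XtXi %*% t(X)
  df <- nrow(X) - ncol(X)
  n <- nrow(X)
  set.seed(seed)
  null_max_k <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    Yp <- fitted_r + res_r[sample.int(n), , drop = FALSE]
    B <- P %*% Yp
    res <- Yp - X %*% B
    s2 <- colSums(res^2) / df
    se <- sqrt(s2 * XtXi[ci, ci])
    tv <- ifelse(se > 0, B[ci, ] / se, 0)
    pv <- 2 * stats::pt(-abs(tv), df)
    rej <- fdr_bh(pv, cluster_forming_alpha)$reject
    null_max_k[b] <- if (any(rej)) {
      .max_cluster_k(rej, tv, grid$voxel_coords, gd)
    } else 0L
  }
  for (i in seq_along(clusters)) {
    k <- clusters[[i]]$k
    clusters[[i]]$p_fwe_cluster <- (1 + sum(null_max_k >= k)) / (1 + n_perm)
  }
  list(clusters = clusters, stat = obs, null_max_k = null_max_k,
       n_perm = n_perm, seed = seed)
}
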