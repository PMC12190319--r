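#' Log Jacobian determinant of a displacement field
#'
#' Given a per-voxel displacement field u (subject-to-reference, physical
#' units), computes `ln det(I + grad(u))` at every voxel via central
#' differences (one-sided at the grid borders). The identity field maps to
#' 0 everywhere; negative values mean local contraction toward the
#' reference, positive values dilation. Voxels with a non-invertible local
#' Jacobian (determinant <= 0) are flagged `NA` and excluded from
#' downstream statistics.
#'
#' @param deformation 4-D array `(nx, ny, nz, 3)`: displacement components
#'   in the same physical units as `voxel_size_um`.
#' @param voxel_size_um Positive triple, grid spacing (micrometres).
#' @return 3-D array of log Jacobian determinants with attributes
#'   `voxel_size_um` and `n_flagged` (count of non-invertible voxels).
#' @export
log_jacobian <- function(deformation, voxel_size_um) {
  d <- dim(deformation)
  if (length(d) != 4 || d[4] != 3)
    stopf("`deformation` must be an (nx, ny, nz, 3) array")
  if (!all(is.finite(deformation))) stopf("displacement field must be finite")
  check_positive(voxel_size_um, "voxel_size_um")
  # gradient along axis `ax` of 3-D array `a`, central differences inside,
  # one-sided at the borders
  grad_axis <- function(a, ax) {
    n <- d[ax]
    h <- voxel_size_um[ax]
    slice <- function(i) {
      switch(ax,
             a[i, , , drop = FALSE],
             a[, i, , drop = FALSE],
             a[, , i, drop = FALSE])
    }
    up <- slice(c(2:n, n))
    dn <- slice(c(1, 1:(n - 1)))
    sp <- rep(2 * h, n)
    sp[c(1, n)] <- h  # one-sided spacing at the borders
    before <- prod(d[seq_len(ax - 1)])
    after <- prod(d[1:3]) / (before * n)
    span <- array(rep(rep(sp, each = before), times = after), d[1:3])
    (up - dn) / span
  }
  J <- vector("list", 9)  # J[[3*(i-1)+j]] = d u_i / d x_j
  for (i in 1:3) for (j in 1:3) {
    g <- grad_axis(array(deformation[, , , i], d[1:3]), j)
    if (i == j) g <- g + 1
    J[[3 * (i - 1) + j]] <- g
  }
  det3 <- J[[1]] * (J[[5]] * J[[9]] - J[[6]] * J[[8]]) -
    J[[2]] * (J[[4]] * J[[9]] - J[[6]] * J[[7]]) +
    J[[3]] * (J[[4]] * J[[8]] - J[[5]] * J[[7]])
  bad <- det3 <= 0
  ljd <- array(NA_real_, d[1:3])
  ljd[!bad] <- log(det3[!bad])
  attr(ljd, "voxel_size_um") <- voxel_size_um
  attr(ljd, "n_flagged") <- sum(bad)
  ljd
}

#' Subject-space mask volume and brain-normalised percentage
#'
#' For a log-Jacobian map, the subject-space volume of a reference-space
#' mask is the integral of the local volume factor: `sum(exp(LJD)) *
#' voxel volume` over the mask (mathematically equivalent to
#' inverse-transforming the mask and counting voxels, without
#' re-implementing registration). For a binary segmentation the volume is
#' the voxel count times the voxel volume. The percentage of brain uses the
#' same rule on the brain mask.
#'
#' @param subject Either a 3-D numeric LJD array (use `mode = "ljd"`) or a
#'   logical/0-1 segmentation array (`mode = "segmentation"`).
#' @param mask Logical array: the region of interest.
#' @param brain_mask Logical array: whole-brain reference mask.
#' @param voxel_size_um Voxel spacing (falls back to the array's
#'   `voxel_size_um` attribute).
#' @param mode Input interpretation; default guesses `"ljd"` for numeric
#'   input and `"segmentation"` for logical input.
#' @return Data frame: `mask_volume_um3`, `brain_volume_um3`,
#'   `percent_of_brain`.
#' @export
mask_volume <- function(subject, mask, brain_mask,
                        voxel_size_um = attr(subject, "voxel_size_um"),
                        mode = NULL) {
  mode <- mode %||% (if (is.logical(subject)) "segmentation" else "ljd")
  if (!is.logical(mask)) mask <- mask > 0
  if (!is.logical(brain_mask)) brain_mask <- brain_mask > 0
  if (!identical(dim(mask), dim(subject)) ||
      !identical(dim(brain_mask), dim(subject)))
    stopf("masks must match the subject grid")
  if (!any(mask)) stopf("empty mask")
  check_positive(voxel_size_um, "voxel_size_um")
  vv <- prod(voxel_size_um)
  vol_of <- function(mk) {
    if (mode == "segmentation") sum(subject[mk]) * vv
    else sum(exp(subject[mk]), na.rm = TRUE) * vv
  }
  mv <- vol_of(mask)
  bv <- vol_of(brain_mask)
  data.frame(mask_volume_um3 = mv, brain_volume_um3 = bv,
             percent_of_brain = 100 * mv / bv)
}

# Flatten a list of equal-shaped arrays into a voxels x subjects matrix.
stack_maps <- function(maps) {
  d <- dim(maps[[1]])
  for (m in maps) if (!identical(dim(m), d)) stopf("maps must share one grid")
  list(V = vapply(maps, as.vector, numeric(prod(d))), dim = d)
}

# Vectorised Welch two-sample t over the rows of V (voxels x subjects).
welch_rows <- function(V, g1, g2) {
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(V[, g1, drop = FALSE]); m2 <- rowMeans(V[, g2, drop = FALSE])
  v1 <- rowSums((V[, g1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((V[, g2, drop = FALSE] - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  zero <- se2 == 0
  t[zero] <- NA; df[zero] <- NA
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' Voxelwise two-group statistic map
#'
#' Unequal-variance (Welch) two-sample t statistic at every voxel, with the
#' nominal two-sided p-value. Voxels with zero variance in both groups are
#' set to `NA`.
#'
#' @param maps List of per-subject arrays on a shared grid.
#' @param groups Vector of two group labels, one per subject; the first
#'   level (or first encountered label) is the reference group.
#' @return List with `t_map`, `p_map`, `df_map` (arrays) and `groups`.
#' @export
voxelwise_group_stat <- function(maps, groups) {
  groups <- factor(groups, levels = unique(as.character(groups)))
  if (nlevels(groups) != 2) stopf("exactly two groups required")
  if (length(maps) != length(groups)) stopf("one map per subject required")
  if (min(table(groups)) < 2) stopf("need >= 2 subjects per group")
  st <- stack_maps(maps)
  w <- welch_rows(st$V, groups == levels(groups)[1], groups == levels(groups)[2])
  list(t_map = array(w$t, st$dim), p_map = array(w$p, st$dim),
       df_map = array(w$df, st$dim), groups = levels(groups))
}

#' Permutation-calibrated cluster inference
#'
#' Family-wise-error-controlled detection of voxel clusters differing
#' between two groups. Candidate clusters are connected components
#' (26-connectivity by default) of voxels whose Welch-t nominal p falls
#' below the cluster-forming threshold. Group labels are permuted `n_perm`
#' times and the maximum supra-threshold cluster extent (voxel count) is
#' recorded per permutation; an observed cluster is significant when its
#' extent exceeds the `(1 - cluster_alpha)` quantile of that null
#' distribution. If `n_perm` meets or exceeds the number of distinct label
#' arrangements, exhaustive enumeration is used and a message is emitted.
#'
#' @param maps List of per-subject arrays on a shared grid.
#' @param groups Two-level group vector, one entry per subject (>= 3 per
#'   group).
#' @param n_perm Number of permutations (>= 100).
#' @param cluster_alpha Family-wise error target (default 0.05).
#' @param forming_p Cluster-forming voxelwise p threshold (two-sided,
#'   default 0.01).
#' @param connectivity 26 (default) or 6.
#' @param min_cluster_vox Minimum extent for a candidate cluster.
#' @param seed RNG seed for the permutation draw.
#' @return An object of class `cluster_result`: `stat_map` (Welch t),
#'   `p_map` (nominal voxel p inside significant clusters, `NA` elsewhere),
#'   `cluster_labels` (integer array, 0 = background), `clusters` (data
#'   frame: id, size_vox, peak_t, p_cluster, significant), `null_max_size`,
#'   `size_threshold`, `n_perm`, `exhaustive`, plus the settings used.
#' @export
permutation_cluster <- function(maps, groups, n_perm = 1000,
                                cluster_alpha = 0.05, forming_p = 0.01,
                                connectivity = 26, min_cluster_vox = 1,
                                seed = 1L) {
  groups <- factor(groups, levels = unique(as.character(groups)))
  if (nlevels(groups) != 2) stopf("exactly two groups required")
  tab <- table(groups)
  if (min(tab) < 3) stopf("need >= 3 subjects per group")
  if (n_perm < 100) stopf("`n_perm` must be >= 100")
  st <- stack_maps(maps)
  V <- st$V
  n <- ncol(V)
  n1 <- tab[[1]]
  lev <- levels(groups)

  max_supra_size <- function(g1) {
    w <- welch_rows(V, g1, !g1)
    idx <- which(!is.na(w$p) & w$p < forming_p)
    if (!length(idx)) return(0L)
    lab <- label_components(idx, st$dim, connectivity)
    max(tabulate(lab))
  }
  cluster_of <- function(g1) {
    w <- welch_rows(V, g1, !g1)
    idx <- which(!is.na(w$p) & w$p < forming_p)
    lab <- if (length(idx)) label_components(idx, st$dim, connectivity) else integer(0)
    list(w = w, idx = idx, lab = lab)
  }

  obs_g1 <- groups == lev[1]
  obs <- cluster_of(obs_g1)

  n_arr <- choose(n, n1)
  exhaustive <- n_perm >= n_arr
  if (exhaustive) {
    message(sprintf(
      "n_perm (%d) >= distinct label arrangements (%d): using exhaustive enumeration",
      n_perm, n_arr))
    combs <- utils::combn(n, n1)
    perms <- lapply(seq_len(ncol(combs)), function(k) {
      g <- rep(FALSE, n); g[combs[, k]] <- TRUE; g
    })
  } else {
    # the observed arrangement is itself one draw from the exchangeable
    # null, so it is included; under continuity this makes the family-wise
    # error exactly cluster_alpha
    perms <- c(list(obs_g1),
               with_seed(seed, lapply(seq_len(n_perm - 1), function(k) {
                 g <- rep(FALSE, n); g[sample.int(n, n1)] <- TRUE; g
               })))
  }
  null_max <- vapply(perms, max_supra_size, integer(1))
  size_thr <- stats::quantile(null_max, 1 - cluster_alpha, type = 1, names = FALSE)

  labels_arr <- array(0L, st$dim)
  clusters <- data.frame(id = integer(0), size_vox = integer(0),
                         peak_t = numeric(0), p_cluster = numeric(0),
                         significant = logical(0))
  if (length(obs$idx)) {
    sizes <- tabulate(obs$lab)
    keep_ids <- which(sizes >= min_cluster_vox)
    ord <- keep_ids[order(sizes[keep_ids], decreasing = TRUE)]
    newid <- 0L
    for (cid in ord) {
      newid <- newid + 1L
      vox <- obs$idx[obs$lab == cid]
      sig <- sizes[cid] > size_thr
      if (sig) labels_arr[vox] <- newid
      clusters <- rbind(clusters, data.frame(
        id = newid, size_vox = sizes[cid],
        peak_t = max(abs(obs$w$t[vox])),
        p_cluster = mean(null_max >= sizes[cid]),
        significant = sig))
    }
  }
  p_map <- array(NA_real_, st$dim)
  sig_vox <- labels_arr > 0
  p_map[sig_vox] <- obs$w$p[as.vector(sig_vox)]
  structure(list(stat_map = array(obs$w$t, st$dim), p_map = p_map,
                 cluster_labels = labels_arr, clusters = clusters,
                 null_max_size = null_max, size_threshold = size_thr,
                 n_perm = length(perms), exhaustive = exhaustive,
                 forming_p = forming_p, cluster_alpha = cluster_alpha,
                 connectivity = connectivity, seed = seed, groups = lev),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d candidate cluster(s), %d significant (alpha %.2f, %d perms%s)\n",
              nrow(x$clusters), sum(x$clusters$significant), x$cluster_alpha,
              x$n_perm, if (x$exhaustive) ", exhaustive" else ""))
  invisible(x)
}

#' Bilateral symmetrization of a significance map
#'
#' Replaces the value at every voxel by the greater of its own p-value and
#' the p-value at the bilaterally symmetric position, mirrored across the
#' midsagittal plane of the declared axis. Voxels whose mirror position is
#' absent (`NA`, i.e. not significant) become absent too, so only
#' bilaterally supported voxels survive. The operation is idempotent and
#' never decreases any p-value. The mirror axis must be declared
#' explicitly; the grid is flipped about its centre along that axis (for
#' even extents the plane lies between voxel centres, mapping voxel i to
#' n + 1 - i).
#'
#' @param p_map Numeric array of p-values (`NA` = absent).
#' @param axis Mirror axis (1-based index into the array dimensions).
#' @return Symmetrized array of the same shape.
#' @export
symmetrize <- function(p_map, axis) {
  if (missing(axis)) stopf("mirror `axis` must be declared explicitly")
  d <- dim(p_map)
  if (is.null(d) || axis < 1 || axis > length(d)) stopf("invalid mirror axis")
  sel <- lapply(d, seq_len)
  sel[[axis]] <- rev(sel[[axis]])
  mirrored <- do.call(`[`, c(list(p_map), sel, list(drop = FALSE)))
  out <- pmax(p_map, mirrored)
  dim(out) <- d
  out
}

#' Voxelwise two-way ANOVA across cohorts
#'
#' Fits an additive two-way model (group + cohort) at every voxel and
#' returns the F statistic and p-value of the group main effect, with the
#' cohort acting as a blocking factor. This is how two independently
#' imaged cohorts are combined into a single voxelwise test. Voxels with
#' zero residual variance are `NA`.
#'
#' @param maps List of per-subject arrays on a shared grid.
#' @param groups Group label per subject (>= 2 levels).
#' @param cohort Cohort/blocking label per subject (>= 2 levels; with a
#'   single cohort use [voxelwise_group_stat()] instead).
#' @return List with `F_map`, `p_map`, `df` (numerator, denominator).
#' @export
voxelwise_anova <- function(maps, groups, cohort) {
  groups <- as.factor(groups); cohort <- as.factor(cohort)
  if (nlevels(cohort) < 2)
    stopf("need >= 2 cohorts; for a single cohort use voxelwise_group_stat()")
  if (nlevels(groups) < 2) stopf("need >= 2 groups")
  if (any(table(groups, cohort) == 0)) stopf("empty group x cohort cell")
  st <- stack_maps(maps)
  V <- st$V
  Xf <- stats::model.matrix(~ groups + cohort)
  Xr <- stats::model.matrix(~ cohort)
  rss <- function(X) {
    Q <- diag(nrow(X)) - X %*% solve(crossprod(X)) %*% t(X)
    rowSums((V %*% Q) * V)
  }
  rss_f <- rss(Xf); rss_r <- rss(Xr)
  df1 <- nlevels(groups) - 1
  df2 <- ncol(V) - ncol(Xf)
  Fv <- ((rss_r - rss_f) / df1) / (rss_f / df2)
  Fv[rss_f <= .Machine$double.eps * rowSums(V^2)] <- NA
  p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  list(F_map = array(Fv, st$dim), p_map = array(p, st$dim), df = c(df1, df2))
}

#' In-mask channel intensity by group
#'
#' Per-subject mean channel intensity inside a mask, group means, and the
#' percent difference of the comparison group relative to the reference:
#' `100 * (1 - mean_cmp / mean_ref)` (positive = reduction).
#'
#' @param maps List of per-subject intensity arrays.
#' @param mask Logical array.
#' @param groups Two-level group vector; the first level is the reference.
#' @return List with `per_subject` (data frame), `group_means` (named) and
#'   `percent_difference`.
#' @export
region_intensity_summary <- function(maps, mask, groups) {
  groups <- factor(groups, levels = unique(as.character(groups)))
  if (nlevels(groups) != 2) stopf("exactly two groups required")
  if (!is.logical(mask)) mask <- mask > 0
  if (!any(mask)) stopf("empty mask")
  means <- vapply(maps, function(m) mean(m[mask]), numeric(1))
  gm <- tapply(means, groups, mean)
  per_subject <- data.frame(subject = seq_along(means), group = groups,
                            mask_mean = means)
  list(per_subject = per_subject, group_means = gm,
       percent_difference = 100 * (1 - gm[[2]] / gm[[1]]))
}
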