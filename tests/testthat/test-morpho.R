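test_that("log Jacobian matches closed forms for identity and scalings", {
  shape <- c(10, 10, 6); vs <- c(2, 2, 4)
  expect_true(all(log_jacobian(array(0, c(shape, 3)), vs) == 0))
  for (s in c(0.9, 1.05, 1.3)) {
    lj <- log_jacobian(scaling_field(shape, vs, s), vs)
    expect_lt(max(abs(lj - 3 * log(s))), 1e-6)
  }
  # additivity: composing uniform scalings s1 then s2 scales by s1*s2
  s1 <- 1.1; s2 <- 0.95
  lj12 <- log_jacobian(scaling_field(shape, vs, s1 * s2), vs)
  expect_lt(max(abs(lj12 - 3 * log(s1 * s2))), 1e-6)
})

test_that("log Jacobian agrees with a per-voxel determinant oracle", {
  set.seed(4)
  shape <- c(8, 8, 6); vs <- c(2, 2, 3)
  u <- array(0, c(shape, 3))
  for (i in 1:3) u[, , , i] <-
    2 * larvaquant:::gauss_smooth_array(array(rnorm(prod(shape)), shape), 2)
  lj <- log_jacobian(u, vs)
  # oracle: assemble the local Jacobian numerically and use base det()
  grad1 <- function(f, i, j, k, ax) {
    idx <- c(i, j, k)
    lo <- idx; hi <- idx
    hi[ax] <- min(shape[ax], idx[ax] + 1); lo[ax] <- max(1, idx[ax] - 1)
    (f[hi[1], hi[2], hi[3]] - f[lo[1], lo[2], lo[3]]) /
      ((hi[ax] - lo[ax]) * vs[ax])
  }
  for (pt in list(c(4, 4, 3), c(1, 1, 1), c(8, 5, 6), c(2, 7, 4))) {
    J <- diag(3)
    for (a in 1:3) for (b in 1:3)
      J[a, b] <- J[a, b] + grad1(u[, , , a], pt[1], pt[2], pt[3], b)
    expect_equal(lj[pt[1], pt[2], pt[3]], log(det(J)), tolerance = 1e-9)
  }
})

test_that("non-invertible local Jacobians are flagged, not propagated", {
  shape <- c(6, 6, 4); vs <- c(1, 1, 1)
  u <- scaling_field(shape, vs, -0.2)  # fold-over: det < 0 everywhere
  lj <- log_jacobian(u, vs)
  expect_true(all(is.na(lj)))
  expect_equal(attr(lj, "n_flagged"), prod(shape))
})

test_that("mask volumes integrate exp(LJD) over the reference mask", {
  shape <- c(12, 12, 8); vs <- c(2, 2, 4)
  brain <- array(TRUE, shape)
  mask <- array(FALSE, shape); mask[4:9, 4:9, 3:6] <- TRUE
  zero <- array(0, shape)
  mv0 <- mask_volume(zero, mask, brain, voxel_size_um = vs)
  expect_equal(mv0$mask_volume_um3, sum(mask) * prod(vs))
  contracted <- zero; contracted[mask] <- log(0.92)
  mv <- mask_volume(contracted, mask, brain, voxel_size_um = vs)
  expect_equal(mv$mask_volume_um3 / mv0$mask_volume_um3, 0.92, tolerance = 1e-12)
  # segmentation mode counts voxels
  seg <- mask
  mvs <- mask_volume(seg, mask, brain, voxel_size_um = vs)
  expect_equal(mvs$mask_volume_um3, sum(mask) * prod(vs))
  expect_error(mask_volume(zero, array(FALSE, shape), brain, voxel_size_um = vs),
               "empty mask")
})

test_that("whole-grid volume is conserved against the planted total", {
  vp <- volume_sim_params(grid_shape = c(14, 14, 10), n_subjects_per_group = 1,
                          planted_contraction = list(mut = c(brain = 0.939,
                                                             MHB = 0.92)),
                          noise_sd = 0)
  vol <- simulate_volumes(vp)
  s <- vol$subjects[["mut_01"]]
  vv <- prod(vol$voxel_size_um)
  br <- vol$masks$brain; mhb <- vol$masks$MHB
  planted <- (sum(br) - sum(mhb)) * 0.939 * vv + sum(mhb) * 0.939 * 0.92 * vv
  expect_equal(sum(exp(s$ljd[br])) * vv, planted, tolerance = 1e-9)
})

test_that("voxelwise Welch t matches t.test and is null-calibrated", {
  set.seed(12)
  shape <- c(9, 9, 5)
  maps <- lapply(1:12, function(i) array(rnorm(prod(shape)), shape))
  grp <- rep(c("wt", "mut"), each = 6)
  vs <- voxelwise_group_stat(maps, grp)
  # oracle: stats::t.test at a few voxels
  for (pt in list(c(1, 1, 1), c(5, 4, 3), c(9, 9, 5))) {
    a <- vapply(maps[1:6], function(m) m[pt[1], pt[2], pt[3]], numeric(1))
    b <- vapply(maps[7:12], function(m) m[pt[1], pt[2], pt[3]], numeric(1))
    tt <- t.test(a, b)
    expect_equal(vs$t_map[pt[1], pt[2], pt[3]], unname(tt$statistic),
                 tolerance = 1e-9)
    expect_equal(vs$p_map[pt[1], pt[2], pt[3]], tt$p.value, tolerance = 1e-9)
  }
  # null calibration: ~5% of voxels nominally significant
  expect_lt(abs(mean(vs$p_map < 0.05) - 0.05), 0.02)
  expect_error(voxelwise_group_stat(maps[1:2], c("a", "b")), ">= 2 subjects")
  # a planted 3-SD shift dominates the statistic map
  maps2 <- maps
  for (i in 7:12) maps2[[i]][3:5, 3:5, 2:3] <- maps2[[i]][3:5, 3:5, 2:3] + 3
  vs2 <- voxelwise_group_stat(maps2, grp)
  hot <- array(FALSE, shape); hot[3:5, 3:5, 2:3] <- TRUE
  expect_gt(mean(abs(vs2$t_map[hot])), 2 * mean(abs(vs2$t_map[!hot])))
})

test_that("permutation cluster inference recovers a planted contraction", {
  vp <- volume_sim_params(
    grid_shape = c(16, 16, 8), n_subjects_per_group = 8,
    region_masks = list(MHB = list(center = c(0.5, 0.62, 0.55),
                                   semi_axes = c(0.28, 0.18, 0.22))),
    planted_contraction = list(mut = c(MHB = 0.8)), noise_sd = 0.05, seed = 2)
  vol <- simulate_volumes(vp)
  maps <- lapply(vol$subjects, function(s) s$ljd)
  grp <- vapply(vol$subjects, function(s) s$group, character(1))
  pc <- permutation_cluster(maps, grp, n_perm = 500, seed = 9)
  expect_true(any(pc$clusters$significant))
  planted <- which(vol$masks$MHB)
  covered <- mean(planted %in% which(pc$cluster_labels > 0))
  expect_gte(covered, 0.8)
  # labelled voxels all pass the forming threshold
  lab <- which(pc$cluster_labels > 0)
  expect_true(all(pc$p_map[lab] < pc$forming_p))
  # deterministic under the seed
  pc2 <- permutation_cluster(maps, grp, n_perm = 500, seed = 9)
  expect_identical(pc$cluster_labels, pc2$cluster_labels)
})

test_that("small designs switch to exhaustive enumeration with a notice", {
  set.seed(3)
  shape <- c(6, 6, 4)
  maps <- lapply(1:6, function(i) array(rnorm(prod(shape)), shape))
  grp <- rep(c("a", "b"), each = 3)
  expect_message(pc <- permutation_cluster(maps, grp, n_perm = 100, seed = 1),
                 "exhaustive")
  expect_true(pc$exhaustive)
  expect_equal(pc$n_perm, choose(6, 3))
})

test_that("symmetrization takes the greater bilateral p and is idempotent", {
  p <- array(NA_real_, c(4, 3, 2))
  p[1, 2, 1] <- 0.01; p[4, 2, 1] <- 0.04  # mirror pair along axis 1
  s <- symmetrize(p, axis = 1)
  expect_equal(s[1, 2, 1], 0.04)
  expect_equal(s[4, 2, 1], 0.04)
  expect_identical(symmetrize(s, axis = 1), s)
  # never decreases any p-value
  set.seed(6)
  q <- array(runif(4 * 3 * 2), c(4, 3, 2))
  sq <- symmetrize(q, axis = 1)
  expect_true(all(sq >= q))
  # unilateral significance does not survive
  u <- array(NA_real_, c(4, 3, 2)); u[1, 1, 1] <- 0.01
  expect_true(all(is.na(symmetrize(u, axis = 1))))
  expect_error(symmetrize(q), "axis")
})

test_that("voxelwise ANOVA matches aov and absorbs cohort offsets", {
  set.seed(14)
  shape <- c(7, 7, 4)
  n_per <- 5
  grp <- rep(rep(c("wt", "mut"), each = n_per), 2)
  coh <- rep(c("c1", "c2"), each = 2 * n_per)
  maps <- lapply(seq_along(grp), function(i) {
    base <- array(rnorm(prod(shape)), shape)
    base + ifelse(coh[i] == "c2", 5, 0)  # strong cohort offset
  })
  va <- voxelwise_anova(maps, grp, coh)
  # oracle: stats::aov at a few voxels
  for (pt in list(c(1, 1, 1), c(4, 4, 2), c(7, 7, 4))) {
    y <- vapply(maps, function(m) m[pt[1], pt[2], pt[3]], numeric(1))
    an <- summary(aov(y ~ factor(grp) + factor(coh)))[[1]]
    expect_equal(va$F_map[pt[1], pt[2], pt[3]], an["factor(grp)", "F value"],
                 tolerance = 1e-8)
    expect_equal(va$p_map[pt[1], pt[2], pt[3]], an["factor(grp)", "Pr(>F)"],
                 tolerance = 1e-8)
  }
  # null: ~5% nominal positives despite the cohort offset
  expect_lt(abs(mean(va$p_map < 0.05) - 0.05), 0.025)
  # planted group effect present in both cohorts is detected
  maps2 <- maps
  for (i in which(grp == "mut")) maps2[[i]] <- maps2[[i]] + 2
  va2 <- voxelwise_anova(maps2, grp, coh)
  expect_gt(mean(va2$p_map < 0.01), 0.5)
  expect_error(voxelwise_anova(maps, grp, rep("c1", length(grp))),
               "voxelwise_group_stat")
})

test_that("region intensity summaries report percent group differences", {
  shape <- c(8, 8, 4)
  mask <- array(FALSE, shape); mask[3:6, 3:6, 2:3] <- TRUE
  flat <- lapply(1:6, function(i) array(100, shape))
  grp <- rep(c("wt", "mut"), each = 3)
  expect_equal(region_intensity_summary(flat, mask, grp)$percent_difference, 0)
  dim_maps <- c(flat[1:3], lapply(1:3, function(i) {
    m <- array(100, shape); m[mask] <- 95; m
  }))
  ri <- region_intensity_summary(dim_maps, mask, grp)
  expect_equal(ri$percent_difference, 5, tolerance = 1e-12)
  expect_equal(unname(ri$group_means["wt"]), 100)
})

test_that("noisy planted intensity effects are covered by the group CI", {
  vp <- volume_sim_params(
    grid_shape = c(14, 14, 8), n_subjects_per_group = 15,
    planted_intensity_scale = list(mut = list(gad1b = c(subpallium = 0.95))),
    noise_sd = 0.02, seed = 8)
  vol <- simulate_volumes(vp)
  grp <- vapply(vol$subjects, function(s) s$group, character(1))
  mask <- vol$masks$subpallium
  means <- vapply(vol$subjects, function(s) mean(s$channels$gad1b[mask]),
                  numeric(1))
  wt <- means[grp == "wt"]; mut <- means[grp == "mut"]
  ci <- t.test(wt, mut)$conf.int  # CI on the mean difference
  ci_pct <- 100 * ci / mean(wt)
  expect_gte(5, ci_pct[1])
  expect_lte(5, ci_pct[2])
})
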