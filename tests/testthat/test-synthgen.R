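test_that("conduction bookkeeping is exact for integer ratios at zero noise", {
  for (ratio in c(1, 2, 3)) {
    tr <- simulate_cardiac_trace(
      cardiac_sim_params(120, conduction_ratio = ratio, duration_s = 30))
    gt <- attr(tr, "ground_truth")
    expect_equal(gt$n_atrial_beats, 60)
    expect_equal(gt$n_ventricular_beats, 60 / ratio)
  }
})

test_that("intermediate ratios reach their long-run conduction ratio", {
  tr <- simulate_cardiac_trace(
    cardiac_sim_params(120, conduction_ratio = 1.5, duration_s = 300))
  gt <- attr(tr, "ground_truth")
  expect_lt(abs(gt$n_atrial_beats / gt$n_ventricular_beats - 1.5), 0.01)
  # Bernoulli conduction converges too, within binomial error
  trb <- simulate_cardiac_trace(
    cardiac_sim_params(180, conduction_ratio = 1.5, duration_s = 300,
                       conduction = "bernoulli", seed = 4))
  gtb <- attr(trb, "ground_truth")
  n <- gtb$n_atrial_beats
  se <- sqrt(n * (2 / 3) * (1 / 3))
  expect_lt(abs(gtb$n_ventricular_beats - n / 1.5), 4 * se)
})

test_that("simulators are bit-identical under a fixed seed", {
  p <- cardiac_sim_params(150, 2, duration_s = 20, noise_sd = 0.15, seed = 42)
  expect_identical(simulate_cardiac_trace(p), simulate_cardiac_trace(p))
  tp <- track_sim_params(n_larvae_per_group = 2,
                         group_labels = data.frame(genotype = "wt",
                                                   treatment = "vehicle"),
                         phase_durations_s = c(30, 30),
                         seizure_burst_rate_per_min = 1, seed = 7)
  expect_identical(simulate_tracks(tp), simulate_tracks(tp))
  vp <- volume_sim_params(grid_shape = c(10, 10, 6), n_subjects_per_group = 2,
                          noise_sd = 0.1, seed = 3)
  expect_identical(simulate_volumes(vp), simulate_volumes(vp))
  gp <- gcamp_sim_params(noise_sd = 1, seed = 5)
  expect_identical(simulate_gcamp(gp), simulate_gcamp(gp))
  # a different seed changes the noise
  p2 <- cardiac_sim_params(150, 2, duration_s = 20, noise_sd = 0.15, seed = 43)
  expect_false(identical(simulate_cardiac_trace(p)$atrium,
                         simulate_cardiac_trace(p2)$atrium))
})

test_that("a mid-recording regime switch changes the conducted fraction", {
  tr <- simulate_cardiac_trace(
    cardiac_sim_params(120, conduction_ratio = 1, duration_s = 60,
                       switch_time_s = 30, switch_ratio = 2))
  gt <- attr(tr, "ground_truth")
  # 60 matched beats in the first half, ~30 conducted of 60 in the second
  expect_equal(gt$n_atrial_beats, 120)
  expect_equal(gt$n_ventricular_beats, 90)
})

test_that("invalid simulator parameters are rejected with clear messages", {
  expect_error(cardiac_sim_params(120, conduction_ratio = 0.5), "ratio")
  expect_error(cardiac_sim_params(120, duration_s = 0.4), "too short")
  expect_error(cardiac_sim_params(1, duration_s = 30), "single beat")
  expect_error(cardiac_sim_params(120, switch_time_s = 10), "switch_ratio")
  expect_error(track_sim_params(bout_displacement_mm = c(2, 0.3),
                                seizure_displacement_mm = c(1.5, 0.2)),
               "strictly exceed")
  expect_error(volume_sim_params(planted_contraction = list(mut = c(nowhere = 0.9))),
               "unknown region")
  expect_error(volume_sim_params(planted_contraction = list(mut = c(MHB = -1))),
               "> 0")
  expect_error(simulate_av_cohort(numeric(0)), "empty")
})

test_that("quiescent tracks stay put and all tracks respect the arena", {
  quiet <- track_sim_params(n_larvae_per_group = 2,
                            group_labels = data.frame(genotype = "wt",
                                                      treatment = "vehicle"),
                            phase_durations_s = c(30, 30), bout_rate_hz = 0,
                            seizure_burst_rate_per_min = 0)
  tk <- simulate_tracks(quiet)
  wd <- window_distances(tk)
  expect_true(all(wd$distance_mm == 0))

  busy <- track_sim_params(n_larvae_per_group = 3,
                           group_labels = data.frame(genotype = "wt",
                                                     treatment = "vehicle"),
                           phase_durations_s = c(60, 60), bout_rate_hz = 0.5,
                           seizure_burst_rate_per_min = 3, seed = 2)
  tk2 <- simulate_tracks(busy)
  expect_true(all(tk2$x_mm >= 0 & tk2$x_mm <= 7))
  expect_true(all(tk2$y_mm >= 0 & tk2$y_mm <= 7))
  # per-frame displacement never exceeds the arena diagonal
  for (sp in split(tk2, tk2$larva_id)) {
    step <- sqrt(diff(sp$x_mm)^2 + diff(sp$y_mm)^2)
    expect_lt(max(step), 7 * sqrt(2))
  }
})

test_that("planted burst counts follow the programmed Poisson rate", {
  rate <- 2  # per minute
  tp <- track_sim_params(n_larvae_per_group = 20,
                         group_labels = data.frame(genotype = "mut",
                                                   treatment = "ptz"),
                         phase_durations_s = c(300, 0), bout_rate_hz = 0.1,
                         seizure_burst_rate_per_min = rate, seed = 11)
  tk <- simulate_tracks(tp)
  gt <- attr(tk, "ground_truth")
  total <- sum(gt$n_burst_windows)
  expected <- 20 * 5 * rate  # larvae x minutes x rate
  expect_lt(abs(total - expected), 4 * sqrt(expected))
})

test_that("planted volumetric and intensity effects are exact at zero noise", {
  vp <- volume_sim_params(grid_shape = c(16, 16, 10), n_subjects_per_group = 1,
                          planted_contraction = list(mut = c(MHB = 0.92)),
                          planted_intensity_scale =
                            list(mut = list(gad1b = c(subpallium = 0.95))),
                          noise_sd = 0)
  vol <- simulate_volumes(vp)
  wt <- vol$subjects[["wt_01"]]; mut <- vol$subjects[["mut_01"]]
  expect_true(all(wt$ljd == 0))
  mk <- vol$masks$MHB
  vv <- prod(vol$voxel_size_um)
  # region-integrated exp(LJD) equals planted factor x region volume
  expect_equal(sum(exp(mut$ljd[mk])) * vv, 0.92 * sum(mk) * vv,
               tolerance = 1e-9)
  sp <- vol$masks$subpallium
  expect_equal(mean(mut$channels$gad1b[sp]) / mean(wt$channels$gad1b[sp]),
               0.95, tolerance = 1e-12)
  # region masks are subsets of the brain mask
  for (r in c("MHB", "subpallium", "cellular"))
    expect_true(all(!vol$masks[[r]] | vol$masks$brain))
})

test_that("fluorescence series have the programmed span and event amplitude", {
  g0 <- simulate_gcamp(gcamp_sim_params(event_rate = 0, noise_sd = 0))
  expect_true(all(g0$data == 100))
  expect_equal(dim(g0$data)[3] / g0$frame_rate_hz, 300)  # 5 min at 0.5 Hz
  g1 <- simulate_gcamp(gcamp_sim_params(event_rate = 0.3, noise_sd = 0,
                                        event_amplitude_frac = 0.5, seed = 3))
  gt <- attr(g1, "ground_truth")
  m <- dff_map(g1)
  expect_true(all(abs(m$values[unique(gt$voxel)] - 50) < 1e-12))
  expect_true(all(m$values[-unique(gt$voxel)] == 0))
})
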