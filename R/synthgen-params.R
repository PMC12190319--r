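#' Parameters for the dual-chamber cardiac trace simulator
#'
#' Defines a quasi-periodic two-chamber contraction recording: the atrium
#' beats at a programmed rate and the ventricle follows according to a
#' conduction ratio (1 = matched 1:1 rhythm, 2 = 2:1 atrioventricular block,
#' non-integer values give intermediate n:1 rhythms). An optional regime
#' switch changes the conduction ratio mid-recording, emulating the abrupt
#' transitions seen in intermittently arrhythmic larvae.
#'
#' @param atrial_rate_bpm Atrial contraction rate in beats per minute.
#' @param conduction_ratio Atrial beats per ventricular beat (>= 1).
#' @param duration_s Recording duration in seconds.
#' @param sample_rate_hz Sampling rate of the intensity trace (default 100,
#'   the frame rate of high-speed cardiac video).
#' @param noise_sd Standard deviation of additive Gaussian noise, as a
#'   fraction of the pulse amplitude.
#' @param switch_time_s Optional time (s) at which the conduction regime
#'   changes; requires `switch_ratio`.
#' @param switch_ratio Conduction ratio in force after `switch_time_s`.
#' @param conduction How non-integer ratios are realised: `"regular"`
#'   (deterministic phase-accumulator conduction whose long-run ratio equals
#'   `conduction_ratio` exactly) or `"bernoulli"` (each atrial beat conducts
#'   independently with probability 1/ratio).
#' @param seed Integer RNG seed.
#' @return An object of class `cardiac_sim_params`.
#' @seealso [simulate_cardiac_trace()]
#' @export
cardiac_sim_params <- function(atrial_rate_bpm, conduction_ratio = 1,
                               duration_s = 30, sample_rate_hz = 100,
                               noise_sd = 0, switch_time_s = NULL,
                               switch_ratio = NULL,
                               conduction = c("regular", "bernoulli"),
                               seed = 1L) {
  check_positive(atrial_rate_bpm, "atrial_rate_bpm")
  check_positive(duration_s, "duration_s")
  check_positive(sample_rate_hz, "sample_rate_hz")
  check_nonnegative(noise_sd, "noise_sd")
  if (!is.numeric(conduction_ratio) || conduction_ratio < 1)
    stopf("`conduction_ratio` must be >= 1 (got %s)", format(conduction_ratio))
  if (duration_s * sample_rate_hz < 256)
    stopf("trace too short: need at least 256 samples, got %d",
          as.integer(duration_s * sample_rate_hz))
  if (duration_s < 60 / atrial_rate_bpm)
    stopf("duration too short for a single beat at %g bpm", atrial_rate_bpm)
  if (!is.null(switch_time_s)) {
    if (is.null(switch_ratio)) stopf("`switch_ratio` required with `switch_time_s`")
    if (switch_ratio < 1) stopf("`switch_ratio` must be >= 1")
    if (switch_time_s <= 0 || switch_time_s >= duration_s)
      stopf("`switch_time_s` must fall inside the recording")
  }
  structure(list(atrial_rate_bpm = atrial_rate_bpm,
                 conduction_ratio = conduction_ratio,
                 duration_s = duration_s, sample_rate_hz = sample_rate_hz,
                 noise_sd = noise_sd, switch_time_s = switch_time_s,
                 switch_ratio = switch_ratio,
                 conduction = match.arg(conduction),
                 seed = as.integer(seed)),
            class = "cardiac_sim_params")
}

#' Parameters for the locomotor track simulator
#'
#' Describes bout-structured larval swimming in a square arena: long
#' immobility interrupted by brief swim bouts, plus rare high-displacement
#' seizure-like bursts planted at a programmable rate. Recordings span an
#' illuminated phase followed by a dark phase.
#'
#' @param n_larvae_per_group Larvae per (genotype, treatment) group.
#' @param group_labels Data frame with columns `genotype` and `treatment`;
#'   one row per group.
#' @param phase_durations_s Durations (s) of the illuminated and dark phase.
#' @param sample_rate_hz Tracking rate (default 10 Hz).
#' @param arena_mm Side length of the square well (default 7 mm).
#' @param bout_rate_hz Baseline swim-bout rate per second.
#' @param bout_displacement_mm Length-2 numeric `c(location, scale)` of the
#'   truncated-normal per-bout displacement (mm).
#' @param seizure_burst_rate_per_min Burst rate per minute; either a single
#'   number applied to every group or a numeric vector named by
#'   `"genotype.treatment"`.
#' @param seizure_displacement_mm `c(location, scale)` of the per-burst
#'   displacement; its location must strictly exceed the baseline bout
#'   location so planted ground truth is well defined.
#' @param seed Integer RNG seed.
#' @return An object of class `track_sim_params`.
#' @seealso [simulate_tracks()]
#' @export
track_sim_params <- function(n_larvae_per_group = 12,
                             group_labels = data.frame(
                               genotype = c("wt", "het", "mut"),
                               treatment = "vehicle"),
                             phase_durations_s = c(900, 900),
                             sample_rate_hz = 10, arena_mm = 7,
                             bout_rate_hz = 0.2,
                             bout_displacement_mm = c(1.2, 0.3),
                             seizure_burst_rate_per_min = 0,
                             seizure_displacement_mm = c(10, 1),
                             seed = 1L) {
  check_positive(n_larvae_per_group, "n_larvae_per_group")
  if (!is.data.frame(group_labels) ||
      !all(c("genotype", "treatment") %in% names(group_labels)))
    stopf("`group_labels` needs columns genotype and treatment")
  check_nonnegative(phase_durations_s, "phase_durations_s")
  if (length(phase_durations_s) != 2 || sum(phase_durations_s) <= 0)
    stopf("`phase_durations_s` must be two durations with positive total")
  check_positive(sample_rate_hz, "sample_rate_hz")
  check_positive(arena_mm, "arena_mm")
  check_nonnegative(bout_rate_hz, "bout_rate_hz")
  check_nonnegative(seizure_burst_rate_per_min, "seizure_burst_rate_per_min")
  if (seizure_displacement_mm[1] <= bout_displacement_mm[1])
    stopf("burst displacement location (%g) must strictly exceed baseline bout location (%g)",
          seizure_displacement_mm[1], bout_displacement_mm[1])
  structure(list(n_larvae_per_group = as.integer(n_larvae_per_group),
                 group_labels = group_labels,
                 phase_durations_s = phase_durations_s,
                 sample_rate_hz = sample_rate_hz, arena_mm = arena_mm,
                 bout_rate_hz = bout_rate_hz,
                 bout_displacement_mm = bout_displacement_mm,
                 seizure_burst_rate_per_min = seizure_burst_rate_per_min,
                 seizure_displacement_mm = seizure_displacement_mm,
                 seed = as.integer(seed)),
            class = "track_sim_params")
}

#' Parameters for the volumetric morphometry simulator
#'
#' Describes cohorts of registered per-subject volumes on a shared reference
#' grid: a brain mask (ellipsoid), named region masks (sub-ellipsoids), and
#' per-group planted effects. Volumetric effects are planted as a constant
#' log-Jacobian ln(f) inside a region, so the region-integrated local volume
#' factor equals the planted factor f exactly at zero noise. Intensity
#' effects multiply the in-region channel intensity.
#'
#' Region specifications are lists with elements `center` (fractional grid
#' coordinates) and `semi_axes` (fractional semi-axis lengths).
#'
#' @param grid_shape Integer triple, reference grid dimensions.
#' @param voxel_size_um Positive triple, voxel spacing in micrometres.
#' @param brain_mask_spec Ellipsoid spec for the whole-brain mask.
#' @param region_masks Named list of ellipsoid specs; defaults provide
#'   `"MHB"` (midbrain-hindbrain boundary-like), `"subpallium"` and
#'   `"cellular"` regions inside the brain mask.
#' @param n_subjects_per_group Subjects per group.
#' @param groups Character vector of group labels.
#' @param planted_contraction Named list: group -> named numeric of
#'   region -> volumetric scale factor (use region `"brain"` for a global
#'   factor). Factor f < 1 plants a contraction.
#' @param planted_intensity_scale Named list: group -> list of
#'   channel -> named numeric region -> intensity factor.
#' @param baseline_intensity In-brain baseline channel intensity.
#' @param channels Channel names to generate.
#' @param field_smoothness_vox Gaussian sigma (voxels) of the smooth noise
#'   fields.
#' @param noise_sd Noise standard deviation (log-Jacobian units for the LJD
#'   channel; fraction of baseline for intensity channels).
#' @param seed Integer RNG seed.
#' @return An object of class `volume_sim_params`.
#' @seealso [simulate_volumes()]
#' @export
volume_sim_params <- function(grid_shape = c(32, 32, 16),
                              voxel_size_um = c(4, 4, 8),
                              brain_mask_spec = list(center = c(0.5, 0.5, 0.5),
                                                     semi_axes = c(0.42, 0.42, 0.42)),
                              region_masks = list(
                                MHB = list(center = c(0.5, 0.62, 0.55),
                                           semi_axes = c(0.16, 0.08, 0.10)),
                                subpallium = list(center = c(0.5, 0.28, 0.45),
                                                  semi_axes = c(0.14, 0.10, 0.12)),
                                cellular = list(center = c(0.5, 0.45, 0.5),
                                                semi_axes = c(0.30, 0.28, 0.28))),
                              n_subjects_per_group = 10,
                              groups = c("wt", "mut"),
                              planted_contraction = list(),
                              planted_intensity_scale = list(),
                              baseline_intensity = 100,
                              channels = c("tuba", "gad1b"),
                              field_smoothness_vox = 1.5,
                              noise_sd = 0, seed = 1L) {
  if (length(grid_shape) != 3 || any(grid_shape < 4))
    stopf("`grid_shape` must be a triple of integers >= 4")
  check_positive(voxel_size_um, "voxel_size_um")
  check_positive(n_subjects_per_group, "n_subjects_per_group")
  check_nonnegative(noise_sd, "noise_sd")
  check_positive(field_smoothness_vox, "field_smoothness_vox")
  known <- c("brain", names(region_masks))
  for (g in names(planted_contraction)) {
    if (!g %in% groups) stopf("planted contraction for unknown group '%s'", g)
    f <- planted_contraction[[g]]
    if (any(f <= 0)) stopf("planted scale factors must be > 0")
    bad <- setdiff(names(f), known)
    if (length(bad)) stopf("unknown region '%s' in planted_contraction", bad[1])
  }
  for (g in names(planted_intensity_scale)) {
    if (!g %in% groups) stopf("planted intensity for unknown group '%s'", g)
    for (ch in names(planted_intensity_scale[[g]])) {
      f <- planted_intensity_scale[[g]][[ch]]
      if (any(f <= 0)) stopf("planted scale factors must be > 0")
      bad <- setdiff(names(f), known)
      if (length(bad)) stopf("unknown region '%s' in planted_intensity_scale", bad[1])
    }
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_um = voxel_size_um,
                 brain_mask_spec = brain_mask_spec,
                 region_masks = region_masks,
                 n_subjects_per_group = as.integer(n_subjects_per_group),
                 groups = groups,
                 planted_contraction = planted_contraction,
                 planted_intensity_scale = planted_intensity_scale,
                 baseline_intensity = baseline_intensity,
                 channels = channels,
                 field_smoothness_vox = field_smoothness_vox,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "volume_sim_params")
}

#' Parameters for the slow-rate fluorescence series simulator
#'
#' Emulates epifluorescent whole-brain calcium-indicator recordings: a
#' per-voxel baseline with sparse transient events of programmable relative
#' amplitude, recorded at a slow frame rate (default 0.5 Hz for 5 minutes).
#'
#' @param grid_shape Integer pair (widefield) or triple (volumetric).
#' @param n_frames Number of frames (default 150; 150 frames at 0.5 Hz span
#'   5 minutes).
#' @param frame_rate_hz Acquisition rate (default 0.5).
#' @param baseline_level Per-voxel baseline fluorescence.
#' @param event_amplitude_frac Event amplitude as a fraction of baseline.
#' @param event_rate Expected number of events per voxel over the recording.
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param seed Integer RNG seed.
#' @return An object of class `gcamp_sim_params`.
#' @seealso [simulate_gcamp()]
#' @export
gcamp_sim_params <- function(grid_shape = c(16, 16), n_frames = 150,
                             frame_rate_hz = 0.5, baseline_level = 100,
                             event_amplitude_frac = 0.5, event_rate = 0.5,
                             noise_sd = 0, seed = 1L) {
  if (!length(grid_shape) %in% 2:3 || any(grid_shape < 1))
    stopf("`grid_shape` must be a pair or triple of positive integers")
  if (n_frames < 2) stopf("need at least 2 frames")
  check_positive(frame_rate_hz, "frame_rate_hz")
  check_positive(baseline_level, "baseline_level")
  check_nonnegative(event_amplitude_frac, "event_amplitude_frac")
  check_nonnegative(event_rate, "event_rate")
  check_nonnegative(noise_sd, "noise_sd")
  structure(list(grid_shape = as.integer(grid_shape),
                 n_frames = as.integer(n_frames),
                 frame_rate_hz = frame_rate_hz,
                 baseline_level = baseline_level,
                 event_amplitude_frac = event_amplitude_frac,
                 event_rate = event_rate, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "gcamp_sim_params")
}
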