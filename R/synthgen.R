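#' Construct a dual-chamber cardiac trace object
#'
#' Paired atrial and ventricular mean-intensity time series sampled at a
#' fixed rate, the unit of analysis for all cardiac rhythm operations.
#'
#' @param time_s Monotone time stamps (s).
#' @param atrium,ventricle Intensity series (arbitrary units).
#' @param sample_rate_hz Sampling rate (Hz), consistent with `time_s`.
#' @param subject_id,recording_id Labels.
#' @return An object of class `dual_chamber_trace`.
#' @export
dual_chamber_trace <- function(time_s, atrium, ventricle, sample_rate_hz,
                               subject_id = "s1", recording_id = "r1") {
  n <- length(time_s)
  if (length(atrium) != n || length(ventricle) != n)
    stopf("time and chamber series must have equal lengths")
  if (n > 1 && any(diff(time_s) <= 0)) stopf("`time_s` must be strictly increasing")
  if (!all(is.finite(atrium)) || !all(is.finite(ventricle)))
    stopf("intensities must be finite")
  check_positive(sample_rate_hz, "sample_rate_hz")
  if (n > 1) {
    dt <- stats::median(diff(time_s))
    if (abs(dt - 1 / sample_rate_hz) > 0.01 / sample_rate_hz)
      stopf("time stamps inconsistent with sample_rate_hz")
  }
  structure(list(time_s = time_s, atrium = atrium, ventricle = ventricle,
                 sample_rate_hz = sample_rate_hz, subject_id = subject_id,
                 recording_id = recording_id),
            class = "dual_chamber_trace")
}

#' @export
as.data.frame.dual_chamber_trace <- function(x, ...) {
  data.frame(time_s = x$time_s, atrium = x$atrium, ventricle = x$ventricle)
}

#' @export
print.dual_chamber_trace <- function(x, ...) {
  cat(sprintf("<dual_chamber_trace> %s/%s: %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$recording_id, length(x$time_s),
              x$sample_rate_hz, length(x$time_s) / x$sample_rate_hz))
  invisible(x)
}

# Render a train of raised-cosine pulses (centers `tc`, width `w` seconds)
# onto the sample grid `t`. Only pulse timing is analysed downstream, so a
# smooth unimodal waveform suffices.
render_pulses <- function(t, tc, w) {
  y <- numeric(length(t))
  half <- w / 2
  for (c0 in tc) {
    i <- which(t > c0 - half & t < c0 + half)
    if (length(i)) y[i] <- y[i] + 0.5 * (1 + cos(2 * pi * (t[i] - c0) / w))
  }
  y
}

#' Simulate a dual-chamber cardiac intensity trace
#'
#' Generates a quasi-periodic atrial pulse train at the programmed rate and a
#' ventricular train that follows per the conduction ratio. Integer ratios
#' conduct every k-th atrial beat exactly; non-integer ratios are realised
#' either by deterministic phase-accumulator conduction (default; the
#' long-run atrium:ventricle beat ratio equals the programmed ratio) or by
#' independent Bernoulli conduction with probability 1/ratio. After
#' `switch_time_s` the conduction regime changes to `switch_ratio`. Additive
#' Gaussian noise is scaled to the unit pulse amplitude. Output is
#' bit-identical under a fixed seed.
#'
#' @param params A [cardiac_sim_params()] object.
#' @param subject_id,recording_id Labels attached to the trace.
#' @return A [dual_chamber_trace()] with attribute `"ground_truth"`: a list
#'   with the planted beat counts (`n_atrial_beats`, `n_ventricular_beats`),
#'   conduction ratio(s) and the true AV class per regime.
#' @examples
#' tr <- simulate_cardiac_trace(cardiac_sim_params(120, conduction_ratio = 2))
#' attr(tr, "ground_truth")$n_ventricular_beats
#' @export
simulate_cardiac_trace <- function(params, subject_id = "s1", recording_id = "r1") {
  stopifnot(inherits(params, "cardiac_sim_params"))
  p <- params
  fs <- p$sample_rate_hz
  n <- round(p$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  period <- 60 / p$atrial_rate_bpm
  k <- 0:floor(p$duration_s / period)
  centers <- (k + 0.5) * period
  centers <- centers[centers <= p$duration_s]
  ratio_at <- rep(p$conduction_ratio, length(centers))
  if (!is.null(p$switch_time_s)) ratio_at[centers >= p$switch_time_s] <- p$switch_ratio

  with_seed(p$seed, {
    conducted <- logical(length(centers))
    if (p$conduction == "regular") {
      acc <- 0; done <- 0L
      for (i in seq_along(centers)) {
        acc <- acc + 1 / ratio_at[i]
        if (floor(acc + 1e-12) > done) {
          conducted[i] <- TRUE
          done <- done + 1L
        }
      }
    } else {
      conducted <- stats::runif(length(centers)) < 1 / ratio_at
    }
    w <- 0.45 * period
    atrium <- render_pulses(t, centers, w)
    v_centers <- centers[conducted] + 0.25 * period
    ventricle <- render_pulses(t, v_centers, w)
    if (p$noise_sd > 0) {
      atrium <- atrium + stats::rnorm(n, 0, p$noise_sd)
      ventricle <- ventricle + stats::rnorm(n, 0, p$noise_sd)
    }
  })

  tr <- dual_chamber_trace(t, atrium, ventricle, fs, subject_id, recording_id)
  attr(tr, "ground_truth") <- list(
    n_atrial_beats = length(centers),
    n_ventricular_beats = sum(conducted),
    conduction_ratio = p$conduction_ratio,
    switch_ratio = p$switch_ratio,
    true_class = av_class_from_ratio(p$conduction_ratio))
  tr
}

# Planted AV class implied by a programmed conduction ratio.
av_class_from_ratio <- function(ratio) {
  if (abs(ratio - 1) < 1e-9) "matched_1to1"
  else if (abs(ratio - 2) < 1e-9) "block_2to1"
  else "intermediate_n_to_1"
}

#' Simulate a cohort of larvae for AV-ratio studies
#'
#' Generates one or two dual-chamber recordings per larva with ground-truth
#' conduction classes attached, for exercising cohort-level classification
#' and between-recording switch detection. Per-recording seeds are derived
#' reproducibly from the master seed, so any single larva can be regenerated
#' bit-identically in isolation.
#'
#' @param ratios Numeric vector: conduction ratio of each larva (first
#'   recording).
#' @param ratios2 Optional numeric vector: per-larva ratio for the second
#'   recording (required when `recordings_per_larva = 2`; larvae whose two
#'   ratios imply different AV classes are planted switchers).
#' @param recordings_per_larva 1 or 2.
#' @param atrial_rate_bpm,duration_s,sample_rate_hz,noise_sd,conduction
#'   Shared trace parameters; see [cardiac_sim_params()].
#' @param seed Master seed.
#' @return A list with one element per larva: `subject_id`, `traces` (list of
#'   [dual_chamber_trace()]), `true_class` (character, one per recording) and
#'   `true_switch` (logical). Attribute `"class_counts"` tabulates the
#'   planted first-recording classes.
#' @export
simulate_av_cohort <- function(ratios, ratios2 = NULL, recordings_per_larva = 1,
                               atrial_rate_bpm = 120, duration_s = 30,
                               sample_rate_hz = 100, noise_sd = 0.1,
                               conduction = "regular", seed = 1L) {
  if (length(ratios) == 0) stopf("empty cohort specification")
  if (!recordings_per_larva %in% 1:2)
    stopf("`recordings_per_larva` must be 1 or 2")
  if (recordings_per_larva == 2) {
    if (is.null(ratios2)) ratios2 <- ratios
    if (length(ratios2) != length(ratios))
      stopf("`ratios2` must match `ratios` in length")
  }
  cohort <- lapply(seq_along(ratios), function(i) {
    sid <- sprintf("larva%03d", i)
    rs <- if (recordings_per_larva == 2) c(ratios[i], ratios2[i]) else ratios[i]
    traces <- lapply(seq_along(rs), function(r) {
      simulate_cardiac_trace(
        cardiac_sim_params(atrial_rate_bpm, conduction_ratio = rs[r],
                           duration_s = duration_s,
                           sample_rate_hz = sample_rate_hz,
                           noise_sd = noise_sd, conduction = conduction,
                           seed = derive_seed(seed, sid, r)),
        subject_id = sid, recording_id = sprintf("r%d", r))
    })
    cls <- vapply(rs, av_class_from_ratio, character(1))
    list(subject_id = sid, traces = traces, true_class = cls,
         true_switch = length(unique(cls)) > 1)
  })
  attr(cohort, "class_counts") <-
    table(vapply(cohort, function(x) x$true_class[1], character(1)))
  cohort
}

#' Simulate bout-structured larval tracking data
#'
#' Generates per-larva 2-D positions in a square arena at the tracking rate:
#' immobility broken by Poisson-process swim bouts (each spreading its drawn
#' displacement over ~0.3 s), plus seizure-like bursts planted at a per-group
#' Poisson rate. Each planted burst is confined to a single 1-second analysis
#' window so the ground-truth episode count per larva is exact. Positions are
#' folded back into the arena by specular reflection at the walls.
#'
#' @param params A [track_sim_params()] object.
#' @return A data frame with columns `larva_id`, `time_s`, `x_mm`, `y_mm`,
#'   `genotype`, `treatment`, `phase`, and attribute `"ground_truth"`: a data
#'   frame of planted burst-window counts per larva and phase.
#' @export
simulate_tracks <- function(params) {
  stopifnot(inherits(params, "track_sim_params"))
  p <- params
  fs <- p$sample_rate_hz
  dt <- 1 / fs
  n1 <- round(p$phase_durations_s[1] * fs)
  n2 <- round(p$phase_durations_s[2] * fs)
  n <- n1 + n2
  total_s <- n / fs
  frames_per_win <- round(fs)  # 1 s windows
  n_win <- floor(n / frames_per_win)
  # windows fully inside one phase (burst candidates)
  win_start <- (seq_len(n_win) - 1L) * frames_per_win + 1L
  win_phase <- ifelse(win_start + frames_per_win - 1L <= n1, "light", "dark")
  win_ok <- win_start >= 1 & (win_start + frames_per_win - 1L) <= n &
    (win_start > n1 | win_start + frames_per_win - 1L <= n1)

  burst_rate <- p$seizure_burst_rate_per_min
  group_key <- paste(p$group_labels$genotype, p$group_labels$treatment, sep = ".")

  out <- list(); gt <- list(); li <- 0L
  for (g in seq_len(nrow(p$group_labels))) {
    geno <- as.character(p$group_labels$genotype[g])
    trt <- as.character(p$group_labels$treatment[g])
    rate_g <- if (length(burst_rate) == 1 && is.null(names(burst_rate))) burst_rate
              else burst_rate[[group_key[g]]] %||% 0
    for (j in seq_len(p$n_larvae_per_group)) {
      li <- li + 1L
      lid <- sprintf("%s_%s_%02d", geno, trt, j)
      sim <- with_seed(derive_seed(p$seed, geno, trt, j), {
        sx <- numeric(n); sy <- numeric(n)  # step i moves frame i -> i+1
        n_bouts <- stats::rpois(1, p$bout_rate_hz * total_s)
        if (n_bouts > 0 && n > 4) {
          starts <- sample.int(n - 4L, n_bouts, replace = TRUE)
          D <- pmax(stats::rnorm(n_bouts, p$bout_displacement_mm[1],
                                 p$bout_displacement_mm[2]), 0.05)
          th <- stats::runif(n_bouts, 0, 2 * pi)
          for (b in seq_len(n_bouts)) {
            i <- starts[b] + 0:2
            a <- th[b] + stats::rnorm(3, 0, 0.3)
            sx[i] <- sx[i] + D[b] / 3 * cos(a)
            sy[i] <- sy[i] + D[b] / 3 * sin(a)
          }
        }
        n_bursts <- stats::rpois(1, rate_g * total_s / 60)
        burst_wins <- integer(0)
        if (n_bursts > 0) {
          cand <- which(win_ok)
          burst_wins <- sample(cand, min(n_bursts, length(cand)))
          nb <- frames_per_win - 2L
          for (w in burst_wins) {
            D <- max(stats::rnorm(1, p$seizure_displacement_mm[1],
                                  p$seizure_displacement_mm[2]),
                     p$bout_displacement_mm[1] * 2)
            i <- win_start[w] + seq_len(nb) - 1L
            a <- stats::runif(nb, 0, 2 * pi)
            sx[i] <- D / nb * cos(a)   # bursts override any coinciding bout
            sy[i] <- D / nb * sin(a)
          }
        }
        # fold the cumulated path back into [0, arena] (specular reflection)
        fold <- function(v) {
          m <- v %% (2 * p$arena_mm)
          ifelse(m > p$arena_mm, 2 * p$arena_mm - m, m)
        }
        x <- fold(p$arena_mm / 2 + cumsum(c(0, sx[-n])))
        y <- fold(p$arena_mm / 2 + cumsum(c(0, sy[-n])))
        list(x = x, y = y, burst_wins = burst_wins)
      })
      tsec <- (seq_len(n) - 1) * dt
      out[[li]] <- data.frame(
        larva_id = lid, time_s = tsec, x_mm = sim$x, y_mm = sim$y,
        genotype = geno, treatment = trt,
        phase = ifelse(tsec < p$phase_durations_s[1], "light", "dark"),
        stringsAsFactors = FALSE)
      gt[[li]] <- data.frame(
        larva_id = lid, genotype = geno, treatment = trt,
        phase = c("light", "dark"),
        n_burst_windows = c(sum(win_phase[sim$burst_wins] == "light"),
                            sum(win_phase[sim$burst_wins] == "dark")),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "ground_truth") <- do.call(rbind, gt)
  res
}

# Ellipsoid mask on a grid from fractional center / semi-axes.
ellipsoid_mask <- function(shape, spec) {
  ax <- lapply(seq_len(3), function(d) ((seq_len(shape[d]) - 0.5) / shape[d] -
                                          spec$center[d]) / spec$semi_axes[d])
  o <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  o <= 1
}

# Smooth unit-variance Gaussian random field times `sd` (zeros if sd == 0).
smooth_noise_field <- function(shape, sigma, sd) {
  if (sd <= 0) return(array(0, shape))
  z <- gauss_smooth_array(array(stats::rnorm(prod(shape)), shape), sigma)
  z / stats::sd(z) * sd
}

#' Simulate registered volumetric cohorts with planted effects
#'
#' Generates per-subject log-Jacobian determinant (LJD) maps and channel
#' intensity volumes on a shared reference grid. A planted volumetric factor
#' f for a region adds the constant ln(f) to the LJD inside that region, so
#' at zero noise the region-integrated local volume, sum of exp(LJD) times
#' the voxel volume, equals f times the reference region volume exactly.
#' Planted intensity factors multiply the in-region channel intensity.
#' Noise is a smooth Gaussian random field.
#'
#' @param params A [volume_sim_params()] object.
#' @return A list with elements `masks` (logical arrays: `brain` plus the
#'   named regions, all clipped to the brain mask), `subjects` (list of
#'   per-subject lists: `subject_id`, `group`, `ljd` array, `channels` list
#'   of intensity arrays) and `voxel_size_um`.
#' @export
simulate_volumes <- function(params) {
  stopifnot(inherits(params, "volume_sim_params"))
  p <- params
  shape <- p$grid_shape
  brain <- ellipsoid_mask(shape, p$brain_mask_spec)
  regions <- lapply(p$region_masks, function(s) ellipsoid_mask(shape, s) & brain)
  mask_for <- function(nm) if (nm == "brain") brain else regions[[nm]]
  subjects <- list()
  for (g in p$groups) {
    contr <- p$planted_contraction[[g]]
    for (j in seq_len(p$n_subjects_per_group)) {
      sid <- sprintf("%s_%02d", g, j)
      subj <- with_seed(derive_seed(p$seed, g, j), {
        ljd <- smooth_noise_field(shape, p$field_smoothness_vox, p$noise_sd)
        for (nm in names(contr)) ljd <- ljd + log(contr[[nm]]) * mask_for(nm)
        channels <- list()
        for (ch in p$channels) {
          scale_map <- array(1, shape)
          isc <- p$planted_intensity_scale[[g]][[ch]]
          for (nm in names(isc)) {
            mk <- mask_for(nm)
            scale_map[mk] <- scale_map[mk] * isc[[nm]]
          }
          vol <- p$baseline_intensity * scale_map * brain +
            smooth_noise_field(shape, p$field_smoothness_vox,
                               p$noise_sd * p$baseline_intensity)
          channels[[ch]] <- vol
        }
        list(ljd = ljd, channels = channels)
      })
      subjects[[sid]] <- list(subject_id = sid, group = g,
                              ljd = subj$ljd, channels = subj$channels)
    }
  }
  list(masks = c(list(brain = brain), regions), subjects = subjects,
       voxel_size_um = p$voxel_size_um)
}

#' Simulate a slow-rate fluorescence voxel time series
#'
#' Per-voxel series are a constant baseline with sparse single-frame
#' transient events of amplitude `event_amplitude_frac` times baseline,
#' plus additive Gaussian noise; the per-voxel event count is Poisson with
#' mean `event_rate` over the recording.
#'
#' @param params A [gcamp_sim_params()] object.
#' @return A list with `data` (array: spatial dims then time),
#'   `frame_rate_hz`, and attribute `"ground_truth"`: a data frame of the
#'   planted events (linear voxel index, frame).
#' @export
simulate_gcamp <- function(params) {
  stopifnot(inherits(params, "gcamp_sim_params"))
  p <- params
  nvox <- prod(p$grid_shape)
  res <- with_seed(p$seed, {
    m <- matrix(p$baseline_level, nvox, p$n_frames)
    counts <- stats::rpois(nvox, p$event_rate)
    ev_vox <- rep(which(counts > 0), counts[counts > 0])
    ev_frame <- if (length(ev_vox))
      sample.int(p$n_frames, length(ev_vox), replace = TRUE) else integer(0)
    if (length(ev_vox))
      m[cbind(ev_vox, ev_frame)] <-
        p$baseline_level * (1 + p$event_amplitude_frac)
    if (p$noise_sd > 0)
      m <- m + stats::rnorm(length(m), 0, p$noise_sd)
    list(m = m, ev = data.frame(voxel = ev_vox, frame = ev_frame))
  })
  out <- list(data = array(res$m, c(p$grid_shape, p$n_frames)),
              frame_rate_hz = p$frame_rate_hz)
  attr(out, "ground_truth") <- res$ev
  out
}
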