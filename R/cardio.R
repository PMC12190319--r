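#' Mean ROI intensity trace from an image stack
#'
#' Collapses a frame stack to a single intensity time series by averaging the
#' pixels inside a region of interest at every frame — the standard readout
#' for chamber-wall contraction from high-speed cardiac video.
#'
#' @param frame_stack 3-D numeric array `(rows, cols, frames)`.
#' @param roi Logical matrix matching the frame dimensions; `TRUE` pixels are
#'   averaged.
#' @return Numeric vector, one value per frame.
#' @export
extract_roi_trace <- function(frame_stack, roi) {
  d <- dim(frame_stack)
  if (length(d) != 3) stopf("`frame_stack` must be a 3-D array (rows, cols, frames)")
  if (!is.logical(roi)) roi <- roi > 0
  if (!identical(dim(roi), d[1:2])) stopf("`roi` must match the frame dimensions")
  if (!any(roi)) stopf("`roi` is empty")
  m <- matrix(frame_stack, d[1] * d[2], d[3])
  colMeans(m[as.vector(roi), , drop = FALSE])
}

#' Beat rate by peak counting
#'
#' Detects contraction peaks in an intensity trace and converts the mean
#' inter-peak interval to beats per minute:
#' `bpm = 60 * (n_peaks - 1) / (time from first to last peak)`.
#' The trace is linearly detrended and lightly smoothed (5-sample moving
#' average) before detection; peaks must exceed a topographic-prominence
#' floor (`prominence_frac` times the robust peak-to-trough amplitude of
#' the trace) and be separated by at least `min_distance_s` (default
#' `60 / (1.5 * band_max_bpm)`, rejecting dicrotic ripple without
#' suppressing true beats).
#'
#' @param trace Numeric intensity series.
#' @param sample_rate_hz Sampling rate (Hz).
#' @param min_distance_s Minimum peak separation (s); default derived from
#'   `band_max_bpm`.
#' @param prominence_frac Prominence floor as a fraction of the robust
#'   (outlier-trimmed) peak-to-trough amplitude.
#' @param band_max_bpm Fastest rate considered physiological (default 480).
#' @return List with `bpm`, `n_peaks` and `peak_times_s`.
#'   Fewer than two detected peaks raise an error of class
#'   `larvaquant_insufficient_beats`, distinguishing a flat/asystolic trace
#'   from a parameterisation problem.
#' @export
beat_rate_peaks <- function(trace, sample_rate_hz, min_distance_s = NULL,
                            prominence_frac = 0.4, band_max_bpm = 480) {
  check_positive(sample_rate_hz, "sample_rate_hz")
  if (length(trace) < 4) stopf("trace too short")
  min_distance_s <- min_distance_s %||% (60 / (1.5 * band_max_bpm))
  x <- detrend_linear(trace)
  x <- as.numeric(stats::filter(x, rep(1 / 5, 5), sides = 2))
  x[is.na(x)] <- 0
  # robust peak-to-trough amplitude: outlier-trimmed range of the smoothed
  # trace; true beats have prominence near this swing, noise far below it
  amp <- unname(diff(stats::quantile(x, c(0.005, 0.995))))
  pk <- NULL
  if (amp > 0) {
    pk <- pracma::findpeaks(
      x, minpeakdistance = max(1L, round(min_distance_s * sample_rate_hz)))
    if (!is.null(pk)) {
      prom <- peak_prominence(x, pk[, 2])
      pk <- pk[prom >= prominence_frac * amp, , drop = FALSE]
    }
  }
  if (is.null(pk) || nrow(pk) < 2)
    stop(structure(class = c("larvaquant_insufficient_beats", "error", "condition"),
                   list(message = "insufficient beats: fewer than 2 peaks detected",
                        call = sys.call(-1))))
  times <- sort(pk[, 2]) / sample_rate_hz
  list(bpm = 60 * (length(times) - 1) / (times[length(times)] - times[1]),
       n_peaks = nrow(pk), peak_times_s = times)
}

#' Short-time Fourier spectrogram of a contraction trace
#'
#' Power of the short-time Fourier transform over sliding windows, after
#' linear detrending of the whole trace (removing photobleaching drift).
#' The default 5-second Hann window captures at least two beats at the
#' slowest rates of interest; the display band 0–5 Hz corresponds to
#' 0–300 bpm.
#'
#' @param trace Numeric intensity series.
#' @param sample_rate_hz Sampling rate (Hz).
#' @param window_s Window length in seconds (default 5).
#' @param overlap_frac Fractional window overlap (default 0.75).
#' @return An object of class `cardiac_spectrogram`: list with `power`
#'   (frequency x time matrix, non-negative), `freqs_hz`, `times_s`,
#'   `window_s`, `overlap_frac`.
#' @export
compute_spectrogram <- function(trace, sample_rate_hz, window_s = 5,
                                overlap_frac = 0.75) {
  check_positive(sample_rate_hz, "sample_rate_hz")
  if (overlap_frac < 0 || overlap_frac >= 1) stopf("`overlap_frac` must be in [0, 1)")
  nfft <- round(window_s * sample_rate_hz)
  if (nfft > length(trace)) stopf("window longer than trace")
  x <- detrend_linear(trace)
  sg <- signal::specgram(x, n = nfft, Fs = sample_rate_hz,
                         overlap = round(nfft * overlap_frac))
  structure(list(power = Mod(sg$S)^2, freqs_hz = as.numeric(sg$f),
                 times_s = as.numeric(sg$t), window_s = window_s,
                 overlap_frac = overlap_frac),
            class = "cardiac_spectrogram")
}

#' Dominant contraction frequency by Fourier transform
#'
#' Returns the frequency of maximum periodogram power within a band,
#' expressed in beats per minute, together with the spectral resolution.
#' This is the robust fallback when peak counting becomes unreliable at
#' high contraction rates. The band default 0.5–8 Hz (30–480 bpm) excludes
#' DC and respiratory drift.
#'
#' @param trace Numeric intensity series.
#' @param sample_rate_hz Sampling rate (Hz).
#' @param band_hz Length-2 frequency band searched; must exclude 0 Hz.
#' @return List with `bpm`, `freq_hz` and `resolution_bpm`
#'   (60 * sample rate / trace length).
#' @export
dominant_frequency <- function(trace, sample_rate_hz, band_hz = c(0.5, 8)) {
  check_positive(sample_rate_hz, "sample_rate_hz")
  if (band_hz[1] <= 0) stopf("band must exclude 0 Hz (DC)")
  if (band_hz[2] <= band_hz[1]) stopf("invalid band")
  sp <- stats::spec.pgram(stats::ts(trace, frequency = sample_rate_hz),
                          taper = 0, detrend = TRUE, demean = TRUE,
                          fast = FALSE, plot = FALSE)
  sel <- sp$freq >= band_hz[1] & sp$freq <= band_hz[2]
  if (!any(sel) || all(sp$spec[sel] <= 0) || !any(is.finite(sp$spec[sel])))
    stopf("no dominant frequency: zero spectral power in band")
  f <- sp$freq[sel][which.max(sp$spec[sel])]
  list(bpm = 60 * f, freq_hz = f,
       resolution_bpm = 60 * sample_rate_hz / length(trace))
}

#' Default atrioventricular classification bands
#'
#' A larva is called matched (1:1) when the atrium:ventricle rate ratio lies
#' within `tol` of 1, 2:1 block when within `tol` of 2 (multiplicatively),
#' and intermediate otherwise. The default 15% multiplicative tolerance
#' absorbs rate-estimation error at typical trace lengths while keeping the
#' two bands disjoint.
#'
#' @param tol Multiplicative half-width of each band (default 1.15).
#' @return List with `matched` and `block` ratio intervals.
#' @export
av_bands <- function(tol = 1.15) {
  stopifnot(tol > 1, tol^2 < 2)  # bands must not overlap
  list(matched = c(1 / tol, tol), block = c(2 / tol, 2 * tol))
}

#' Classify the atrioventricular conduction pattern
#'
#' Classifies a larva from its two chamber rates using the ratio
#' `r = atrial_bpm / ventricular_bpm` alone: matched 1:1, 2:1 block, or
#' intermediate n:1. A zero ventricular rate is reported as the dedicated
#' class `"ventricular_standstill"`.
#'
#' @param atrial_bpm,ventricular_bpm Chamber rates (bpm).
#' @param bands Classification bands from [av_bands()].
#' @param method Label recording how the rates were estimated
#'   (`"peaks"` or `"fourier"`); metadata only.
#' @return An object of class `av_assessment`: list with `atrial_bpm`,
#'   `ventricular_bpm`, `av_ratio`, `av_class`, `method`.
#' @export
classify_av <- function(atrial_bpm, ventricular_bpm, bands = av_bands(),
                        method = c("peaks", "fourier")) {
  method <- match.arg(method)
  check_nonnegative(atrial_bpm, "atrial_bpm")
  check_nonnegative(ventricular_bpm, "ventricular_bpm")
  if (ventricular_bpm == 0) {
    return(structure(list(atrial_bpm = atrial_bpm, ventricular_bpm = 0,
                          av_ratio = Inf, av_class = "ventricular_standstill",
                          method = method), class = "av_assessment"))
  }
  r <- atrial_bpm / ventricular_bpm
  cls <- if (r >= bands$matched[1] && r <= bands$matched[2]) "matched_1to1"
  else if (r >= bands$block[1] && r <= bands$block[2]) "block_2to1"
  else "intermediate_n_to_1"
  structure(list(atrial_bpm = atrial_bpm, ventricular_bpm = ventricular_bpm,
                 av_ratio = r, av_class = cls, method = method),
            class = "av_assessment")
}

#' @export
print.av_assessment <- function(x, ...) {
  cat(sprintf("<av_assessment> A %.1f / V %.1f bpm, ratio %.2f -> %s (%s)\n",
              x$atrial_bpm, x$ventricular_bpm, x$av_ratio, x$av_class, x$method))
  invisible(x)
}

#' Assess a dual-chamber trace end to end
#'
#' Estimates both chamber rates (peak counting or Fourier dominant
#' frequency) and classifies the AV conduction pattern.
#'
#' @param trace A [dual_chamber_trace()].
#' @param method `"peaks"` or `"fourier"`.
#' @param bands Classification bands from [av_bands()].
#' @param band_hz Search band for the Fourier method.
#' @return An `av_assessment` with `subject_id`/`recording_id` carried over.
#' @export
assess_trace <- function(trace, method = c("peaks", "fourier"),
                         bands = av_bands(), band_hz = c(0.5, 8)) {
  stopifnot(inherits(trace, "dual_chamber_trace"))
  method <- match.arg(method)
  est <- function(x) {
    if (method == "peaks") beat_rate_peaks(x, trace$sample_rate_hz)$bpm
    else dominant_frequency(x, trace$sample_rate_hz, band_hz)$bpm
  }
  a <- est(trace$atrium)
  v <- tryCatch(est(trace$ventricle),
                larvaquant_insufficient_beats = function(e) 0)
  out <- classify_av(a, v, bands = bands, method = method)
  out$subject_id <- trace$subject_id
  out$recording_id <- trace$recording_id
  out
}

#' Detect between-recording AV-class switches
#'
#' Compares the AV class of each subject across exactly two recordings
#' (typically separated by several hours); a subject switched when the two
#' classes differ. Subjects without exactly two recordings are excluded with
#' a warning.
#'
#' @param assessments Data frame with columns `subject_id`, `recording_id`
#'   and `av_class` (e.g. rows built from [assess_trace()] results).
#' @return Data frame with one row per retained subject: `subject_id`,
#'   `class_1`, `class_2`, `switched`; attribute `"switch_fraction"` gives
#'   the cohort switcher fraction and `"n_excluded"` the exclusion count.
#' @export
detect_switch <- function(assessments) {
  stopifnot(all(c("subject_id", "recording_id", "av_class") %in% names(assessments)))
  counts <- table(assessments$subject_id)
  bad <- names(counts)[counts != 2]
  if (length(bad))
    warning(sprintf("%d subject(s) without exactly 2 recordings excluded", length(bad)))
  keep <- assessments[!assessments$subject_id %in% bad, , drop = FALSE]
  keep <- keep[order(keep$subject_id, keep$recording_id), ]
  ids <- unique(keep$subject_id)
  res <- data.frame(
    subject_id = ids,
    class_1 = keep$av_class[seq(1, nrow(keep), by = 2)],
    class_2 = keep$av_class[seq(2, nrow(keep), by = 2)],
    stringsAsFactors = FALSE)
  res$switched <- res$class_1 != res$class_2
  attr(res, "switch_fraction") <- mean(res$switched)
  attr(res, "n_excluded") <- length(bad)
  res
}

#' Cohort summary of AV assessments
#'
#' Tabulates AV-class fractions (summing to 1 over reported classes) and
#' per-class rate statistics for a cohort of assessments.
#'
#' @param assessments Data frame with columns `av_class`, `atrial_bpm`,
#'   `ventricular_bpm` (one row per larva).
#' @return List with `fractions` (named numeric, sums to 1), `counts`, and
#'   `rates` (per-class mean and SD of both chamber rates).
#' @export
cohort_summary <- function(assessments) {
  if (nrow(assessments) < 1) stopf("need at least one assessment")
  counts <- table(assessments$av_class)
  fr <- as.numeric(counts) / sum(counts)
  names(fr) <- names(counts)
  rates <- do.call(rbind, lapply(names(counts), function(cl) {
    s <- assessments[assessments$av_class == cl, ]
    data.frame(av_class = cl, n = nrow(s),
               atrial_bpm_mean = mean(s$atrial_bpm),
               atrial_bpm_sd = stats::sd(s$atrial_bpm),
               ventricular_bpm_mean = mean(s$ventricular_bpm),
               ventricular_bpm_sd = stats::sd(s$ventricular_bpm))
  }))
  list(fractions = fr, counts = counts, rates = rates)
}

#' Flag a within-recording conduction-regime change
#'
#' Classifies the atrium:ventricle ratio in each spectrogram window and
#' flags the recording when the windowed AV class changes over time —
#' the signature of an abrupt mid-recording switch between conduction
#' regimes. Reported as a flag, separate from the two-recording switch
#' statistic.
#'
#' @param trace A [dual_chamber_trace()].
#' @param window_s,overlap_frac Spectrogram settings.
#' @param band_hz Frequency band searched for the windowed peak.
#' @param bands Classification bands from [av_bands()].
#' @return List with `changed` (logical), `window_classes` and
#'   `window_times_s`.
#' @export
detect_regime_change <- function(trace, window_s = 5, overlap_frac = 0.75,
                                 band_hz = c(0.5, 8), bands = av_bands()) {
  stopifnot(inherits(trace, "dual_chamber_trace"))
  cls_per_window <- function(x) {
    sg <- compute_spectrogram(x, trace$sample_rate_hz, window_s, overlap_frac)
    sel <- sg$freqs_hz >= band_hz[1] & sg$freqs_hz <= band_hz[2]
    apply(sg$power[sel, , drop = FALSE], 2, function(p) sg$freqs_hz[sel][which.max(p)])
  }
  fa <- cls_per_window(trace$atrium)
  fv <- cls_per_window(trace$ventricle)
  wc <- vapply(seq_along(fa), function(i)
    classify_av(60 * fa[i], 60 * fv[i])$av_class, character(1))
  sg <- compute_spectrogram(trace$atrium, trace$sample_rate_hz, window_s, overlap_frac)
  list(changed = length(unique(wc)) > 1, window_classes = wc,
       window_times_s = sg$times_s)
}

#' Assess every recording in a simulated or assembled cohort
#'
#' Runs [assess_trace()] over a list of larvae (each holding one or more
#' recordings, as produced by [simulate_av_cohort()]) and returns the
#' per-recording results as one table — the cohort-level input for
#' [detect_switch()], [cohort_summary()] or a results CSV.
#'
#' @param cohort List of larvae; each element has a `traces` list of
#'   [dual_chamber_trace()] objects.
#' @param method,bands,band_hz Passed to [assess_trace()].
#' @return Data frame: `subject_id`, `recording_id`, `atrial_bpm`,
#'   `ventricular_bpm`, `av_ratio`, `av_class`.
#' @export
assess_cohort <- function(cohort, method = c("peaks", "fourier"),
                          bands = av_bands(), band_hz = c(0.5, 8)) {
  method <- match.arg(method)
  rows <- lapply(cohort, function(larva) {
    do.call(rbind, lapply(larva$traces, function(tr) {
      a <- assess_trace(tr, method = method, bands = bands, band_hz = band_hz)
      data.frame(subject_id = a$subject_id, recording_id = a$recording_id,
                 atrial_bpm = a$atrial_bpm, ventricular_bpm = a$ventricular_bpm,
                 av_ratio = a$av_ratio, av_class = a$av_class,
                 stringsAsFactors = FALSE)
    }))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
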