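#' Per-window path lengths from a tracking table
#'
#' Computes the total distance moved by each larva in consecutive
#' non-overlapping windows (default 1 s), the base quantity for
#' seizure-like episode scoring. A step from sample i to i+1 is attributed
#' to the window containing sample i; the trailing partial window is
#' dropped. Windows are anchored at each larva's recording start.
#'
#' @param tracks Data frame with columns `larva_id`, `time_s`, `x_mm`,
#'   `y_mm` and optionally `genotype`, `treatment`, `phase` (carried over
#'   per window; a window takes the phase of its first sample).
#' @param window_s Window length in seconds (default 1).
#' @return Data frame: `larva_id`, `window_index`, `distance_mm`, plus any
#'   carried label columns.
#' @export
window_distances <- function(tracks, window_s = 1) {
  need <- c("larva_id", "time_s", "x_mm", "y_mm")
  stopifnot(all(need %in% names(tracks)))
  check_positive(window_s, "window_s")
  labels <- intersect(c("genotype", "treatment", "phase"), names(tracks))
  out <- lapply(split(tracks, tracks$larva_id), function(tr) {
    tr <- tr[order(tr$time_s), ]
    n <- nrow(tr)
    if (n < 2) stopf("larva '%s': single-sample track", tr$larva_id[1])
    t0 <- tr$time_s[1]
    dt <- stats::median(diff(tr$time_s))
    # nominal recording span n*dt; trailing partial window dropped
    n_win <- floor(n * dt / window_s + 1e-9)
    if (n_win < 1) stopf("larva '%s': no complete window", tr$larva_id[1])
    step <- sqrt(diff(tr$x_mm)^2 + diff(tr$y_mm)^2)
    win <- floor((tr$time_s[-n] - t0) / window_s + 1e-9) + 1L
    keep <- win <= n_win
    d <- numeric(n_win)
    agg <- rowsum(step[keep], win[keep])
    d[as.integer(rownames(agg))] <- agg[, 1]
    first_idx <- match(seq_len(n_win), win)
    res <- data.frame(larva_id = tr$larva_id[1], window_index = seq_len(n_win),
                      distance_mm = d, stringsAsFactors = FALSE)
    for (lb in labels) res[[lb]] <- tr[[lb]][first_idx]
    res
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Calibrate the large-movement threshold
#'
#' Empirical quantile rule: the threshold is the (1 - `exceed_frac`)
#' quantile (type 1, a lower order statistic) of the pooled per-window
#' distances of the calibration larvae — conventionally all wild-type
#' vehicle-treated animals pooled together. By construction, the fraction
#' of calibration windows strictly exceeding the threshold is at most
#' `exceed_frac` (0.1% by default), so over a 900-window recording slightly
#' less than one exceedance is expected from baseline behaviour alone.
#'
#' @param calib_distances Numeric vector of pooled calibration window
#'   distances (mm), or a data frame from [window_distances()] whose
#'   `distance_mm` column is used.
#' @param exceed_frac Target exceedance fraction (default 0.001).
#' @return Threshold in mm, with attributes `n` (pool size) and
#'   `exceedance` (re-measured strict-exceedance fraction on the pool).
#' @export
calibrate_threshold <- function(calib_distances, exceed_frac = 0.001) {
  if (is.data.frame(calib_distances)) calib_distances <- calib_distances$distance_mm
  if (length(calib_distances) == 0) stopf("empty calibration pool")
  if (exceed_frac <= 0 || exceed_frac >= 1) stopf("`exceed_frac` must be in (0, 1)")
  if (length(calib_distances) < 1 / exceed_frac)
    warning(sprintf("calibration pool (%d windows) smaller than 1/exceed_frac; quantile unstable",
                    length(calib_distances)))
  thr <- stats::quantile(calib_distances, probs = 1 - exceed_frac,
                         type = 1, names = FALSE)
  structure(thr, n = length(calib_distances),
            exceedance = mean(calib_distances > thr))
}

#' Count seizure-like episodes
#'
#' An episode is a window whose distance strictly exceeds the calibrated
#' threshold. Counts and per-minute rates are reported per larva and, when
#' a `phase` column is present, per light/dark phase.
#'
#' @param windows Data frame from [window_distances()].
#' @param threshold_mm Calibrated threshold (see [calibrate_threshold()]).
#' @param window_s Window length used (s), for the per-minute rate.
#' @return Data frame: `larva_id` (+ labels), `phase` if available,
#'   `n_windows`, `n_episodes`, `episodes_per_min`.
#' @export
count_episodes <- function(windows, threshold_mm, window_s = 1) {
  stopifnot(all(c("larva_id", "distance_mm") %in% names(windows)))
  by <- list(larva_id = windows$larva_id)
  labels <- intersect(c("genotype", "treatment"), names(windows))
  for (lb in labels) by[[lb]] <- windows[[lb]]
  if ("phase" %in% names(windows)) by$phase <- windows$phase
  agg <- stats::aggregate(windows$distance_mm, by = by,
                          FUN = function(d) c(n = length(d),
                                              ep = sum(d > threshold_mm)))
  res <- data.frame(agg[setdiff(names(agg), "x")],
                    n_windows = agg$x[, "n"],
                    n_episodes = agg$x[, "ep"],
                    stringsAsFactors = FALSE)
  res$episodes_per_min <- res$n_episodes / (res$n_windows * window_s / 60)
  rownames(res) <- NULL
  res
}

#' Mean locomotor speed during movement bouts
#'
#' Instantaneous speed is each per-frame displacement divided by the frame
#' interval; frames with speed above `movement_threshold_mm_s` are
#' classified as moving and their mean speed is reported. A larva with no
#' moving frames is reported as `NA` (absent), not zero.
#'
#' @param tracks Tracking data frame (see [window_distances()]).
#' @param movement_threshold_mm_s Speed cutoff separating bouts from rest.
#' @return Data frame: `larva_id`, `mean_bout_speed_mm_s`, `n_moving_frames`.
#' @export
bout_speed <- function(tracks, movement_threshold_mm_s = 0.5) {
  stopifnot(all(c("larva_id", "time_s", "x_mm", "y_mm") %in% names(tracks)))
  out <- lapply(split(tracks, tracks$larva_id), function(tr) {
    tr <- tr[order(tr$time_s), ]
    dt <- diff(tr$time_s)
    v <- sqrt(diff(tr$x_mm)^2 + diff(tr$y_mm)^2) / dt
    moving <- v > movement_threshold_mm_s
    data.frame(larva_id = tr$larva_id[1],
               mean_bout_speed_mm_s = if (any(moving)) mean(v[moving]) else NA_real_,
               n_moving_frames = sum(moving), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genotype effect on episode rates across experiments
#'
#' Per phase, tests the main effect of genotype on a per-larva measure
#' (episodes per minute by default) with the experiment/replicate as an
#' additive blocking factor, then applies Benjamini-Hochberg correction
#' across the phases (and any further measures tested together). Groups
#' with fewer than two larvae are excluded with a warning.
#'
#' @param results Data frame of per-larva results (e.g. from
#'   [count_episodes()]) with a `genotype` column, optionally `phase` and a
#'   replicate column.
#' @param value_col Name of the response column (default
#'   `"episodes_per_min"`).
#' @param replicate_col Optional name of the blocking column; `NULL` for a
#'   single experiment.
#' @return List with `effects` (data frame: phase, F, df, p, p_adj) and
#'   `group_stats` (per genotype x phase mean, SD, n).
#' @export
group_compare <- function(results, value_col = "episodes_per_min",
                          replicate_col = NULL) {
  stopifnot("genotype" %in% names(results), value_col %in% names(results))
  if (!is.null(replicate_col)) stopifnot(replicate_col %in% names(results))
  if ("phase" %in% names(results)) {
    phases <- unique(results$phase)
  } else {
    results$phase <- "all"; phases <- "all"
  }
  # drop genotype groups with n < 2 in any phase
  tab <- table(results$genotype, results$phase)
  small <- rownames(tab)[apply(tab, 1, min) < 2]
  if (length(small)) {
    warning(sprintf("excluding genotype group(s) with n < 2: %s",
                    paste(small, collapse = ", ")))
    results <- results[!results$genotype %in% small, , drop = FALSE]
  }
  if (length(unique(results$genotype)) < 2)
    stopf("need at least 2 genotype groups")
  effects <- do.call(rbind, lapply(phases, function(ph) {
    d <- results[results$phase == ph, , drop = FALSE]
    d$genotype <- factor(d$genotype)
    block <- replicate_col
    if (!is.null(block)) {
      d[[block]] <- factor(d[[block]])
      if (nlevels(droplevels(d[[block]])) < 2) block <- NULL
    }
    form <- if (is.null(block)) stats::as.formula(paste(value_col, "~ genotype"))
    else stats::as.formula(paste(value_col, "~ genotype +", block))
    an <- stats::anova(stats::lm(form, data = d))
    data.frame(phase = ph, term = "genotype",
               F = an["genotype", "F value"],
               df1 = an["genotype", "Df"],
               df2 = an["Residuals", "Df"],
               p = an["genotype", "Pr(>F)"], stringsAsFactors = FALSE)
  }))
  effects$p_adj <- stats::p.adjust(effects$p, method = "BH")
  gs <- stats::aggregate(results[[value_col]],
                         by = list(genotype = results$genotype,
                                   phase = results$phase),
                         FUN = function(x) c(mean = mean(x), sd = stats::sd(x),
                                             n = length(x)))
  group_stats <- data.frame(gs[c("genotype", "phase")],
                            mean = gs$x[, "mean"], sd = gs$x[, "sd"],
                            n = gs$x[, "n"])
  list(effects = effects, group_stats = group_stats)
}
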