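#' Spatial Gaussian smoothing of a fluorescence series
#'
#' Applies a separable Gaussian filter (default sigma 2 voxels) to the
#' spatial dimensions of every frame, suppressing sub-pixel drift and shot
#' noise before dF/F computation. `sigma_vox = 0` is the identity. The
#' kernel is truncated at 3 sigma and renormalised at the borders so
#' constant fields are preserved.
#'
#' @param series Numeric array whose last dimension is time: `(x, y, t)`
#'   for widefield or `(x, y, z, t)` for volumetric data; or a list with a
#'   `data` element of that form (as returned by [simulate_gcamp()]).
#' @param sigma_vox Gaussian sigma in voxels (>= 0).
#' @return The smoothed series in the same form as the input.
#' @export
smooth_series <- function(series, sigma_vox = 2) {
  check_nonnegative(sigma_vox, "sigma_vox")
  wrapped <- is.list(series) && !is.null(series$data)
  a <- if (wrapped) series$data else series
  d <- dim(a)
  if (is.null(d) || length(d) < 3)
    stopf("`series` must be an array with >= 2 spatial dims plus time")
  if (sigma_vox > 0) {
    nt <- d[length(d)]
    sp <- d[-length(d)]
    m <- matrix(a, prod(sp), nt)
    for (f in seq_len(nt))
      m[, f] <- as.vector(gauss_smooth_array(array(m[, f], sp), sigma_vox))
    a <- array(m, d)
  }
  if (wrapped) { series$data <- a; series } else a
}

#' Per-voxel dF/F map with minimum baseline
#'
#' For each voxel, the baseline F0 is the minimum fluorescence over the
#' recording and dF/F is the largest change relative to it, in percent:
#' `100 * (max - F0) / F0`. The min-baseline construction makes the map
#' non-negative and invariant to multiplicative intensity scaling, but it
#' explodes at near-zero baselines, so voxels with `F0 <= baseline_floor`
#' are flagged invalid (`NA`) and excluded from all summaries. The floor
#' defaults to 1% of the series' robust maximum (99.9th percentile).
#'
#' @param series Array `(spatial dims, time)` or a list with a `data`
#'   element (see [smooth_series()]).
#' @param baseline_floor Minimum admissible baseline; `NULL` for the
#'   default.
#' @return An object of class `dff_map`: list with `values` (percent
#'   change, `NA` where invalid), `baseline` (per-voxel F0), `valid`
#'   (logical array) and `baseline_floor`.
#' @export
dff_map <- function(series, baseline_floor = NULL) {
  a <- if (is.list(series) && !is.null(series$data)) series$data else series
  d <- dim(a)
  if (is.null(d) || length(d) < 3)
    stopf("`series` must be an array with >= 2 spatial dims plus time")
  nt <- d[length(d)]
  if (nt < 2) stopf("need at least 2 frames")
  sp <- d[-length(d)]
  m <- matrix(a, prod(sp), nt)
  f0 <- do.call(pmin, as.data.frame(m))
  fmax <- do.call(pmax, as.data.frame(m))
  floor_ <- baseline_floor %||% (0.01 * stats::quantile(m, 0.999, names = FALSE))
  valid <- f0 > floor_
  if (!any(valid)) stopf("all voxels below the baseline floor")
  values <- rep(NA_real_, length(f0))
  values[valid] <- 100 * (fmax[valid] - f0[valid]) / f0[valid]
  structure(list(values = array(values, sp), baseline = array(f0, sp),
                 valid = array(valid, sp), baseline_floor = floor_),
            class = "dff_map")
}

#' @export
print.dff_map <- function(x, ...) {
  cat(sprintf("<dff_map> %s grid; %d/%d valid voxels; mean dF/F %.2f%%\n",
              paste(dim(x$values), collapse = "x"), sum(x$valid),
              length(x$valid), mean(x$values[x$valid])))
  invisible(x)
}

#' Mean dF/F within a mask
#'
#' Arithmetic mean of the valid in-mask dF/F values — with a mask covering
#' cellular brain regions this is the scalar spontaneous-activity readout
#' compared across genotypes.
#'
#' @param map A [dff_map()] result.
#' @param mask Logical array matching the spatial grid.
#' @return Scalar mean dF/F in percent.
#' @export
mask_mean_dff <- function(map, mask) {
  stopifnot(inherits(map, "dff_map"))
  if (!is.logical(mask)) mask <- mask > 0
  if (!identical(dim(mask), dim(map$values)))
    stopf("mask dimensions do not match the map")
  sel <- mask & map$valid
  if (!any(sel)) stopf("mask does not overlap any valid voxel")
  mean(map$values[sel])
}
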