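---
title: "Methods: models, parameters and design choices in larvaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in larvaquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvaquant)
```

larvaquant packages four quantification procedures used in larval
zebrafish phenotyping — dual-chamber cardiac rhythm analysis, seizure-like
locomotor episode scoring, whole-brain dF/F activity mapping, and
voxel-based morphometry statistics — together with a synthetic-data module
that generates every input class with planted ground truth. This vignette
is the package's account of the underlying models, the parameters that
matter, and the choices made where the procedures are underdetermined.

## Cardiac rhythm

The unit of analysis is a `dual_chamber_trace`: paired mean-intensity time
series from regions of interest over the atrial and ventricular walls,
sampled at the video frame rate (100 Hz by default). Contraction shows up
as a quasi-periodic intensity oscillation in each chamber.

Two rate estimators are provided, because they fail differently:

* `beat_rate_peaks()` counts contraction peaks and converts the spanning
  interval to beats per minute, `bpm = 60 (n-1) / (t_n - t_1)`. It is the
  natural estimator for irregular rhythms (the ventricular rate under
  atrioventricular block is defined by how many beats actually occur),
  but peak detection degrades at high rates and low pulse amplitude.
* `dominant_frequency()` takes the argmax of the periodogram inside a
  band (default 0.5–8 Hz, i.e. 30–480 bpm, excluding DC and slow drift)
  and reports the spectral resolution `60 fs / n` alongside. It is robust
  to noise but reads the dominant periodicity, which for an irregularly
  conducted ventricle can be the atrial frequency rather than the
  effective ventricular rate — hence the peak-based default for
  classification work and the Fourier method for fast, regular rhythms.

Peak detection operates on the linearly detrended (photobleaching), lightly
smoothed (5-sample moving average) trace. Candidate peaks must be separated
by at least `60/(1.5 * band_max_bpm)` s and must have topographic
prominence of at least 0.4 times the robust peak-to-trough amplitude
(the 0.5%–99.5% quantile range of the smoothed trace). This floor was
calibrated on simulated pulse trains: across 60–300 bpm and additive noise
up to 0.2 of the pulse amplitude, the recovered rate is within a fraction
of a beat per minute, while lower floors (e.g. a quarter of a MAD-scaled
amplitude) admit noise peaks between beats.

The atrioventricular (AV) classification uses only the rate ratio
`r = atrial_bpm / ventricular_bpm`: matched 1:1 when `r` is within a
multiplicative 15% of 1, 2:1 block when within 15% of 2, intermediate n:1
otherwise, and a dedicated ventricular-standstill class at zero
ventricular rate. The 15% band half-width absorbs the estimation error of
30–60 s recordings while keeping the bands disjoint; it is exposed via
`av_bands()`. Classification therefore inherits the ratio-symmetry
property (scaling both rates never changes the class), which is tested.

Spectrograms (`compute_spectrogram()`, Hann window, 5 s, 75% overlap)
give the time-resolved view: at least two beats fit a window at the
slowest rates of interest, and the 0–5 Hz display band corresponds to
0–300 bpm. `detect_regime_change()` classifies the windowed AV ratio per
spectrogram column and flags recordings whose class changes mid-recording;
this is deliberately separate from `detect_switch()`, which compares
classes across two recordings of the same larva taken hours apart.

## Seizure-like episode scoring

Tracking comes in at 10 Hz as per-larva positions in a 7 x 7 mm well.
`window_distances()` sums successive Euclidean displacements into
non-overlapping 1 s windows anchored at the recording start (a step is
attributed to the window containing its first sample; the trailing partial
window is dropped, so a 15 min recording yields exactly 900 windows).

The episode threshold is purely empirical: the (1 - 0.001) quantile of the
pooled window distances of wild-type vehicle-treated larvae, using the
type-1 (lower order statistic) quantile so that the fraction of
calibration windows *strictly* exceeding the threshold is at most 0.1% by
construction — over a 900-window recording, slightly less than one
exceedance is expected from baseline behaviour. Pooling is across all
calibration larvae, not per larva, and a single threshold serves both
light and dark phases (per-phase calibration is possible by passing
phase-subset windows). Ties count only strictly-greater windows, so an
all-zero pool gives threshold 0 and zero exceedances.

`group_compare()` tests the genotype main effect on episodes per minute
per phase with the experiment as an additive blocking factor
(`lm(rate ~ genotype + experiment)`), and applies Benjamini–Hochberg
correction across the phases/measures tested together. Groups with fewer
than two larvae are excluded with a warning; a blocking factor that is
constant within a phase is dropped rather than made singular.

## dF/F activity mapping

Slow-rate (0.5 Hz, 5 min) fluorescence series are spatially smoothed with
a separable Gaussian (sigma 2 voxels by default; kernel truncated at
3 sigma and renormalised at borders so constants are preserved), then
reduced per voxel to `dF/F = 100 (max - min) / min` over the recording.
The minimum-baseline construction makes the map non-negative and invariant
to multiplicative intensity scaling (differences in indicator expression),
but it is *not* invariant to additive offsets — a constant background
offset lowers dF/F — and it diverges at near-zero baselines. Voxels whose
baseline falls at or below a floor (default 1% of the series' 99.9th
percentile) are flagged invalid and excluded from `mask_mean_dff()`, the
scalar activity readout over a cellular-regions mask. Inputs are assumed
motion-corrected; rigid drift correction and cross-subject registration
are out of scope.

## Voxel-based morphometry

`log_jacobian()` turns a subject-to-reference displacement field into the
log Jacobian determinant map `ln det(I + grad u)` via central differences
(one-sided at borders): 0 under the identity, negative where the subject
is locally contracted relative to the reference, `3 ln s` under uniform
scaling by `s`. Non-invertible local Jacobians (determinant <= 0) are
flagged rather than propagated.

Subject-space volumes integrate the local volume factor over
reference-space masks: `sum(exp(LJD)) * voxel volume`. This is
mathematically equivalent to inverse-transforming the mask onto the
subject and counting voxels, without re-implementing registration; a
voxel-counting mode for binary segmentations is also provided.
`mask_volume()` reports both absolute volume and percent of whole-brain
volume computed the same way. Note that with a region-restricted
contraction `f` inside a mask occupying fraction `m/B` of the brain, the
brain-*normalized* group reduction is `1 - f B / (B - (1-f) m)`, slightly
less than `1 - f`; for small masks the difference is well under a percent.

Cluster inference is permutation-calibrated: candidate clusters are
26-connected components of voxels with Welch-t nominal `p < 0.01`
(two-sided); group labels are permuted and the maximum cluster extent per
permutation forms the null; observed clusters are kept iff their extent
exceeds the (1 - alpha) type-1 quantile of that null. The observed
labeling is included in the sampled null (it is itself a draw from the
exchangeable null), which makes the family-wise error exact at alpha
under continuity; when the requested permutations meet or exceed the
number of distinct label arrangements the procedure enumerates them
exhaustively and says so. Extent was chosen as the cluster statistic and
`p < 0.01` as the forming threshold as standard conservative defaults;
both are explicit configuration, not claimed reproductions of any prior
tool's internals.

`symmetrize()` implements bilateral symmetrization of significance maps:
each voxel takes the greater of its own p-value and that of its mirror
across the declared midsagittal axis. Absent values (non-significant
voxels, stored as `NA`) dominate, so only bilaterally supported voxels
survive; the operation is idempotent and never decreases a p-value. The
mirror axis must be declared explicitly — the package cannot guess the
anatomy — and the grid is flipped about its centre (for even extents the
plane lies between voxel centres).

Two independently imaged cohorts are combined by `voxelwise_anova()`: an
additive two-way fit (group + cohort) per voxel, reporting the group
main-effect F and p with the cohort offset absorbed by the blocking term.
It is computed by projection matrices shared across voxels and is tested
against `stats::aov` voxel by voxel.

## The synthetic-data module

The generator exists so that every downstream stage can be exercised
against known truth without animal data. Its defaults encode the study
conditions the pipelines target:

* Cardiac: 100 samples/s; pulses are raised cosines (only timing, not
  waveform shape, is analysed); ventricular conduction follows the
  programmed ratio. Non-integer ratios default to a deterministic phase
  accumulator whose long-run atrium:ventricle beat ratio equals the
  programmed ratio exactly; a Bernoulli mode (independent conduction with
  probability 1/ratio) is available. The deterministic default was chosen
  because a planted cohort composition (e.g. 4 of 27 larvae at ratio 1.5)
  should classify identically under any seed, and the binomial spread of
  Bernoulli conduction over a 30 s recording occasionally carries a
  ratio-1.5 larva outside the intermediate band.
* Locomotion: 10 Hz positions in a 7 mm well; immobility broken by
  Poisson-process swim bouts whose displacement is spread over ~0.3 s;
  seizure-like bursts are planted at a per-group Poisson rate per minute,
  each confined to a single 1 s analysis window so the per-larva
  ground-truth episode count is exact. Positions fold back into the arena
  by specular reflection. Default bout statistics (0.2 bouts/s, ~1.2 mm
  per bout) were chosen once as plausible larval baseline behaviour; the
  burst displacement (~10 mm) is constrained to sit strictly above the
  baseline distribution so planted truth is well defined.
* Volumes: ellipsoidal brain and region masks on a shared reference grid;
  a planted volumetric factor `f` adds the constant `ln f` to the LJD
  inside the region (the analysis consumes LJD values, so composing
  actual deformations is unnecessary), making region-integrated volume
  identities exact at zero noise; noise is a smooth Gaussian random field
  (sigma 1.5 voxels), emulating the spatial correlation of registration
  residuals.
* Fluorescence: 150 frames at 0.5 Hz (5 min); sparse single-frame events
  of amplitude `a` times baseline, so the planted dF/F is exactly `100 a`
  at event voxels.

All cohort seeds derive from the master seed via a stable label hash, so
any subject can be regenerated bit-identically in isolation.

What the generator does *not* emulate: real cardiac waveform morphology
and amplitude variability, wall-motion artefacts, tracking dropouts,
anatomically shaped regions, registration failures, or indicator
photobleaching beyond a linear trend. Passing tests therefore demonstrate
correctness of the quantification given its stated input model, not
robustness to every artefact of real recordings.

## Problem sizes and numerical choices

The validation suite runs at desk scale: cardiac cohorts of 27–41 larvae
at 30–60 s per trace; behavioural calibration pools of 120 larvae x 900
windows (1.08e5 windows, enough for a stable 99.9th percentile);
morphometry grids of 16x16x8 to 32x32x16 voxels with 10–20 subjects per
group. The family-wise error of the cluster procedure is verified over
500 independently generated null cohorts (7+7 subjects, 200 permutations
each), where the measured rate must sit within 2 points of the nominal
5%. Quantile definitions are type-1 (lower order statistic) throughout
the thresholding code; periodograms use the exact `fs/n` frequency grid
(no padding) so the reported resolution is honest; Welch t statistics use
the Welch–Satterthwaite degrees of freedom and mark zero-variance voxels
absent rather than infinite.

## Interfaces

The package's interface is its functions plus plain-text I/O: traces and
tracks as CSV, volumes and masks as NIfTI with voxel size in the header
(`write_trace_csv()`, `write_tracks_csv()`, `write_volume_nifti()` and
their readers), and per-larva assessment tables from `assess_cohort()`
ready for `write.csv`. The repository's `scripts/acceptance.R` recomputes
the headline quantities end to end from freshly generated synthetic
cohorts.

## Known limitations

* The Fourier rate estimator reports the dominant periodicity; under
  irregular conduction it can lock to the atrial frequency. Use the peak
  method for classification.
* The AV bands are calibrated for 30–60 s recordings; much shorter traces
  need wider bands (pass `av_bands(tol = ...)`).
* Cluster-extent inference is conservative for small, intense effects;
  the planted-effect tests use regions of ~100 voxels.
* `symmetrize()` assumes the grid is already aligned so that the declared
  axis flip is the anatomical mirror; no registration is performed.
* Volumes are Jacobian integrals over reference masks; if a segmentation
  in subject space is available, the voxel-counting mode is the more
  direct measurement.
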