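#' Write / read a dual-chamber trace as CSV
#'
#' Plain-text interchange format: columns `time_s`, `atrium`, `ventricle`.
#' The sampling rate is recovered from the time stamps on read.
#'
#' @param trace A [dual_chamber_trace()].
#' @param path File path.
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   returns a [dual_chamber_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "dual_chamber_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param subject_id,recording_id Labels for the trace read back.
#' @export
read_trace_csv <- function(path, subject_id = "s1", recording_id = "r1") {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_s", "atrium", "ventricle") %in% names(d)))
  fs <- 1 / stats::median(diff(d$time_s))
  dual_chamber_trace(d$time_s, d$atrium, d$ventricle, fs,
                     subject_id = subject_id, recording_id = recording_id)
}

#' Write / read tracking tables as CSV
#'
#' Columns: `larva_id`, `time_s`, `x_mm`, `y_mm`, `genotype`, `treatment`,
#' `phase`.
#'
#' @param tracks Tracking data frame (see [simulate_tracks()]).
#' @param path File path.
#' @return `write_tracks_csv()` returns `path` invisibly;
#'   `read_tracks_csv()` returns the data frame.
#' @export
write_tracks_csv <- function(tracks, path) {
  utils::write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("larva_id", "time_s", "x_mm", "y_mm") %in% names(d)))
  d
}

#' Write / read a volume as NIfTI
#'
#' Thin wrappers over RNifti that carry the voxel size in the header.
#'
#' @param vol 3-D numeric or logical array.
#' @param path File path (`.nii` or `.nii.gz`).
#' @param voxel_size_um Voxel spacing recorded in the header (micrometres).
#' @return `write_volume_nifti()` returns `path` invisibly;
#'   `read_volume_nifti()` returns a plain array with a `voxel_size_um`
#'   attribute.
#' @export
write_volume_nifti <- function(vol, path, voxel_size_um = c(1, 1, 1)) {
  img <- RNifti::asNifti(vol + 0)
  RNifti::pixdim(img) <- voxel_size_um
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "voxel_size_um") <- RNifti::pixdim(img)[seq_along(dim(img))]
  out
}
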