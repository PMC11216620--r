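#' Acquisition metadata for a DCE series
#'
#' Holds the timing and pulse-sequence parameters of a dynamic
#' contrast-enhanced acquisition. Frames are 1-based; `injection_frame` is
#' the last frame acquired before the contrast bolus, so the first
#' post-injection frame is `injection_frame + 1` (the bolus is given
#' between the two).
#'
#' @param frame_interval_s Temporal footprint of one dynamic frame, seconds.
#' @param injection_frame Index of the last pre-injection frame (default 4).
#' @param tr_ms,te_ms Repetition and echo time, milliseconds.
#' @param flip_angle_deg Excitation flip angle, degrees.
#' @param voxel_size_mm Length-3 voxel edge lengths, millimetres.
#' @param n_slices,n_frames Grid extents.
#' @return An object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(frame_interval_s, injection_frame = 4,
                             tr_ms = 101.493, te_ms = 1.872,
                             flip_angle_deg = 75,
                             voxel_size_mm = c(0.156, 0.156, 0.85),
                             n_slices, n_frames) {
  if (!is.finite(frame_interval_s) || frame_interval_s <= 0)
    stopf("frame_interval_s must be > 0")
  if (!is.finite(injection_frame) || injection_frame < 1 ||
      injection_frame >= n_frames)
    stopf("injection_frame must satisfy 1 <= injection_frame < n_frames")
  if (length(voxel_size_mm) != 3 || any(voxel_size_mm <= 0))
    stopf("voxel_size_mm must be three positive lengths")
  structure(list(frame_interval_s = frame_interval_s,
                 injection_frame = as.integer(injection_frame),
                 tr_ms = tr_ms, te_ms = te_ms,
                 flip_angle_deg = flip_angle_deg,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 n_slices = as.integer(n_slices),
                 n_frames = as.integer(n_frames)),
            class = "acquisition_meta")
}

#' A 4-D dynamic contrast-enhanced image series
#'
#' @param intensities 4-D numeric array `(x, y, slice, frame)`, arbitrary
#'   signal units.
#' @param meta An [acquisition_meta()] object consistent with the array.
#' @return An object of class `dce_series`.
#' @export
dce_series <- function(intensities, meta) {
  d <- dim(intensities)
  if (length(d) != 4) stopf("intensities must be a 4-D array")
  if (!inherits(meta, "acquisition_meta")) stopf("meta must be acquisition_meta")
  if (d[3] != meta$n_slices || d[4] != meta$n_frames)
    stopf("array dims (%s) disagree with metadata (%d slices, %d frames)",
          paste(d, collapse = "x"), meta$n_slices, meta$n_frames)
  if (!all(is.finite(intensities))) stopf("intensities must be finite")
  structure(list(intensities = intensities, meta = meta),
            class = "dce_series")
}

#' @export
print.dce_series <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("DCE series: %d x %d x %d voxels, %d frames @ %.3g s\n",
              d[1], d[2], d[3], d[4], x$meta$frame_interval_s))
  cat(sprintf("  injection after frame %d; TR %.3f ms, FA %g deg\n",
              x$meta$injection_frame, x$meta$tr_ms, x$meta$flip_angle_deg))
  invisible(x)
}

#' @export
dim.dce_series <- function(x) dim(x$intensities)

as_series_array <- function(x) {
  if (inherits(x, "dce_series")) x$intensities
  else if (is.array(x) && length(dim(x)) == 4) x
  else stopf("expected a dce_series or a 4-D array")
}

#' Save a volume or series as NIfTI-1
#'
#' Values round-trip exactly: arrays are written with a 64-bit float
#' datatype.
#'
#' @param volume Numeric array (3-D or 4-D), or a [dce_series()].
#' @param path Output `.nii`/`.nii.gz` path.
#' @param voxel_size_mm Optional voxel size recorded in the header.
#' @return The path, invisibly.
#' @export
save_map <- function(volume, path, voxel_size_mm = NULL) {
  if (inherits(volume, "dce_series")) {
    voxel_size_mm <- voxel_size_mm %||% volume$meta$voxel_size_mm
    volume <- volume$intensities
  }
  if (!is.null(voxel_size_mm))
    RNifti::pixdim(volume) <- c(voxel_size_mm,
                                rep(1, max(0, length(dim(volume)) - 3)))
  RNifti::writeNifti(volume, path, datatype = "double")
  invisible(path)
}

#' Load a volume from NIfTI-1
#'
#' @param path NIfTI file path.
#' @return A plain numeric array.
#' @export
load_map <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  arr
}

#' Write / read the JSON acquisition sidecar
#'
#' @param meta An [acquisition_meta()].
#' @param path JSON path.
#' @return `save_sidecar`: the path; `load_sidecar`: an `acquisition_meta`.
#' @export
save_sidecar <- function(meta, path) {
  jsonlite::write_json(unclass(meta), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_sidecar
#' @export
load_sidecar <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("frame_interval_s", "injection_frame", "tr_ms",
                "flip_angle_deg", "voxel_size_mm", "n_slices", "n_frames")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stopf("sidecar %s is missing required metadata: %s", path,
          paste(missing, collapse = ", "))
  acquisition_meta(frame_interval_s = x$frame_interval_s,
                   injection_frame = x$injection_frame,
                   tr_ms = x$tr_ms, te_ms = x$te_ms %||% NA_real_,
                   flip_angle_deg = x$flip_angle_deg,
                   voxel_size_mm = x$voxel_size_mm,
                   n_slices = x$n_slices, n_frames = x$n_frames)
}

#' Load a DCE series (NIfTI + JSON sidecar)
#'
#' @param path 4-D NIfTI path.
#' @param sidecar JSON sidecar path with the acquisition metadata.
#' @return A [dce_series()].
#' @export
load_dce_series <- function(path, sidecar) {
  arr <- load_map(path)
  meta <- load_sidecar(sidecar)
  dce_series(arr, meta)
}

#' Check that a label map shares the spatial grid of a series
#' @noRd
check_grid <- function(series, label_map) {
  d <- dim(as_series_array(series))[1:3]
  if (!identical(as.integer(dim(label_map)), as.integer(d)))
    stopf("label map grid (%s) does not match series grid (%s)",
          paste(dim(label_map), collapse = "x"), paste(d, collapse = "x"))
  invisible(TRUE)
}
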