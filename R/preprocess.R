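#' Temporal denoising: median filter then morphological closing
#'
#' Removes maternal-respiration spikes and transient large translations
#' from every voxel's time course: a 1-D temporal median filter (window
#' `time_window`) followed by 1-D grayscale morphological closing
#' (dilation then erosion with a flat structuring element of
#' `closing_length` frames). Time courses are replicate-padded at both
#' ends; spatial dimensions and metadata are unchanged.
#'
#' @param series A [dce_series()] or 4-D array.
#' @param time_window Odd median window length in frames (default 3).
#' @param closing_length Odd structuring-element length in frames (default 3).
#' @return Same type as the input, filtered along time.
#' @export
temporal_denoise <- function(series, time_window = 3, closing_length = 3) {
  arr <- as_series_array(series)
  d <- dim(arr)
  time_window <- check_odd_window(time_window, d[4], "time_window")
  closing_length <- check_odd_window(closing_length, d[4], "closing_length")
  m <- matrix(arr, nrow = prod(d[1:3]), ncol = d[4])
  if (time_window > 1) m <- cpp_row_median(m, time_window)
  if (closing_length > 1) {
    m <- cpp_row_extremum(m, closing_length, TRUE)   # dilate
    m <- cpp_row_extremum(m, closing_length, FALSE)  # erode
  }
  out <- array(m, dim = d)
  if (inherits(series, "dce_series")) dce_series(out, series$meta) else out
}

#' 3 x 3 x 3 spatial median filter
#'
#' Each voxel is replaced by the median over its 27-voxel neighbourhood
#' with replicate edge padding. A 4-D input is filtered frame by frame.
#'
#' @param volume_or_frame 3-D volume, 4-D series array, or [dce_series()].
#' @return Same type as the input.
#' @export
spatial_median3 <- function(volume_or_frame) {
  if (inherits(volume_or_frame, "dce_series")) {
    out <- spatial_median3(volume_or_frame$intensities)
    return(dce_series(out, volume_or_frame$meta))
  }
  d <- dim(volume_or_frame)
  if (is.null(d) || !(length(d) %in% c(3, 4)))
    stopf("expected a 3-D or 4-D array")
  if (any(d[1:3] < 3)) stopf("need at least 3 voxels along each spatial axis")
  if (length(d) == 4) {
    out <- volume_or_frame
    for (t in seq_len(d[4]))
      out[, , , t] <- array(cpp_median3(as.numeric(volume_or_frame[, , , t]),
                                        d[1], d[2], d[3]), d[1:3])
    return(out)
  }
  array(cpp_median3(as.numeric(volume_or_frame), d[1], d[2], d[3]), d[1:3])
}

#' Mean-removed maximum intensity projection
#'
#' The mean kinetic image is the frame average over the initial uptake
#' phase; the projection is, per voxel, the maximum over all frames of the
#' signal minus that mean. Serves as the segmentation reference image.
#'
#' @param series A [dce_series()] or 4-D array.
#' @param uptake_frames Integer frame indices of the initial uptake phase
#'   (typically first post-injection frame through the AIF peak frame).
#' @return 3-D projection array.
#' @export
mean_removed_mip <- function(series, uptake_frames) {
  arr <- as_series_array(series)
  d <- dim(arr)
  uptake_frames <- as.integer(uptake_frames)
  if (length(uptake_frames) == 0)
    stopf("uptake_frames must be a nonempty frame range")
  if (any(uptake_frames < 1 | uptake_frames > d[4]))
    stopf("uptake_frames out of range 1..%d", d[4])
  m <- matrix(arr, nrow = prod(d[1:3]), ncol = d[4])
  mean_kinetic <- rowMeans(m[, uptake_frames, drop = FALSE])
  proj <- apply(m - mean_kinetic, 1, max)
  array(proj, dim = d[1:3])
}
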