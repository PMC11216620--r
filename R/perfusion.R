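#' Extract the arterial input function from a renal-hilum ROI
#'
#' Per-frame mean over the ROI, minus the mean of the pre-injection
#' frames. The peak enhancement (which normalises the steepest-slope
#' model) and the steepest slope of the trace itself (max forward
#' difference over the frame interval) are recorded.
#'
#' @param series A [dce_series()].
#' @param label_map Integer volume on the series grid.
#' @param roles Optional role table (`label`, `role`) as produced by the
#'   phantom; the ROI is the label with role `"aif"`.
#' @param aif_label ROI label, used when `roles` is not given.
#' @return An object of class `aif_trace`.
#' @export
extract_aif <- function(series, label_map, roles = NULL, aif_label = NULL) {
  stopifnot(inherits(series, "dce_series"))
  check_grid(series, label_map)
  if (is.null(aif_label)) {
    if (is.null(roles) || !any(roles$role == "aif"))
      stopf("no AIF label: supply aif_label or a roles table with role 'aif'")
    aif_label <- roles$label[roles$role == "aif"][1]
  }
  vox <- which(label_map == aif_label)
  if (length(vox) == 0) stopf("AIF ROI (label %s) is empty", aif_label)
  d <- dim(series$intensities)
  m <- matrix(series$intensities, nrow = prod(d[1:3]), ncol = d[4])
  trace <- colMeans(m[vox, , drop = FALSE])
  inj <- series$meta$injection_frame
  enh <- trace - mean(trace[seq_len(inj)])
  peak <- max(enh); peak_index <- which.max(enh)
  if (peak <= 0)
    stopf("degenerate AIF: no positive enhancement in the ROI")
  dt <- series$meta$frame_interval_s
  structure(list(time_s = (seq_len(d[4]) - 1) * dt,
                 enhancement = enh,
                 peak_value = peak, peak_index = peak_index,
                 steepest_slope = max(diff(enh)) / dt,
                 frame_interval_s = dt, n_roi_voxels = length(vox)),
            class = "aif_trace")
}

#' @export
print.aif_trace <- function(x, ...) {
  cat(sprintf("AIF trace: %d frames, peak %.4g at frame %d (t = %g s)\n",
              length(x$enhancement), x$peak_value, x$peak_index,
              x$time_s[x$peak_index]))
  cat(sprintf("  steepest slope %.4g signal/s over %d ROI voxels\n",
              x$steepest_slope, x$n_roi_voxels))
  invisible(x)
}

#' @export
plot.aif_trace <- function(x, ...) {
  graphics::plot(x$time_s, x$enhancement, type = "b",
                 xlab = "time (s)", ylab = "enhancement (signal units)",
                 main = "Arterial input function", ...)
  graphics::abline(v = x$time_s[x$peak_index], lty = 2)
  invisible(x)
}

#' Voxelwise steepest slope of the uptake curve
#'
#' Per voxel, the maximum forward difference of the (baseline-subtracted)
#' signal divided by the frame interval, clamped at zero; the frame index
#' at which it occurs is stored. Expects a series already
#' motion-corrected, temporally denoised and spatially median filtered.
#'
#' @param series A [dce_series()].
#' @param baseline_frames Frames averaged as the pre-injection baseline
#'   (default `1:injection_frame` from the metadata).
#' @return An object of class `steepest_slope_map`: `slope` (signal
#'   units/s), `argmax_frame`.
#' @export
steepest_slope_map <- function(series, baseline_frames = NULL) {
  stopifnot(inherits(series, "dce_series"))
  d <- dim(series$intensities)
  if (d[4] < 2) stopf("need at least 2 frames")
  baseline_frames <- baseline_frames %||% seq_len(series$meta$injection_frame)
  m <- matrix(series$intensities, nrow = prod(d[1:3]), ncol = d[4])
  m <- m - rowMeans(m[, baseline_frames, drop = FALSE])
  dt <- series$meta$frame_interval_s
  dm <- m[, -1, drop = FALSE] - m[, -d[4], drop = FALSE]
  am <- max.col(dm, ties.method = "first")
  best <- dm[cbind(seq_len(nrow(dm)), am)]
  structure(list(slope = array(pmax(best / dt, 0), d[1:3]),
                 argmax_frame = array(am, d[1:3]),
                 frame_interval_s = dt),
            class = "steepest_slope_map")
}

#' Steepest-slope perfusion map
#'
#' One-parameter perfusion estimate: the voxel's maximal uptake rate
#' normalised by the peak of the arterial input,
#' \deqn{F/V_T \cong \frac{[dC_T/dt]_{max}}{[C_A]_{max}}}
#' in 1/s, reported as mL/min/100 mL via the factor 6000. Signal
#' enhancement stands in for concentration (linear signal-concentration
#' assumption), so the global signal scale cancels.
#'
#' @param ss A [steepest_slope_map()].
#' @param aif An [aif_trace()].
#' @return An object of class `perfusion_map` with `f_over_vt`
#'   (mL/min/100 mL per voxel).
#' @export
perfusion_map <- function(ss, aif) {
  stopifnot(inherits(ss, "steepest_slope_map"), inherits(aif, "aif_trace"))
  if (aif$peak_value <= 0) stopf("degenerate AIF: peak enhancement <= 0")
  structure(list(f_over_vt = 6000 * ss$slope / aif$peak_value,
                 aif_peak = aif$peak_value,
                 frame_interval_s = ss$frame_interval_s),
            class = "perfusion_map")
}

#' @export
print.perfusion_map <- function(x, ...) {
  v <- x$f_over_vt[x$f_over_vt > 0]
  cat(sprintf("Perfusion map: %s grid; nonzero voxels %d, median %.4g mL/min/100mL\n",
              paste(dim(x$f_over_vt), collapse = "x"), length(v),
              if (length(v)) median(v) else NA))
  invisible(x)
}
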