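# modified periodogram of one windowed segment matrix (nt x nvox);
# returns one-sided PSD (nfreq x nvox), density scaling
segment_psd <- function(seg, w, fs) {
  nt <- nrow(seg)
  seg <- seg - matrix(colMeans(seg), nt, ncol(seg), byrow = TRUE)
  X <- mvfft(seg * w)
  P <- Mod(X)^2 / (fs * sum(w^2))
  nf <- floor(nt / 2) + 1
  P <- P[seq_len(nf), , drop = FALSE]
  # one-sided: double everything except DC (and Nyquist when nt is even)
  dbl <- seq(2, nf - if (nt %% 2 == 0) 1 else 0)
  P[dbl, ] <- 2 * P[dbl, , drop = FALSE]
  P
}

welch_segments <- function(n, seg_len, overlap_fraction) {
  hop <- max(1L, as.integer(round(seg_len * (1 - overlap_fraction))))
  starts <- seq(1L, n - seg_len + 1L, by = hop)
  lapply(starts, function(s) s:(s + seg_len - 1L))
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram: the trace is split into
#' `segment_length`-sample segments with `overlap_fraction` overlap, each
#' segment is mean-removed, Hamming-windowed and transformed, and the
#' one-sided periodograms are averaged. Default segment length is
#' `floor(n/4)` forced odd; with `segment_length = length(trace)` the
#' estimate degenerates to the raw (modified) periodogram.
#'
#' @param trace Numeric time series.
#' @param fs Sampling frequency, Hz.
#' @param segment_length Samples per segment.
#' @param overlap_fraction Overlap between segments (default 0.5).
#' @return An object of class `welch_psd`: `freq` (Hz, 0 to `fs/2`),
#'   `psd` (power per Hz), `df`, `segment_length`, `n_segments`.
#' @export
welch_psd <- function(trace, fs, segment_length = NULL,
                      overlap_fraction = 0.5) {
  n <- length(trace)
  if (is.null(segment_length)) {
    segment_length <- max(3L, floor(n / 4))
    if (segment_length %% 2 == 0) segment_length <- segment_length + 1L
  }
  if (segment_length > n)
    stopf("segment_length (%d) exceeds the trace length (%d)",
          segment_length, n)
  if (segment_length < 2) stopf("segment_length must be >= 2")
  w <- signal::hamming(segment_length)
  segs <- welch_segments(n, segment_length, overlap_fraction)
  acc <- 0
  for (s in segs)
    acc <- acc + segment_psd(matrix(trace[s], ncol = 1), w, fs)
  psd <- as.numeric(acc) / length(segs)
  nf <- floor(segment_length / 2) + 1
  structure(list(freq = (seq_len(nf) - 1) * fs / segment_length,
                 psd = psd, df = fs / segment_length,
                 segment_length = segment_length,
                 n_segments = length(segs)),
            class = "welch_psd")
}

#' @export
print.welch_psd <- function(x, ...) {
  cat(sprintf("Welch PSD: %d segments of %d samples; %d bins up to %.4g Hz\n",
              x$n_segments, x$segment_length, length(x$freq),
              max(x$freq)))
  pk <- which.max(x$psd)
  cat(sprintf("  peak at %.4g Hz\n", x$freq[pk]))
  invisible(x)
}

#' @export
plot.welch_psd <- function(x, ...) {
  graphics::plot(x$freq * 1000, x$psd, type = "l", xlab = "frequency (mHz)",
                 ylab = "power / Hz", main = "Welch periodogram", ...)
  invisible(x)
}

#' Short-time Fourier spectrogram of a motion trace
#'
#' Magnitude-squared STFT with a 15-sample Bartlett window, 50% overlap
#' between segments and a zero-padded transform length of ten times the
#' trace length.
#'
#' @param trace Numeric time series (length >= `window_length`).
#' @param fs Sampling frequency, Hz.
#' @param window_length Bartlett window length (default 15).
#' @param overlap Samples shared by consecutive segments (default 50%,
#'   i.e. `floor(window_length/2)`).
#' @param nfft Transform length (default `10 * length(trace)`).
#' @return An object of class `stft_spectrogram`: `power` (freq x time),
#'   `freq` (Hz), `time_s`, and the framing parameters.
#' @export
spectrogram_stft <- function(trace, fs, window_length = 15, overlap = NULL,
                             nfft = NULL) {
  n <- length(trace)
  if (n < window_length)
    stopf("trace (%d samples) shorter than the %d-sample window",
          n, window_length)
  overlap <- overlap %||% floor(window_length / 2)
  nfft <- nfft %||% (10L * n)
  sg <- signal::specgram(trace, n = nfft, Fs = fs,
                         window = signal::bartlett(window_length),
                         overlap = overlap)
  structure(list(power = Mod(sg$S)^2, freq = as.numeric(sg$f),
                 time_s = as.numeric(sg$t),
                 window_length = window_length, overlap = overlap,
                 nfft = nfft),
            class = "stft_spectrogram")
}

#' @export
print.stft_spectrogram <- function(x, ...) {
  cat(sprintf("STFT spectrogram: %d frequency bins x %d segments (window %d, overlap %d, nfft %d)\n",
              nrow(x$power), ncol(x$power), x$window_length, x$overlap,
              x$nfft))
  invisible(x)
}

#' Voxelwise relative power in a frequency sub-band
#'
#' For every voxel, the periodogram of the mean-removed intensity time
#' course is computed (Welch machinery; a single full-length segment by
#' default, i.e. the raw modified periodogram) and the power inside
#' `band_hz` is expressed as a fraction of the total power. Voxels with
#' zero total power get relative power 0. When a label map and chamber
#' assignments are supplied, per-placenta per-chamber means are
#' summarised.
#'
#' @param series A [dce_series()] or 4-D array.
#' @param band_hz Sub-band, Hz (default 8-12 mHz).
#' @param fs Sampling frequency; default from the series metadata.
#' @param segment_length Welch segment length (default: full trace).
#' @param label_map,chambers Optional region definitions for the summary.
#' @return An object of class `subband_map`: `rel_power` (3-D array in
#'   [0, 1]), `freq`, `band_hz`, and optionally `summary` (data frame of
#'   per-region mean relative power).
#' @export
subband_relative_power_map <- function(series, band_hz = c(0.008, 0.012),
                                       fs = NULL, segment_length = NULL,
                                       label_map = NULL, chambers = NULL) {
  arr <- as_series_array(series)
  d <- dim(arr)
  fs <- fs %||% (if (inherits(series, "dce_series"))
    1 / series$meta$frame_interval_s else stopf("fs required for bare arrays"))
  seg_len <- segment_length %||% d[4]
  if (seg_len > d[4]) stopf("segment_length exceeds the number of frames")
  nv <- prod(d[1:3])
  M <- t(matrix(arr, nrow = nv, ncol = d[4]))  # time x voxel
  w <- signal::hamming(seg_len)
  segs <- welch_segments(d[4], seg_len, 0.5)
  acc <- 0
  for (s in segs) acc <- acc + segment_psd(M[s, , drop = FALSE], w, fs)
  P <- acc / length(segs)
  freq <- (seq_len(nrow(P)) - 1) * fs / seg_len
  in_band <- freq >= band_hz[1] & freq <= band_hz[2]
  if (!any(in_band))
    warnf("no frequency bin falls inside the %g-%g Hz band", band_hz[1],
          band_hz[2])
  total <- colSums(P)
  band <- colSums(P[in_band, , drop = FALSE])
  rel <- ifelse(total > 0, band / total, 0)
  out <- list(rel_power = array(rel, d[1:3]), freq = freq,
              band_hz = band_hz, segment_length = seg_len)
  if (!is.null(label_map)) {
    labs <- if (!is.null(chambers)) chambers$placenta_labels else
      setdiff(sort(unique(as.integer(label_map))), 0L)
    rows <- list()
    for (k in labs) {
      vox <- which(label_map == k)
      regions <- list(whole = vox)
      if (!is.null(chambers)) {
        asg <- chambers$assignments[[as.character(k)]]
        regions$low <- asg$voxels[asg$is_low]
        regions$high <- asg$voxels[!asg$is_low]
      }
      for (rg in names(regions)) {
        if (!length(regions[[rg]])) next
        rows[[length(rows) + 1]] <-
          data.frame(placenta = k, region = rg,
                     mean_rel_power = mean(out$rel_power[regions[[rg]]]),
                     max_rel_power = max(out$rel_power[regions[[rg]]]))
      }
    }
    out$summary <- do.call(rbind, rows)
  }
  structure(out, class = "subband_map")
}

#' @export
print.subband_map <- function(x, ...) {
  cat(sprintf("Sub-band relative power map (%g-%g mHz): grid %s\n",
              1000 * x$band_hz[1], 1000 * x$band_hz[2],
              paste(dim(x$rel_power), collapse = "x")))
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

#' Flag placentas with phasic motion
#'
#' A placenta is phasic when its chamber-maximum relative sub-band power
#' (the largest voxel relative power inside either chamber) exceeds
#' `threshold`. The voxel maximum is used because phasic displacement
#' modulates intensity most strongly where spatial gradients are steep,
#' while the contrast-uptake ramp keeps the chamber-mean relative power
#' low everywhere.
#'
#' @param subband A [subband_relative_power_map()] result carrying a
#'   per-chamber `summary`, or that summary data frame itself.
#' @param threshold Relative-power cutoff (default 0.2).
#' @return Data frame `(placenta, max_chamber_power, phasic)`.
#' @export
classify_phasic <- function(subband, threshold = 0.2) {
  sm <- if (inherits(subband, "subband_map")) subband$summary else subband
  if (is.null(sm)) stopf("no per-region summary available")
  ch <- sm[sm$region %in% c("low", "high"), ]
  if (nrow(ch) == 0) ch <- sm  # whole-placenta fallback
  stat <- if ("max_rel_power" %in% names(ch)) ch$max_rel_power else
    ch$mean_rel_power
  agg <- tapply(stat, ch$placenta, max)
  data.frame(placenta = as.integer(names(agg)),
             max_chamber_power = as.numeric(agg),
             phasic = as.numeric(agg) > threshold,
             row.names = NULL)
}
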