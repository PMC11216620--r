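gauss_blob <- function(n, cx, cy, s = 4, amp = 100) {
  x <- matrix(seq_len(n), n, n)
  y <- t(x)
  amp * exp(-((x - cx)^2 + (y - cy)^2) / (2 * s^2))
}

test_that("Horn-Schunck flow honours its fixed points and invariances", {
  a <- gauss_blob(32, 16, 16)
  fl <- horn_schunck(a, a)
  expect_equal(fl$u, matrix(0, 32, 32))
  expect_equal(fl$v, matrix(0, 32, 32))

  # constant offset added to both frames leaves the flow unchanged
  b <- gauss_blob(32, 17, 16)
  f1 <- horn_schunck(a, b, n_iter = 60)
  f2 <- horn_schunck(a + 50, b + 50, n_iter = 60)
  expect_equal(f1$u, f2$u, tolerance = 1e-10)

  expect_error(horn_schunck(a, a[1:10, ]), "shapes")
  expect_error(horn_schunck(a, a, alpha = 0), "alpha")
})

test_that("a programmed unit shift is recovered inside the blob", {
  a <- gauss_blob(40, 20, 20, s = 5)
  b <- gauss_blob(40, 21, 20, s = 5)   # shifted by (1, 0) in x
  fl <- horn_schunck(a, b, n_iter = 400, tol = 1e-8)
  core <- a > 0.3 * max(a)
  expect_equal(mean(fl$u[core]), 1, tolerance = 0.2)
  expect_lt(abs(mean(fl$v[core])), 0.2)
})

test_that("the flow solution does not increase the HS energy", {
  a <- gauss_blob(24, 12, 12)
  b <- gauss_blob(24, 13, 12)
  energy <- function(fl) {
    u <- fl$u; v <- fl$v
    gx <- function(m) rbind(diff(m), 0)
    gy <- function(m) cbind(t(apply(m, 1, diff)), 0)
    # data term via simple forward-difference gradients
    Ix <- rbind(diff(a), 0); Iy <- cbind(t(apply(a, 1, diff)), 0)
    It <- b - a
    sum((Ix * u + Iy * v + It)^2) +
      100 * sum(gx(u)^2 + gy(u)^2 + gx(v)^2 + gy(v)^2)
  }
  e0 <- energy(list(u = matrix(0, 24, 24), v = matrix(0, 24, 24)))
  prev <- e0
  for (k in c(5, 20, 80)) {
    ek <- energy(horn_schunck(a, b, n_iter = k))
    expect_lte(ek, prev * (1 + 1e-6))
    prev <- ek
  }
})

test_that("velocity traces aggregate chamber motion correctly", {
  d <- c(8, 8, 2, 5)
  fields <- structure(list(u = array(0, c(d[1:3], 4)),
                           v = array(0, c(d[1:3], 4)),
                           magnitude = array(0, c(d[1:3], 4)),
                           frame_interval_s = 18),
                      class = "flow_fields")
  labs <- array(0L, d[1:3]); labs[2:7, 2:7, ] <- 1L
  tr <- velocity_traces(fields, labs)
  expect_true(all(tr$mean_speed == 0))
  expect_equal(nrow(tr), 4)

  # whole-placenta trace is the voxel-weighted mean of chamber traces
  set.seed(41)
  fields$magnitude <- array(runif(prod(d[1:3]) * 4), c(d[1:3], 4))
  f <- array(runif(prod(d[1:3])), d[1:3])
  ch <- assign_chambers(f, labs, "E14.5")
  tr <- velocity_traces(fields, labs, ch)
  w <- tapply(tr$mean_speed, tr$region, identity)
  n_low <- sum(ch$assignments[["1"]]$is_low)
  n_high <- sum(!ch$assignments[["1"]]$is_low)
  expect_equal(w$whole, (n_low * w$low + n_high * w$high) / (n_low + n_high))
})

test_that("motion programmed in the high chamber dominates its trace", {
  spec <- small_spec("E17.5", seed = 3,
                     motion_spec = list(prevalence = 1))
  ph <- synthesize_dce(spec)
  fl <- flow_series(temporal_denoise(ph$dce), n_iter = 40)
  ch <- structure(list(assignments = lapply(seq_len(4), function(k) {
    vox <- which(ph$label_map == k)
    list(voxels = vox, is_low = ph$truth$chamber_map[vox] == 1)
  }), placenta_labels = 1:4), class = "chamber_set")
  names(ch$assignments) <- as.character(1:4)
  tr <- velocity_traces(fl, ph$label_map, ch, 18)
  agg <- tapply(tr$mean_speed, tr$region, mean)
  expect_gt(agg["high"], agg["low"])
})

test_that("Welch periodogram finds tones and conserves power", {
  fs <- 1 / 18
  t <- default_time_grid(50)
  x <- sin(2 * pi * 0.010 * t)
  p <- welch_psd(x, fs)
  expect_equal(p$freq[which.max(p$psd)],
               p$freq[which.min(abs(p$freq - 0.010))])
  expect_true(all(p$psd >= 0))
  expect_lte(max(p$freq), fs / 2)

  # full-length segment reaches the Nyquist limit: 27.8 mHz at 55.6 mHz
  pfull <- welch_psd(x, fs, segment_length = 50)
  expect_equal(max(pfull$freq) * 1000, 27.8, tolerance = 0.1)

  # Parseval within window bias
  set.seed(43)
  y <- rnorm(64); y <- y - mean(y)
  py <- welch_psd(y, fs, segment_length = 64)
  expect_equal(sum(py$psd) * py$df, mean(y^2), tolerance = 0.1)
  expect_error(welch_psd(y, fs, segment_length = 100), "exceeds")
})

test_that("the spectrogram uses the documented framing", {
  fs <- 1 / 18
  x <- rep(3, 50)
  sg <- spectrogram_stft(x, fs)
  expect_equal(ncol(sg$power), floor((50 - 7) / 8))
  expect_equal(sg$nfft, 500)
  # constant trace: every column peaks at DC
  expect_true(all(apply(sg$power, 2, which.max) == 1))
  expect_lte(max(sg$freq), fs / 2)

  # tone switching on halfway raises band power in late columns
  t <- default_time_grid(60)
  x <- c(rep(0, 30), sin(2 * pi * 0.012 * t[31:60]))
  sg <- spectrogram_stft(x, fs)
  band <- sg$freq >= 0.008 & sg$freq <= 0.016
  colpow <- colSums(sg$power[band, , drop = FALSE])
  n <- length(colpow)
  expect_gt(mean(colpow[(n %/% 2 + 1):n]), mean(colpow[1:(n %/% 2)]) * 5)
  expect_error(spectrogram_stft(x[1:10], fs), "shorter")
})

test_that("sub-band relative power separates oscillation from statics", {
  fs <- 1 / 18
  t <- default_time_grid(50)
  arr <- array(0, c(3, 3, 1, 50))
  arr[1, 1, 1, ] <- 10 + sin(2 * pi * 0.010 * t)   # pure 10 mHz
  arr[2, 2, 1, ] <- 7                               # static
  sb <- subband_relative_power_map(arr, fs = fs)
  expect_gt(sb$rel_power[1, 1, 1], 0.8)
  expect_equal(sb$rel_power[2, 2, 1], 0)
  expect_true(all(sb$rel_power >= 0 & sb$rel_power <= 1))
  expect_lte(max(sb$freq), fs / 2)

  # invariance to per-voxel affine intensity rescaling
  arr2 <- arr * 3.7 + 11
  sb2 <- subband_relative_power_map(arr2, fs = fs)
  expect_equal(sb2$rel_power, sb$rel_power, tolerance = 1e-10)
})

test_that("phasic classification follows the truth labels", {
  # zero motion: nothing flagged
  spec0 <- small_spec("E17.5", seed = 5, motion_spec = list(prevalence = 0))
  ph0 <- synthesize_dce(spec0)
  sb0 <- subband_relative_power_map(ph0$dce, label_map = ph0$label_map)
  cl0 <- classify_phasic(sb0)
  expect_equal(sum(cl0$phasic), 0)

  # unreachable threshold: nothing flagged even with motion
  spec1 <- small_spec("E17.5", seed = 5, motion_spec = list(prevalence = 1))
  ph1 <- synthesize_dce(spec1)
  sb1 <- subband_relative_power_map(ph1$dce, label_map = ph1$label_map)
  expect_equal(sum(classify_phasic(sb1, threshold = 1.01)$phasic), 0)
  # moving placentas exceed the default threshold
  expect_equal(sum(classify_phasic(sb1)$phasic), 4)
})
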