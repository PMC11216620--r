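#' Specification of the digital pregnancy phantom
#'
#' Defines a litter of ellipsoidal placentas on a voxel grid, each split
#' into a low- and a high-perfusion chamber, perfused by a shared
#' gamma-variate arterial bolus, imaged by a spoiled gradient-echo DCE
#' protocol and a pre/post variable-flip-angle protocol, with optional
#' phasic sub-voxel motion of the high-perfusion chamber. Defaults emulate
#' the study conditions: 18-s frames, 50 frames, injection between frames
#' 4 and 5, 0.156 x 0.156 x 0.85 mm voxels, DCE at TR 101.493 ms / FA 75
#' deg, VFA at TR 114.88 ms / FA 75, 55, 30, 20, 10 deg, AIF washing out
#' after ~350 s, and phasic-motion prevalence 11.1% at E14.5 versus 82.1%
#' at E17.5 at 10 mHz.
#'
#' @param n_placentas Litter size (6-12, default 8).
#' @param grid_shape Voxels per axis (default `c(128, 128, 10)`, which at
#'   the default voxel size gives near-anatomical placenta extents).
#' @param voxel_size_mm Voxel edge lengths, mm.
#' @param n_frames,frame_interval_s Dynamic frames and frame interval.
#' @param injection_frame Last pre-injection frame (default 4).
#' @param gestational_age `"E14.5"` or `"E17.5"`.
#' @param chamber_fractions Named `c(low=, high=)` volume fractions;
#'   defaults 0.55/0.45 at E14.5 and 0.45/0.55 at E17.5 (stereology-based
#'   labyrinth/decidua proportions that also motivate the analysis
#'   percentile thresholds).
#' @param true_perfusion Named `c(low=, high=)` chamber perfusion,
#'   mL/min/100 mL; defaults (30, 55) at E14.5 and (45.6, 79.97) at E17.5
#'   so that the programmed increases are 15.6 and 24.97.
#' @param aif_params List `delay_s` (bolus arrival; default the injection
#'   time), `rise_exponent`, `decay_s`, `peak` of the gamma-variate bolus.
#' @param r1_baseline_hz Pre-contrast placental R1, Hz (default 1/1.5 s).
#' @param relaxivity_hz Hz change in R1 per concentration unit (default
#'   0.75, keeping the signal-concentration map near-linear while the
#'   enhancement stays well above the noise floor).
#' @param noise_sigma Noise SD as a fraction of the mean baseline
#'   placental signal (default 0.02).
#' @param noise_model `"gaussian"` (additive, default) or `"rician"`.
#' @param motion_spec List `frequency_mhz` (candidate oscillation
#'   frequencies, default 10), `amplitude_voxels` (default 0.5),
#'   `prevalence` (fraction of placentas moving; default by age).
#' @param seed Integer seed controlling all phantom randomness.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_placentas = 8,
                         grid_shape = c(128, 128, 10),
                         voxel_size_mm = c(0.156, 0.156, 0.85),
                         n_frames = 50, frame_interval_s = 18,
                         injection_frame = 4,
                         gestational_age = c("E17.5", "E14.5"),
                         chamber_fractions = NULL,
                         true_perfusion = NULL,
                         aif_params = NULL,
                         r1_baseline_hz = 1 / 1.5,
                         relaxivity_hz = 0.75,
                         noise_sigma = 0.02,
                         noise_model = c("gaussian", "rician"),
                         motion_spec = NULL,
                         seed = 1L) {
  gestational_age <- match.arg(gestational_age)
  noise_model <- match.arg(noise_model)
  if (n_placentas < 1) stopf("n_placentas must be >= 1")
  if (frame_interval_s <= 0) stopf("frame_interval_s must be > 0")
  if (length(grid_shape) != 3 || any(grid_shape < 8))
    stopf("grid_shape must be three extents of at least 8 voxels")
  chamber_fractions <- chamber_fractions %||%
    switch(gestational_age,
           "E14.5" = c(low = 0.55, high = 0.45),
           "E17.5" = c(low = 0.45, high = 0.55))
  if (abs(sum(chamber_fractions) - 1) > 1e-8)
    stopf("chamber fractions must sum to 1")
  true_perfusion <- true_perfusion %||%
    switch(gestational_age,
           "E14.5" = c(low = 30, high = 55),
           "E17.5" = c(low = 30 + 15.6, high = 55 + 24.97))
  if (any(true_perfusion < 0)) stopf("perfusion must be >= 0")
  aif_params <- modifyList(
    list(delay_s = injection_frame * frame_interval_s,
         rise_exponent = 2, decay_s = 40, peak = 1),
    aif_params %||% list())
  motion_spec <- modifyList(
    list(frequency_mhz = 10, amplitude_voxels = 0.5,
         prevalence = switch(gestational_age, "E14.5" = 0.111,
                             "E17.5" = 0.821)),
    motion_spec %||% list())
  if (motion_spec$prevalence < 0 || motion_spec$prevalence > 1)
    stopf("motion prevalence must be in [0, 1]")
  structure(list(n_placentas = as.integer(n_placentas),
                 grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm,
                 n_frames = as.integer(n_frames),
                 frame_interval_s = frame_interval_s,
                 injection_frame = as.integer(injection_frame),
                 gestational_age = gestational_age,
                 chamber_fractions = chamber_fractions,
                 true_perfusion = true_perfusion,
                 aif_params = aif_params,
                 r1_baseline_hz = r1_baseline_hz,
                 relaxivity_hz = relaxivity_hz,
                 noise_sigma = noise_sigma, noise_model = noise_model,
                 motion_spec = motion_spec, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("Phantom spec: %d placentas at %s, grid %s, %d frames @ %g s\n",
              x$n_placentas, x$gestational_age,
              paste(x$grid_shape, collapse = "x"), x$n_frames,
              x$frame_interval_s))
  cat(sprintf("  perfusion low/high = %g/%g mL/min/100mL; motion prevalence %g\n",
              x$true_perfusion["low"], x$true_perfusion["high"],
              x$motion_spec$prevalence))
  invisible(x)
}

#' Gamma-variate arterial input function
#'
#' \deqn{C_A(t) = peak \left(\frac{t - t_0}{ab}\right)^{a}
#'   e^{\,a - (t - t_0)/b}} for `t > t0`, zero before; the peak value
#' `peak` is reached at `t0 + a*b`. Defaults place the peak ~80 s after
#' injection with washout well under way by 350 s.
#'
#' @param aif_params List with `delay_s` (bolus arrival time t0),
#'   `rise_exponent` (a > 0), `decay_s` (b > 0), `peak`.
#' @param time_grid Strictly increasing sample times, seconds.
#' @return Concentration trace at `time_grid` (arbitrary units).
#' @export
simulate_aif <- function(aif_params, time_grid) {
  if (any(diff(time_grid) <= 0))
    stopf("time_grid must be strictly increasing")
  t0 <- aif_params$delay_s; a <- aif_params$rise_exponent
  b <- aif_params$decay_s; peak <- aif_params$peak
  if (a <= 0 || b <= 0) stopf("rise_exponent and decay_s must be > 0")
  if (t0 < min(time_grid) - 1e-9 || t0 > max(time_grid))
    stopf("injection time %g s lies outside the time grid", t0)
  u <- pmax(time_grid - t0, 0)
  ifelse(u > 0, peak * (u / (a * b))^a * exp(a - u / b), 0)
}

#' Tissue concentration under the no-washout uptake model
#'
#' During wash-in, with no venous washout, the tissue concentration is the
#' running integral of the arterial input scaled by perfusion:
#' \deqn{C_T(t) = \frac{F}{V_T}\int_0^t C_A(\tau)\,d\tau} where
#' `F/V_T` in mL/min/100 mL converts to 1/s by division by 6000.
#'
#' @param aif_curve Arterial concentration sampled at `time_grid`.
#' @param f_over_vt Perfusion, mL/min/100 mL (>= 0).
#' @param time_grid Sample times, seconds.
#' @return Non-decreasing tissue concentration trace.
#' @export
simulate_tissue_uptake <- function(aif_curve, f_over_vt, time_grid) {
  if (f_over_vt < 0) stopf("f_over_vt must be >= 0")
  (f_over_vt / 6000) * cumtrapz1(time_grid, aif_curve)
}

# ellipsoidal litter geometry: placentas in the cells of a regular
# in-plane grid, one spare cell hosting the spherical AIF ROI
phantom_geometry <- function(spec) {
  g <- spec$grid_shape
  K <- spec$n_placentas
  ncell <- K + 1
  ncol_ <- ceiling(sqrt(ncell)); nrow_ <- ceiling(ncell / ncol_)
  cw <- g[1] / ncol_; ch <- g[2] / nrow_
  ax <- 0.38 * cw; ay <- 0.32 * ch; az <- max(1.1, 0.45 * g[3])
  label <- array(0L, g)
  chamber <- array(0L, g)   # 1 low, 2 high
  xs <- seq_len(g[1]); ys <- seq_len(g[2]); zs <- seq_len(g[3])
  cz <- (g[3] + 1) / 2
  centers <- matrix(NA_real_, K + 1, 3)
  for (k in seq_len(ncell)) {
    ci <- (k - 1) %% ncol_; ri <- (k - 1) %/% ncol_
    cx <- (ci + 0.5) * cw; cy <- (ri + 0.5) * ch
    centers[k, ] <- c(cx, cy, cz)
    dx <- outer(xs - cx, rep(1, g[2]))
    dy <- outer(rep(1, g[1]), ys - cy)
    if (k <= K) {
      for (z in zs) {
        q <- (dx / ax)^2 + (dy / ay)^2 + ((z - cz) / az)^2
        inside <- q <= 1
        sl <- label[, , z]
        sl[inside] <- k
        label[, , z] <- sl
      }
    } else {
      r <- max(1.5, 0.35 * min(ax, ay))
      for (z in zs) {
        q <- dx^2 + dy^2 + (z - cz)^2
        sl <- label[, , z]
        sl[q <= r^2] <- K + 1L
        label[, , z] <- sl
      }
    }
  }
  # chamber split: plane perpendicular to the in-plane long axis (x),
  # placed at the low-fraction quantile of the axial coordinate
  xcoord <- array(rep(xs, times = g[2] * g[3]), g)
  ycoord <- array(rep(rep(ys, each = g[1]), times = g[3]), g)
  for (k in seq_len(K)) {
    vox <- which(label == k)
    u <- xcoord[vox] - centers[k, 1] + 1e-4 * (ycoord[vox] - centers[k, 2])
    q <- quantile(u, spec$chamber_fractions["low"], type = 7)
    chamber[vox] <- ifelse(u < q, 1L, 2L)
  }
  list(label = label, chamber = chamber, centers = centers,
       semi_axes = c(ax, ay, az), aif_label = K + 1L)
}

#' Synthesize a DCE acquisition and VFA stacks from a phantom spec
#'
#' Forward model: per-voxel concentration from the gamma-variate bolus
#' (AIF region) or the no-washout uptake integral (chambers), linear
#' relaxivity `R1(t) = R1_0 + r1 C(t)`, Ernst-equation signal at the DCE
#' flip angle and TR. The proton-density field carries a smooth axial
#' gradient and a sinusoidal texture inside each placenta (emulating
#' labyrinth vascular texture) so that sub-voxel motion modulates voxel
#' intensity, as in real tissue. Phasic motion is a sinusoidal in-plane
#' translation of the high-perfusion chamber (linear interpolation),
#' applied to a seeded random subset of placentas of size
#' `round(prevalence * n_placentas)`. Noise is added last. Deterministic
#' given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `placenta_phantom`: `dce` ([dce_series()]),
#'   `vfa_pre`/`vfa_post` ([vfa_stack()]), `label_map`, `roles` (label
#'   role table), and `truth` (chamber map, per-chamber perfusion, R1
#'   volumes pre/post, motion table, AIF curve).
#' @export
synthesize_dce <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geom <- phantom_geometry(spec)
  if (spec$motion_spec$amplitude_voxels > geom$semi_axes[1])
    stopf("motion amplitude (%g voxels) exceeds the placental semi-axis (%g)",
          spec$motion_spec$amplitude_voxels, geom$semi_axes[1])
  set.seed(spec$seed)
  g <- spec$grid_shape; K <- spec$n_placentas
  tt <- (seq_len(spec$n_frames) - 1) * spec$frame_interval_s
  aif <- simulate_aif(spec$aif_params, tt)
  ct_low <- simulate_tissue_uptake(aif, spec$true_perfusion["low"], tt)
  ct_high <- simulate_tissue_uptake(aif, spec$true_perfusion["high"], tt)

  # proton-density field
  xs <- seq_len(g[1]); ys <- seq_len(g[2])
  xcoord <- array(rep(xs, times = g[2] * g[3]), g)
  ycoord <- array(rep(rep(ys, each = g[1]), times = g[3]), g)
  zcoord <- array(rep(seq_len(g[3]), each = g[1] * g[2]), g)
  m0 <- array(0.3, g)
  tex <- 1 + 0.3 * sin(2 * pi * xcoord / 6) * sin(2 * pi * ycoord / 6)
  cz <- (g[3] + 1) / 2
  for (k in seq_len(K)) {
    vox <- which(geom$label == k)
    # slice-direction gradient: orthogonal to the chamber divide so that
    # chamber-mean proton density stays balanced
    w <- (zcoord[vox] - cz) / geom$semi_axes[3]
    m0[vox] <- (1 + 0.25 * w) * tex[vox]
  }
  m0[geom$label == geom$aif_label] <- 1

  # per-group R1(t) and Ernst shape factors; S = M0 * shape(group, t)
  r10 <- spec$r1_baseline_hz
  r1_bg <- 0.4
  conc <- rbind(background = rep(0, spec$n_frames),
                low = ct_low, high = ct_high, aif = aif)
  r1t <- r10 + spec$relaxivity_hz * conc
  r1t["background", ] <- r1_bg
  shape_of <- function(r1_hz, fa, tr) {
    a <- fa * pi / 180
    e1 <- exp(-tr * r1_hz / 1000)   # tr ms, r1 Hz
    sin(a) * (1 - e1) / (1 - cos(a) * e1)
  }
  sh <- shape_of(r1t, 75, 101.493)

  group <- array(1L, g)  # background
  group[geom$chamber == 1L] <- 2L
  group[geom$chamber == 2L] <- 3L
  group[geom$label == geom$aif_label] <- 4L
  nv <- prod(g)
  S <- matrix(0, nv, spec$n_frames)
  for (gi in 1:4) {
    sel <- which(group == gi)
    if (length(sel)) S[sel, ] <- outer(m0[sel], sh[gi, ])
  }

  # phasic motion: sinusoidal in-plane translation of the high chamber
  n_moving <- round(spec$motion_spec$prevalence * K)
  moving <- sort(sample(K, n_moving))
  fcand <- spec$motion_spec$frequency_mhz
  freqs <- if (length(fcand) > 1) {
    fcand[sample.int(length(fcand), n_moving, replace = TRUE)]
  } else rep(fcand, n_moving)
  phases <- runif(K, 0, 2 * pi)
  amp <- spec$motion_spec$amplitude_voxels
  motion_tab <- data.frame(placenta = seq_len(K),
                           moving = seq_len(K) %in% moving,
                           frequency_mhz = NA_real_,
                           amplitude_voxels = 0)
  if (n_moving > 0) {
    motion_tab$frequency_mhz[moving] <- freqs
    motion_tab$amplitude_voxels[moving] <- amp
    for (tf in seq_len(spec$n_frames)) {
      frame <- array(S[, tf], g)
      for (j in seq_along(moving)) {
        k <- moving[j]
        dx <- amp * sin(2 * pi * (freqs[j] / 1000) * tt[tf] + phases[k])
        vox <- which(geom$chamber == 2L & geom$label == k)
        if (!length(vox)) next
        x <- xcoord[vox] - dx
        x0 <- pmin(pmax(floor(x), 1), g[1] - 1)
        w <- x - x0
        base <- vox - xcoord[vox]   # linear index of x = 0 on each line
        S[vox, tf] <- (1 - w) * frame[base + x0] + w * frame[base + x0 + 1]
      }
    }
  }

  # noise, scaled to the mean pre-injection placental signal
  sig0 <- mean(S[group %in% 2:3, 1])
  sigma <- spec$noise_sigma * sig0
  add_noise <- function(x) {
    if (sigma <= 0) return(x)
    if (spec$noise_model == "rician")
      sqrt((x + rnorm(length(x), 0, sigma))^2 + rnorm(length(x), 0, sigma)^2)
    else x + rnorm(length(x), 0, sigma)
  }
  S <- add_noise(S)

  meta <- acquisition_meta(frame_interval_s = spec$frame_interval_s,
                           injection_frame = spec$injection_frame,
                           tr_ms = 101.493, te_ms = 1.872,
                           flip_angle_deg = 75,
                           voxel_size_mm = spec$voxel_size_mm,
                           n_slices = g[3], n_frames = spec$n_frames)
  dce <- dce_series(array(S, c(g, spec$n_frames)), meta)

  # VFA stacks: pre-contrast baseline R1, post-contrast R1 at end of DCE
  r1_pre <- array(r1_bg, g)
  r1_pre[group %in% 2:4] <- r10
  c_end <- c(0, ct_low[spec$n_frames], ct_high[spec$n_frames],
             aif[spec$n_frames])
  r1_post <- array(r1_bg, g)
  for (gi in 2:4)
    r1_post[group == gi] <- r10 + spec$relaxivity_hz * c_end[gi]
  vfa_angles <- c(75, 55, 30, 20, 10)
  make_vfa <- function(r1vol) {
    arr <- array(0, c(g, length(vfa_angles)))
    for (i in seq_along(vfa_angles)) {
      a <- vfa_angles[i] * pi / 180
      e1 <- exp(-114.88 * r1vol / 1000)
      arr[, , , i] <- add_noise(m0 * sin(a) * (1 - e1) / (1 - cos(a) * e1))
    }
    vfa_stack(arr, vfa_angles, 114.88)
  }
  vfa_pre <- make_vfa(r1_pre)
  vfa_post <- make_vfa(r1_post)

  roles <- data.frame(label = c(0L, seq_len(K), geom$aif_label),
                      role = c("background", rep("placenta", K), "aif"),
                      placenta = c(NA_integer_, seq_len(K), NA_integer_))
  truth <- list(chamber_map = geom$chamber,
                true_f_over_vt = spec$true_perfusion,
                r1_pre = r1_pre, r1_post = r1_post,
                motion = motion_tab, aif_curve = aif, time_s = tt,
                tissue_conc = list(low = ct_low, high = ct_high),
                m0 = m0)
  structure(list(dce = dce, vfa_pre = vfa_pre, vfa_post = vfa_post,
                 label_map = geom$label, roles = roles, truth = truth,
                 spec = spec),
            class = "placenta_phantom")
}

#' @export
print.placenta_phantom <- function(x, ...) {
  cat(sprintf("Digital placenta phantom (%s): %d placentas, %d moving\n",
              x$spec$gestational_age, x$spec$n_placentas,
              sum(x$truth$motion$moving)))
  print(x$dce)
  invisible(x)
}

#' Write all phantom artifacts to a directory
#'
#' DCE as 4-D NIfTI with JSON sidecar, VFA stacks, label map, chamber map
#' and truth tables as CSV.
#'
#' @param phantom A [synthesize_dce()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- phantom$spec$voxel_size_mm
  save_map(phantom$dce, file.path(dir, "dce.nii.gz"), vs)
  save_sidecar(phantom$dce$meta, file.path(dir, "dce.json"))
  save_map(phantom$vfa_pre$images, file.path(dir, "vfa_pre.nii.gz"), vs)
  save_map(phantom$vfa_post$images, file.path(dir, "vfa_post.nii.gz"), vs)
  save_map(phantom$label_map, file.path(dir, "labels.nii.gz"), vs)
  save_map(phantom$truth$chamber_map, file.path(dir, "chambers.nii.gz"), vs)
  write.csv(phantom$roles, file.path(dir, "roles.csv"), row.names = FALSE)
  write.csv(phantom$truth$motion, file.path(dir, "motion_truth.csv"),
            row.names = FALSE)
  write.csv(data.frame(time_s = phantom$truth$time_s,
                       aif = phantom$truth$aif_curve),
            file.path(dir, "aif_truth.csv"), row.names = FALSE)
  invisible(dir)
}
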