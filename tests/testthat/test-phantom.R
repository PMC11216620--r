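test_that("gamma-variate AIF has the programmed bolus shape", {
  tt <- default_time_grid()
  ap <- default_aif_params()

  # zero amplitude -> identically zero
  ap0 <- ap; ap0$peak <- 0
  expect_equal(simulate_aif(ap0, tt), rep(0, length(tt)))

  aif <- simulate_aif(ap, tt)
  expect_true(all(aif[tt <= ap$delay_s] == 0))
  # peak within minutes of injection, before the ~350 s washout point
  expect_lt(tt[which.max(aif)], 350)
  # decaying by the end of the acquisition
  expect_lt(aif[length(aif)], max(aif))
  # single interior maximum: differences change sign exactly once
  s <- sign(diff(aif[aif > 0]))
  expect_equal(sum(diff(s) != 0), 1)

  # matches an independent dense evaluation of the closed form
  fine <- seq(0, max(tt), by = 0.018)
  u <- pmax(fine - ap$delay_s, 0)
  dense <- ifelse(u > 0,
                  ap$peak * (u / (ap$rise_exponent * ap$decay_s))^ap$rise_exponent *
                    exp(ap$rise_exponent - u / ap$decay_s), 0)
  sub <- dense[match(round(tt, 6), round(fine, 6))]
  expect_equal(aif, sub, tolerance = 1e-10)

  expect_error(simulate_aif(ap, c(0, 10, 5)), "increasing")
})

test_that("tissue uptake is the perfusion-scaled running AIF integral", {
  tt <- default_time_grid()
  ap <- default_aif_params()
  aif <- simulate_aif(ap, tt)

  expect_equal(simulate_tissue_uptake(aif, 0, tt), rep(0, length(tt)))
  expect_error(simulate_tissue_uptake(aif, -1, tt), ">= 0")

  # constant arterial concentration -> linear ramp of slope F*c/6000
  cst <- rep(2, length(tt))
  ct <- simulate_tissue_uptake(cst, 50, tt)
  expect_equal(diff(ct) / diff(tt), rep(50 * 2 / 6000, length(tt) - 1),
               tolerance = 1e-12)

  # steepest tissue uptake coincides with the AIF peak
  ct <- simulate_tissue_uptake(aif, 50, tt)
  expect_true(all(diff(ct) >= 0))
  expect_equal(which.max(diff(ct)), which.max(aif[-1] + aif[-length(aif)]))
  # max derivative equals (F/V_T) * max(C_A) within quadrature error
  expect_equal(max(diff(ct) / diff(tt)), (50 / 6000) * max(aif),
               tolerance = 0.05)
})

test_that("phantom spec validates its invariants", {
  expect_error(phantom_spec(chamber_fractions = c(low = 0.5, high = 0.4)),
               "sum to 1")
  expect_error(phantom_spec(true_perfusion = c(low = -1, high = 5)), ">= 0")
  expect_error(phantom_spec(motion_spec = list(prevalence = 1.2)),
               "prevalence")
  expect_error(phantom_spec(frame_interval_s = 0), "> 0")
})

test_that("noiseless motionless voxels are exact Ernst transforms of C_T", {
  spec <- small_spec(noise_sigma = 0, motion_spec = list(prevalence = 0))
  ph <- synthesize_dce(spec)
  tt <- default_time_grid(spec$n_frames, spec$frame_interval_s)
  ct_high <- simulate_tissue_uptake(ph$truth$aif_curve,
                                    spec$true_perfusion["high"], tt)
  vox <- which(ph$truth$chamber_map == 2)[7]
  r1t <- spec$r1_baseline_hz + spec$relaxivity_hz * ct_high
  expected <- ernst_signal(ph$truth$m0[vox], 75, 101.493, 1000 / r1t)
  d <- dim(ph$dce$intensities)
  got <- matrix(ph$dce$intensities, prod(d[1:3]), d[4])[vox, ]
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("phantom synthesis is deterministic under a fixed seed", {
  spec <- small_spec(seed = 99)
  a <- synthesize_dce(spec)
  b <- synthesize_dce(spec)
  expect_identical(a$dce$intensities, b$dce$intensities)
  expect_identical(a$vfa_post$images, b$vfa_post$images)
  expect_identical(a$truth$motion, b$truth$motion)
})

test_that("programmed motion prevalence matches the study's proportions", {
  ph <- synthesize_dce(phantom_spec(grid_shape = c(48, 48, 8),
                                    gestational_age = "E17.5"))
  expect_equal(sum(ph$truth$motion$moving), round(0.821 * 8))
  ph14 <- synthesize_dce(phantom_spec(grid_shape = c(48, 48, 8),
                                      gestational_age = "E14.5"))
  expect_equal(sum(ph14$truth$motion$moving), round(0.111 * 8))
})

test_that("excessive motion amplitude is rejected", {
  spec <- small_spec(motion_spec = list(amplitude_voxels = 50))
  expect_error(synthesize_dce(spec), "amplitude")
})

test_that("phantom truth respects its own invariants", {
  spec <- small_spec()
  ph <- synthesize_dce(spec)
  # chamber map defined exactly on placental voxels
  pl <- ph$label_map %in% ph$roles$label[ph$roles$role == "placenta"]
  expect_true(all((ph$truth$chamber_map > 0) == pl))
  # AIF zero before injection
  expect_true(all(ph$truth$aif_curve[seq_len(spec$injection_frame)] == 0))
  # chamber volume fractions near the programmed split
  for (k in seq_len(spec$n_placentas)) {
    vox <- ph$label_map == k
    frac_low <- mean(ph$truth$chamber_map[vox] == 1)
    expect_equal(frac_low, unname(spec$chamber_fractions["low"]),
                 tolerance = 0.06)
  }
})
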