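test_that("log10 histogram density is normalised and localised", {
  # point mass: single occupied bin centred at log10(10) = 1
  p <- log_pdf_estimate(rep(10, 50))
  occupied <- p$mids[p$density > 0]
  expect_equal(length(occupied), 1)
  expect_equal(occupied, 1, tolerance = 0.06)

  set.seed(31)
  v <- rlnorm(2000, 1, 0.4)
  p <- log_pdf_estimate(v)
  expect_equal(pracma::trapz(p$mids, p$density), 1, tolerance = 1e-6)

  # lognormal sample: log10 density close to the analytic normal
  mu <- 1 / log(10); sg <- 0.4 / log(10)
  keep <- p$density > 0
  expect_lt(max(abs(p$density[keep] - dnorm(p$mids[keep], mu, sg))), 0.5)
  expect_equal(p$n_excluded, 0)
  expect_error(log_pdf_estimate(c(0, -1)), "positive")
  expect_equal(log_pdf_estimate(c(0, rep(10, 20)))$n_excluded, 1)
})

rmix <- function(n, pi2, mu1, s1, mu2, s2) {
  z <- runif(n) < pi2
  ifelse(z, rnorm(n, mu2, s2), rnorm(n, mu1, s1))
}

test_that("EM recovers mixture parameters at the study's reported scale", {
  set.seed(7)
  # component locations as reported for late gestation, widened sigmas
  x <- rmix(5000, 0.49, 1.60, 0.10, 1.72, 0.06)
  fit <- fit_gmm_em(x)
  expect_true(fit$converged)
  expect_equal(fit$mu1, 1.60, tolerance = 0.02)
  expect_equal(fit$mu2, 1.72, tolerance = 0.02)
  expect_equal(fit$pi, 0.49, tolerance = 0.05)
  # responsibilities are probabilities that sum to one across components
  expect_true(all(fit$responsibilities >= 0 & fit$responsibilities <= 1))
  # log-likelihood trace is non-decreasing at every stored EM iteration
  expect_true(all(diff(fit$loglik_trace) >= -1e-8 * abs(fit$log_likelihood)))
})

test_that("EM matches an independent multi-restart reference on toy data", {
  set.seed(33)
  x <- rmix(50, 0.4, 0, 0.5, 3, 0.7)

  ref_em <- function(x, mu1, mu2, s1, s2, pi2, iters = 2000) {
    for (i in seq_len(iters)) {
      d1 <- (1 - pi2) * dnorm(x, mu1, s1); d2 <- pi2 * dnorm(x, mu2, s2)
      g <- d2 / (d1 + d2)
      pi2 <- mean(g)
      mu1 <- sum((1 - g) * x) / sum(1 - g); mu2 <- sum(g * x) / sum(g)
      s1 <- sqrt(sum((1 - g) * (x - mu1)^2) / sum(1 - g))
      s2 <- sqrt(sum(g * (x - mu2)^2) / sum(g))
      s1 <- max(s1, 1e-3); s2 <- max(s2, 1e-3)
    }
    sum(log((1 - pi2) * dnorm(x, mu1, s1) + pi2 * dnorm(x, mu2, s2)))
  }
  ref_ll <- max(vapply(1:20, function(i) {
    set.seed(100 + i)
    st <- sort(sample(x, 2))
    ref_em(x, st[1], st[2], sd(x) / 2, sd(x) / 2, runif(1, 0.2, 0.8))
  }, numeric(1)))
  fit <- fit_gmm_em(x)
  expect_equal(fit$log_likelihood, ref_ll, tolerance = 1e-6)
})

test_that("EM cross-checks against mclust on a well-separated sample", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  set.seed(34)
  x <- rmix(800, 0.55, 1.5, 0.05, 1.75, 0.08)
  fit <- fit_gmm_em(x)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(c(fit$mu1, fit$mu2)), sort(as.numeric(mc$parameters$mean)),
               tolerance = 1e-3)
  expect_equal(fit$log_likelihood, mc$loglik, tolerance = 1e-4)
})

test_that("mixture degeneracy triggers re-spread and enough-data checks", {
  expect_error(fit_gmm_em(rnorm(5)), "at least 10")
  # near-point-mass component: collapse is caught, not fatal
  set.seed(35)
  x <- c(rep(1.5, 30), rnorm(30, 2.5, 0.2))
  w <- capture_warnings(fit <- fit_gmm_em(x))
  expect_true(any(grepl("floor|collapse", w)))
  expect_s3_class(fit, "gmm_fit")
})

test_that("density biomarkers follow their closed forms", {
  fit <- structure(list(pi = 0.4, mu1 = 1.5, sigma1 = 0.1,
                        mu2 = 1.8, sigma2 = 0.05,
                        log_likelihood = 0, loglik_trace = 0, n_iter = 1,
                        converged = TRUE, responsibilities = NULL, n = 100),
                   class = "gmm_fit")
  b <- pdf_biomarkers(fit)
  expect_equal(b$peak[b$component == "low"], 0.6 / (0.1 * sqrt(2 * pi)))
  expect_equal(b$fwhm, 2 * sqrt(2 * log(2)) * c(0.1, 0.05))
  expect_equal(b$fwhm[2] / 0.05, 2.3548, tolerance = 1e-4)
  # trapezoid AUC agrees with the analytic component weights
  expect_equal(b$auc, c(0.6, 0.4), tolerance = 1e-4)
  expect_equal(sum(b$auc), 1, tolerance = 1e-4)

  nc <- fit; nc$converged <- FALSE
  expect_warning(b2 <- pdf_biomarkers(nc), "non-converged")
  expect_true(attr(b2, "non_converged"))
})

test_that("apparent blood volume is extensive and ordered across ages", {
  v <- rep(40, 200)
  a <- apparent_blood_volume(v, 0.002)
  expect_equal(a$abv_ml_min, 0.002 * 200 * 40 / 100)
  expect_equal(a$n_voxels, 200)
  # linear in perfusion and in size
  expect_equal(apparent_blood_volume(v * 2, 0.002)$abv_ml_min,
               2 * a$abv_ml_min)
  expect_equal(apparent_blood_volume(rep(v, 2), 0.002)$abv_ml_min,
               2 * a$abv_ml_min)
  expect_equal(a$literal_integral, 1 / 200, tolerance = 1e-6)
  expect_error(apparent_blood_volume(v, 0), "> 0")

  # phantom truth: each chamber's ABV grows from mid to late gestation
  ph14 <- synthesize_dce(small_spec("E14.5"))
  ph17 <- synthesize_dce(small_spec("E17.5"))
  vox_ml <- prod(ph14$spec$voxel_size_mm) / 1000
  for (chamber in 1:2) {
    abv <- lapply(list(ph14, ph17), function(ph) {
      f <- ph$spec$true_perfusion[chamber]
      n <- sum(ph$truth$chamber_map == chamber)
      apparent_blood_volume(rep(f, n), vox_ml)$abv_ml_min
    })
    expect_gt(abv[[2]], abv[[1]])
  }
})
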