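#' Histogram density of log10 perfusion
#'
#' Perfusion values are log-base-10 transformed (zeros and negatives are
#' excluded, with the count reported) and binned into a density-normalised
#' histogram. The returned grid is padded with a zero-height point half a
#' bin beyond each end so that the trapezoidal integral of the returned
#' density equals 1.
#'
#' @param perfusion_values Perfusion values, mL/min/100 mL.
#' @param n_bins Number of bins; default Freedman-Diaconis.
#' @return An object of class `log_pdf`: `mids`, `density` (including the
#'   flanking zeros), `breaks`, `n`, `n_excluded`.
#' @export
log_pdf_estimate <- function(perfusion_values, n_bins = NULL) {
  keep <- perfusion_values > 0
  n_excluded <- sum(!keep)
  v <- log10(perfusion_values[keep])
  if (length(v) == 0) stopf("no positive perfusion values to bin")
  rng <- range(v)
  if (diff(rng) == 0) rng <- rng + c(-0.05, 0.05)
  n_bins <- n_bins %||% max(1L, grDevices::nclass.FD(v))
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- hist(v, breaks = breaks, plot = FALSE, include.lowest = TRUE)
  w <- diff(breaks)[1]
  structure(list(mids = c(h$mids[1] - w, h$mids, h$mids[n_bins] + w),
                 density = c(0, h$density, 0),
                 breaks = breaks, n = length(v), n_excluded = n_excluded),
            class = "log_pdf")
}

#' Two-component Gaussian mixture fit by expectation-maximisation
#'
#' Fits \eqn{(1-\pi)N(\mu_1,\sigma_1^2) + \pi N(\mu_2,\sigma_2^2)} to
#' log10-perfusion values by EM: the E step computes each point's
#' responsibility for the second component,
#' \eqn{\gamma_i = \pi\phi(x_i;\mu_2,\sigma_2) /
#' [(1-\pi)\phi(x_i;\mu_1,\sigma_1) + \pi\phi(x_i;\mu_2,\sigma_2)]}, and
#' the M step re-estimates means, variances and the weight from the
#' responsibility-weighted moments. Components are ordered so that
#' `mu1 <= mu2` (low/high perfusion distribution).
#'
#' Initialisation is deterministic by default (split at the sample
#' median, moment-match each half); `init = "random"` draws restarts
#' under `seed` and keeps the best likelihood.
#'
#' @param log_values log10 perfusion observations (>= 10 of them).
#' @param seed Seed for random initialisation (unused by the default).
#' @param tol Convergence: relative log-likelihood change (default 1e-8).
#' @param max_iter Iteration cap (default 500).
#' @param init `"split"` (deterministic) or `"random"`.
#' @param n_restarts Restarts when `init = "random"`.
#' @param var_floor Variance floor preventing component collapse.
#' @return An object of class `gmm_fit`: `pi` (weight of the high
#'   component), `mu1`, `sigma1`, `mu2`, `sigma2`, `log_likelihood`,
#'   `loglik_trace`, `n_iter`, `converged`, `responsibilities`.
#' @export
fit_gmm_em <- function(log_values, seed = NULL, tol = 1e-8, max_iter = 500,
                       init = c("split", "random"), n_restarts = 5,
                       var_floor = 1e-6) {
  init <- match.arg(init)
  x <- as.numeric(log_values)
  if (length(x) < 10) stopf("need at least 10 observations")
  if (!is.null(seed)) set.seed(seed)

  run_em <- function(theta) {
    trace <- numeric(0)
    ll_old <- -Inf
    collapses <- 0L
    converged <- FALSE
    g <- NULL
    for (it in seq_len(max_iter)) {
      d1 <- (1 - theta$pi) * dnorm(x, theta$mu1, theta$s1)
      d2 <- theta$pi * dnorm(x, theta$mu2, theta$s2)
      tot <- d1 + d2
      tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
      g <- d2 / tot
      ll <- sum(log(tot))
      trace <- c(trace, ll)
      if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
        converged <- TRUE
        break
      }
      ll_old <- ll
      s2g <- sum(g); s1g <- length(x) - s2g
      mu2 <- sum(g * x) / s2g
      mu1 <- sum((1 - g) * x) / s1g
      v2 <- sum(g * (x - mu2)^2) / s2g
      v1 <- sum((1 - g) * (x - mu1)^2) / s1g
      if (v1 < var_floor || v2 < var_floor) {
        collapses <- collapses + 1L
        if (collapses > 2L) {
          warnf("repeated component collapse; returning non-converged fit")
          converged <- FALSE
          break
        }
        warnf("component variance hit the floor; re-spreading")
        if (v1 < var_floor) v1 <- var(x) / 4
        if (v2 < var_floor) v2 <- var(x) / 4
      }
      theta <- list(pi = s2g / length(x), mu1 = mu1, s1 = sqrt(v1),
                    mu2 = mu2, s2 = sqrt(v2))
      theta$pi <- min(max(theta$pi, 1e-8), 1 - 1e-8)
    }
    list(theta = theta, ll = trace[length(trace)], trace = trace,
         n_iter = length(trace), converged = converged, gamma = g)
  }

  starts <- if (init == "split") {
    md <- median(x)
    lo <- x[x <= md]; hi <- x[x > md]
    if (length(hi) == 0) { lo <- x; hi <- x }
    list(list(pi = length(hi) / length(x),
              mu1 = mean(lo), s1 = max(sd(lo), 10 * sqrt(var_floor)),
              mu2 = mean(hi), s2 = max(sd(hi), 10 * sqrt(var_floor))))
  } else {
    lapply(seq_len(n_restarts), function(i) {
      mus <- sort(sample(x, 2))
      s0 <- max(sd(x) / 2, 10 * sqrt(var_floor))
      list(pi = runif(1, 0.2, 0.8), mu1 = mus[1], s1 = s0,
           mu2 = mus[2], s2 = s0)
    })
  }
  fits <- lapply(starts, run_em)
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "ll"))]]
  th <- best$theta
  gamma <- best$gamma
  if (th$mu1 > th$mu2) {  # enforce low/high ordering
    th <- list(pi = 1 - th$pi, mu1 = th$mu2, s1 = th$s2,
               mu2 = th$mu1, s2 = th$s1)
    gamma <- 1 - gamma
  }
  structure(list(pi = th$pi, mu1 = th$mu1, sigma1 = th$s1,
                 mu2 = th$mu2, sigma2 = th$s2,
                 log_likelihood = best$ll, loglik_trace = best$trace,
                 n_iter = best$n_iter, converged = best$converged,
                 responsibilities = gamma, n = length(x)),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("2-component Gaussian mixture (n = %d, %s in %d EM iterations)\n",
              x$n, if (x$converged) "converged" else "NOT converged", x$n_iter))
  cat(sprintf("  low : mu %.4g sigma %.4g weight %.3f\n",
              x$mu1, x$sigma1, 1 - x$pi))
  cat(sprintf("  high: mu %.4g sigma %.4g weight %.3f\n",
              x$mu2, x$sigma2, x$pi))
  cat(sprintf("  log-likelihood %.6g\n", x$log_likelihood))
  invisible(x)
}

#' @export
coef.gmm_fit <- function(object, ...) {
  c(pi = object$pi, mu1 = object$mu1, sigma1 = object$sigma1,
    mu2 = object$mu2, sigma2 = object$sigma2)
}

#' @export
logLik.gmm_fit <- function(object, ...) {
  structure(object$log_likelihood, df = 5, nobs = object$n,
            class = "logLik")
}

#' @export
summary.gmm_fit <- function(object, ...) {
  out <- list(coef = coef(object), biomarkers = pdf_biomarkers(object),
              converged = object$converged, n_iter = object$n_iter)
  class(out) <- "summary.gmm_fit"
  out
}

#' @export
print.summary.gmm_fit <- function(x, ...) {
  print(x$coef)
  cat("\nDensity-shape biomarkers:\n")
  print(x$biomarkers)
  invisible(x)
}

#' @param x A `gmm_fit`.
#' @param data Optional log10 values to histogram under the fitted density.
#' @param ... Passed to [graphics::hist()].
#' @rdname fit_gmm_em
#' @export
plot.gmm_fit <- function(x, data = NULL, ...) {
  grid <- seq(min(x$mu1 - 4 * x$sigma1, x$mu2 - 4 * x$sigma2),
              max(x$mu1 + 4 * x$sigma1, x$mu2 + 4 * x$sigma2),
              length.out = 512)
  f1 <- (1 - x$pi) * dnorm(grid, x$mu1, x$sigma1)
  f2 <- x$pi * dnorm(grid, x$mu2, x$sigma2)
  if (!is.null(data)) {
    hist(data, breaks = "FD", freq = FALSE, col = "grey90",
         xlab = "log10 perfusion", main = "Perfusion mixture", ...)
  } else {
    graphics::plot(grid, f1 + f2, type = "n", xlab = "log10 perfusion",
                   ylab = "density", main = "Perfusion mixture")
  }
  lines(grid, f1, col = "purple", lwd = 2)
  lines(grid, f2, col = "steelblue", lwd = 2)
  lines(grid, f1 + f2, col = "black", lty = 2)
  legend("topleft", c("low", "high", "mixture"), lwd = c(2, 2, 1),
         lty = c(1, 1, 2), col = c("purple", "steelblue", "black"),
         bty = "n")
  invisible(x)
}

#' Density-shape biomarkers of the fitted perfusion mixture
#'
#' For each weighted component \eqn{w\,N(\mu,\sigma^2)}: the peak density
#' height \eqn{w/(\sigma\sqrt{2\pi})}, the full width at half maximum
#' \eqn{2\sqrt{2\ln 2}\,\sigma}, and the area under the weighted density
#' (trapezoid over a grid spanning both components' mu +/- 6 sigma).
#' Components are labelled low/high by mean.
#'
#' @param params A [fit_gmm_em()] result.
#' @return Data frame with one row per component; carries a
#'   `non_converged` attribute (with a warning) if the fit did not
#'   converge.
#' @export
pdf_biomarkers <- function(params) {
  stopifnot(inherits(params, "gmm_fit"))
  if (!params$converged)
    warnf("biomarkers computed from a non-converged mixture fit")
  grid <- seq(min(params$mu1 - 6 * params$sigma1,
                  params$mu2 - 6 * params$sigma2),
              max(params$mu1 + 6 * params$sigma1,
                  params$mu2 + 6 * params$sigma2),
              length.out = 4096)
  w <- c(low = 1 - params$pi, high = params$pi)
  mu <- c(low = params$mu1, high = params$mu2)
  sg <- c(low = params$sigma1, high = params$sigma2)
  auc <- vapply(c("low", "high"), function(k)
    pracma::trapz(grid, w[k] * dnorm(grid, mu[k], sg[k])), numeric(1))
  out <- data.frame(component = c("low", "high"),
                    weight = as.numeric(w), mu = as.numeric(mu),
                    sigma = as.numeric(sg),
                    peak = as.numeric(w / (sg * sqrt(2 * pi))),
                    fwhm = as.numeric(2 * sqrt(2 * log(2)) * sg),
                    auc = as.numeric(auc))
  attr(out, "non_converged") <- !params$converged
  out
}

#' Apparent blood volume of a chamber
#'
#' Extensive perfusion summary: voxel volume times the sum of voxel
#' perfusion over the chamber, divided by 100,
#' `ABV = v * sum(F) / 100` in mL/min -- monotone in both chamber size
#' and perfusion. The literal normalised histogram integral
#' (`(1/N) * trapz(pdf)`, which evaluates to `1/N`) is emitted alongside
#' for comparison.
#'
#' @param perfusion_values Voxel perfusion in the chamber, mL/min/100 mL.
#' @param voxel_volume_ml Voxel volume, mL (> 0).
#' @return An object of class `abv`: `abv_ml_min`, `literal_integral`,
#'   `n_voxels`.
#' @export
apparent_blood_volume <- function(perfusion_values, voxel_volume_ml) {
  if (length(perfusion_values) == 0) stopf("empty perfusion value set")
  if (!is.finite(voxel_volume_ml) || voxel_volume_ml <= 0)
    stopf("voxel_volume_ml must be > 0")
  n <- length(perfusion_values)
  lit <- if (any(perfusion_values > 0)) {
    pdf <- log_pdf_estimate(perfusion_values)
    pracma::trapz(pdf$mids, pdf$density) / n
  } else NA_real_
  structure(list(abv_ml_min = voxel_volume_ml * sum(perfusion_values) / 100,
                 literal_integral = lit, n_voxels = n),
            class = "abv")
}

#' @export
print.abv <- function(x, ...) {
  cat(sprintf("Apparent blood volume: %.4g mL/min over %d voxels (literal 1/N integral %.3g)\n",
              x$abv_ml_min, x$n_voxels, x$literal_integral))
  invisible(x)
}
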