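#' Steady-state spoiled gradient-echo (Ernst) signal
#'
#' \deqn{S = M_0 \sin\alpha \frac{1 - E_1}{1 - \cos\alpha\, E_1},\qquad
#'       E_1 = e^{-TR/T_1}}
#'
#' @param m0 Equilibrium magnetisation (arbitrary units); vectorised.
#' @param flip_angle_deg Flip angle, degrees.
#' @param tr_ms Repetition time, milliseconds (> 0).
#' @param t1_ms Longitudinal relaxation time, milliseconds (> 0); vectorised.
#' @return Signal in the units of `m0`.
#' @export
ernst_signal <- function(m0, flip_angle_deg, tr_ms, t1_ms) {
  if (any(!is.finite(tr_ms)) || any(tr_ms <= 0)) stopf("tr_ms must be > 0")
  if (any(!is.finite(t1_ms)) || any(t1_ms <= 0)) stopf("t1_ms must be > 0")
  a <- flip_angle_deg * pi / 180
  e1 <- exp(-tr_ms / t1_ms)
  m0 * sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

#' A variable-flip-angle image stack
#'
#' @param images 4-D array `(x, y, slice, angle)` or list of 3-D volumes,
#'   one per flip angle, on a common grid.
#' @param flip_angles_deg Flip angles, degrees (default the acquisition's
#'   75, 55, 30, 20, 10).
#' @param tr_ms Repetition time, milliseconds (default 114.88).
#' @return An object of class `vfa_stack`.
#' @export
vfa_stack <- function(images, flip_angles_deg = c(75, 55, 30, 20, 10),
                      tr_ms = 114.88) {
  if (is.list(images)) {
    d <- dim(images[[1]])
    if (!all(vapply(images, function(v) identical(dim(v), d), logical(1))))
      stopf("all volumes must share a grid")
    images <- array(unlist(images), dim = c(d, length(images)))
  }
  d <- dim(images)
  if (length(d) != 4) stopf("images must form a 4-D (x, y, slice, angle) array")
  if (d[4] != length(flip_angles_deg))
    stopf("number of volumes (%d) != number of flip angles (%d)",
          d[4], length(flip_angles_deg))
  if (length(unique(flip_angles_deg)) < 2)
    stopf("need at least 2 distinct flip angles")
  structure(list(images = images, flip_angles_deg = as.numeric(flip_angles_deg),
                 tr_ms = tr_ms),
            class = "vfa_stack")
}

#' Voxelwise T1 / R1 estimation from variable flip angles
#'
#' Per voxel, `(M0, E1)` are estimated by nonlinear least squares of the
#' Ernst signal over the acquired flip angles (Gauss-Newton, initialised
#' from the linearised regression of `S/sin(a)` on `S/tan(a)` whose slope
#' is `E1`). Then `T1 = -TR / log(E1)` and `R1 = 1/T1` in Hz. Voxels whose
#' estimated `E1` falls outside (0, 1), or with all-zero signal, are
#' flagged invalid (`NA` in the maps), never silently zeroed.
#'
#' @param stack A [vfa_stack()].
#' @param mask Optional logical volume restricting the fit.
#' @param max_iter Gauss-Newton iteration cap (default 50).
#' @return An object of class `r1_map` with elements `r1` (Hz), `t1_ms`,
#'   `m0`, `fit_quality` (per-voxel residual RMS), `valid_mask`.
#' @export
fit_t1_vfa <- function(stack, mask = NULL, max_iter = 50) {
  stopifnot(inherits(stack, "vfa_stack"))
  d <- dim(stack$images)
  nv <- prod(d[1:3])
  S <- matrix(stack$images, nrow = nv, ncol = d[4])
  if (any(S < 0)) stopf("signals must be non-negative")
  sel <- if (is.null(mask)) rep(TRUE, nv) else as.logical(mask)
  a <- stack$flip_angles_deg * pi / 180
  sa <- sin(a); ca <- cos(a); ta <- tan(a)
  tr <- stack$tr_ms

  nonzero <- rowSums(S) > 0
  idx <- which(sel & nonzero)
  eps <- 1e-6
  e1 <- m0 <- rep(NA_real_, nv)
  if (length(idx)) {
    Ss <- S[idx, , drop = FALSE]
    # linearised initialiser: y = S/sin(a), x = S/tan(a), slope = E1
    Y <- sweep(Ss, 2, sa, "/")
    X <- sweep(Ss, 2, ta, "/")
    mx <- rowMeans(X); my <- rowMeans(Y)
    sxx <- rowSums((X - mx)^2)
    sxy <- rowSums((X - mx) * (Y - my))
    e1i <- pmin(pmax(ifelse(sxx > 0, sxy / sxx, NA_real_), eps), 1 - eps)
    m0i <- pmax((my - e1i * mx) / (1 - e1i), eps)

    for (iter in seq_len(max_iter)) {
      den <- 1 - outer(e1i, ca)          # 1 - cos(a) E1, per voxel x angle
      shape <- sweep((1 - e1i) / den, 2, sa, "*")   # sin(a)(1-E1)/(1-ca E1)
      mod <- m0i * shape
      r <- Ss - mod
      J1 <- shape                        # d/dM0
      J2 <- m0i * sweep(1 / den^2, 2, sa * (ca - 1), "*")  # d/dE1
      a11 <- rowSums(J1 * J1); a12 <- rowSums(J1 * J2)
      a22 <- rowSums(J2 * J2)
      b1 <- rowSums(J1 * r); b2 <- rowSums(J2 * r)
      det <- a11 * a22 - a12^2
      ok <- is.finite(det) & det > 1e-300
      dm0 <- ifelse(ok, (a22 * b1 - a12 * b2) / det, 0)
      de1 <- ifelse(ok, (a11 * b2 - a12 * b1) / det, 0)
      m0i <- pmax(m0i + dm0, eps)
      e1i <- pmin(pmax(e1i + de1, eps), 1 - eps)
      if (max(abs(de1), na.rm = TRUE) < 1e-12) break
    }
    e1[idx] <- e1i
    m0[idx] <- m0i
  }

  # voxels pinned at the parameter bounds did not identify E1 in (0, 1)
  at_bound <- !is.na(e1) & (e1 <= eps | e1 >= 1 - eps)
  valid <- !is.na(e1) & !at_bound
  t1 <- ifelse(valid, -tr / log(e1), NA_real_)
  r1 <- 1000 / t1  # ms -> Hz
  den <- 1 - outer(ifelse(valid, e1, 0.5), ca)
  fitted <- m0 * sweep((1 - ifelse(valid, e1, 0.5)) / den, 2, sa, "*")
  rss <- sqrt(rowMeans((S - fitted)^2))
  rss[!valid] <- NA_real_
  shape3 <- function(v) array(v, dim = d[1:3])
  structure(list(r1 = shape3(r1), t1_ms = shape3(t1), m0 = shape3(m0),
                 fit_quality = shape3(rss), valid_mask = shape3(valid),
                 flip_angles_deg = stack$flip_angles_deg, tr_ms = tr),
            class = "r1_map")
}

#' @export
print.r1_map <- function(x, ...) {
  n <- sum(x$valid_mask)
  cat(sprintf("R1 map: %s grid, %d valid voxels\n",
              paste(dim(x$r1), collapse = "x"), n))
  if (n) cat(sprintf("  R1 median %.4g Hz (T1 %.4g ms)\n",
                     median(x$r1[x$valid_mask]), median(x$t1_ms[x$valid_mask])))
  invisible(x)
}

#' @export
summary.r1_map <- function(object, ...) {
  v <- object$r1[object$valid_mask]
  out <- list(n_valid = sum(object$valid_mask),
              n_invalid = sum(!object$valid_mask),
              r1_quartiles = quantile(v, c(.25, .5, .75)),
              residual_rms = median(object$fit_quality[object$valid_mask]))
  class(out) <- "summary.r1_map"
  out
}

#' @export
print.summary.r1_map <- function(x, ...) {
  cat(sprintf("valid voxels: %d (invalid %d)\n", x$n_valid, x$n_invalid))
  cat("R1 quartiles (Hz):\n"); print(x$r1_quartiles)
  cat(sprintf("median residual RMS: %.4g\n", x$residual_rms))
  invisible(x)
}

#' Change in longitudinal relaxation rate pre- to post-contrast
#'
#' `delta = R1_post - R1_pre` on the joint valid mask. Negative values are
#' retained and counted (a noise indicator), never clamped.
#'
#' @param pre,post [fit_t1_vfa()] results (or bare R1 arrays) on one grid.
#' @return An object of class `delta_r1_map`: `delta` (Hz, `NA` where
#'   either fit is invalid), `valid_mask`, `n_negative`.
#' @export
delta_r1 <- function(pre, post) {
  get_r1 <- function(x) if (inherits(x, "r1_map")) x$r1 else x
  get_mask <- function(x) {
    if (inherits(x, "r1_map")) x$valid_mask else !is.na(x)
  }
  r1a <- get_r1(pre); r1b <- get_r1(post)
  if (!identical(dim(r1a), dim(r1b)))
    stopf("pre and post R1 maps are on different grids (%s vs %s)",
          paste(dim(r1a), collapse = "x"), paste(dim(r1b), collapse = "x"))
  mask <- get_mask(pre) & get_mask(post)
  delta <- array(NA_real_, dim(r1a))
  delta[mask] <- r1b[mask] - r1a[mask]
  structure(list(delta = delta, valid_mask = mask,
                 n_negative = sum(delta[mask] < 0)),
            class = "delta_r1_map")
}

#' @export
print.delta_r1_map <- function(x, ...) {
  cat(sprintf("deltaR1 map: %s grid, %d valid voxels (%d negative)\n",
              paste(dim(x$delta), collapse = "x"), sum(x$valid_mask),
              x$n_negative))
  invisible(x)
}

#' Apparent gadolinium uptake over a chamber
#'
#' An extensive uptake summary: the chamber-mean change in R1 times the
#' chamber voxel count, `AGU = mean(deltaR1) * n_voxels`, units Hz·voxels.
#' The chamber-mean `deltaR1` itself (the volume-normalised variant) is
#' returned as an attribute.
#'
#' @param delta_r1 A [delta_r1()] result or a bare deltaR1 array.
#' @param chamber_mask Logical (or 0/1) volume selecting the chamber.
#' @return AGU scalar with attribute `mean_delta_r1`.
#' @export
apparent_gd_uptake <- function(delta_r1, chamber_mask) {
  d <- if (inherits(delta_r1, "delta_r1_map")) delta_r1$delta else delta_r1
  m <- as.logical(chamber_mask)
  if (!identical(dim(d), dim(chamber_mask) %||% dim(d)))
    stopf("mask grid does not match the deltaR1 grid")
  vals <- d[m & !is.na(d)]
  if (length(vals) == 0) stopf("chamber mask is empty (or entirely invalid)")
  agu <- mean(vals) * length(vals)
  attr(agu, "mean_delta_r1") <- mean(vals)
  agu
}
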