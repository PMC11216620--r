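# shift a matrix by (di, dj) with replicate padding
shift2 <- function(m, di, dj) {
  n <- nrow(m); p <- ncol(m)
  ri <- pmin(pmax(seq_len(n) + di, 1), n)
  rj <- pmin(pmax(seq_len(p) + dj, 1), p)
  m[ri, rj, drop = FALSE]
}

# Horn-Schunck neighbourhood average (weights 1/6 edge, 1/12 corner)
hs_average <- function(m) {
  (shift2(m, -1, 0) + shift2(m, 1, 0) + shift2(m, 0, -1) + shift2(m, 0, 1)) / 6 +
    (shift2(m, -1, -1) + shift2(m, -1, 1) + shift2(m, 1, -1) + shift2(m, 1, 1)) / 12
}

#' Horn-Schunck optical flow between two frames
#'
#' Estimates a dense, globally smooth in-plane velocity field by the
#' Horn-Schunck variational method. Spatial and temporal intensity
#' gradients use the original 2x2x2 finite-difference stencil; each
#' iteration updates the flow from its neighbourhood average
#' \eqn{(\bar u, \bar v)}:
#' \deqn{u = \bar u - I_x \frac{I_x\bar u + I_y\bar v + I_t}
#'   {\alpha + I_x^2 + I_y^2}} (and likewise for `v`), where `alpha` is
#' the squared smoothness weight (default 100, i.e. the regularisation
#' parameter 10^2).
#'
#' @param frame_a,frame_b Same-shape numeric matrices (consecutive frames
#'   of one slice).
#' @param alpha Smoothness weight (> 0, default 100).
#' @param n_iter Maximum iterations (default 100).
#' @param tol Stop when the mean absolute flow update falls below this
#'   (default 1e-4).
#' @return An object of class `velocity_field`: `u`, `v` (voxels/frame),
#'   `magnitude`, `n_iter_used`.
#' @export
horn_schunck <- function(frame_a, frame_b, alpha = 100, n_iter = 100,
                         tol = 1e-4) {
  if (!identical(dim(frame_a), dim(frame_b)))
    stopf("frames have different shapes")
  if (!is.finite(alpha) || alpha <= 0) stopf("alpha must be > 0")
  A <- frame_a; B <- frame_b
  # 2x2x2 stencil gradients (forward differences averaged over the cube);
  # shift2(m, 1, 0)[i, j] = m[i + 1, j]
  dxf <- function(m) shift2(m, 1, 0) - m
  dyf <- function(m) shift2(m, 0, 1) - m
  Ix <- (dxf(A) + dxf(shift2(A, 0, 1)) + dxf(B) + dxf(shift2(B, 0, 1))) / 4
  Iy <- (dyf(A) + dyf(shift2(A, 1, 0)) + dyf(B) + dyf(shift2(B, 1, 0))) / 4
  D <- B - A
  It <- (D + shift2(D, 1, 0) + shift2(D, 0, 1) + shift2(D, 1, 1)) / 4
  u <- v <- matrix(0, nrow(A), ncol(A))
  denom <- alpha + Ix^2 + Iy^2
  used <- 0L
  for (it in seq_len(n_iter)) {
    ub <- hs_average(u); vb <- hs_average(v)
    common <- (Ix * ub + Iy * vb + It) / denom
    un <- ub - Ix * common
    vn <- vb - Iy * common
    delta <- mean(abs(un - u) + abs(vn - v))
    u <- un; v <- vn
    used <- it
    if (delta < tol) break
  }
  structure(list(u = u, v = v, magnitude = sqrt(u^2 + v^2),
                 n_iter_used = used, alpha = alpha),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("Velocity field %dx%d: mean speed %.4g voxels/frame (%d iterations)\n",
              nrow(x$u), ncol(x$u), mean(x$magnitude), x$n_iter_used))
  invisible(x)
}

#' Optical flow for every slice and frame pair of a series
#'
#' @param series A [dce_series()] or 4-D array (ideally temporally
#'   denoised first).
#' @inheritParams horn_schunck
#' @return An object of class `flow_fields`: 4-D arrays `u`, `v`,
#'   `magnitude` of shape `(x, y, slice, n_frames - 1)`.
#' @export
flow_series <- function(series, alpha = 100, n_iter = 100, tol = 1e-4) {
  arr <- as_series_array(series)
  d <- dim(arr)
  if (d[4] < 2) stopf("need at least 2 frames")
  U <- V <- array(0, c(d[1:3], d[4] - 1))
  for (z in seq_len(d[3])) {
    for (t in seq_len(d[4] - 1)) {
      fl <- horn_schunck(arr[, , z, t], arr[, , z, t + 1],
                         alpha = alpha, n_iter = n_iter, tol = tol)
      U[, , z, t] <- fl$u
      V[, , z, t] <- fl$v
    }
  }
  structure(list(u = U, v = V, magnitude = sqrt(U^2 + V^2),
                 frame_interval_s = if (inherits(series, "dce_series"))
                   series$meta$frame_interval_s else NA_real_),
            class = "flow_fields")
}

#' Chamber-wise mean-speed motion traces
#'
#' Per frame pair, the mean velocity magnitude over the whole placenta
#' and over each perfusion chamber.
#'
#' @param fields A [flow_series()] result.
#' @param label_map Placental label volume.
#' @param chambers Optional [assign_chambers()] result; without it only
#'   whole-placenta traces are produced.
#' @param frame_interval_s Frame interval used for the time axis.
#' @return Data frame `(placenta, region, frame_pair, time_s,
#'   mean_speed)` in voxels/frame.
#' @export
velocity_traces <- function(fields, label_map, chambers = NULL,
                            frame_interval_s = NULL) {
  stopifnot(inherits(fields, "flow_fields"))
  dt <- frame_interval_s %||% fields$frame_interval_s
  d <- dim(fields$magnitude)
  nv <- prod(d[1:3])
  M <- matrix(fields$magnitude, nrow = nv, ncol = d[4])
  labs <- setdiff(sort(unique(as.integer(label_map))), 0L)
  if (!is.null(chambers)) labs <- chambers$placenta_labels
  rows <- list()
  for (k in labs) {
    vox_all <- which(label_map == k)
    regions <- list(whole = vox_all)
    if (!is.null(chambers)) {
      asg <- chambers$assignments[[as.character(k)]]
      regions$low <- asg$voxels[asg$is_low]
      regions$high <- asg$voxels[!asg$is_low]
    }
    for (rg in names(regions)) {
      vox <- regions[[rg]]
      if (length(vox) == 0) {
        warnf("placenta %s: region '%s' is empty; omitted", k, rg)
        next
      }
      ms <- colMeans(M[vox, , drop = FALSE])
      rows[[length(rows) + 1]] <-
        data.frame(placenta = k, region = rg,
                   frame_pair = seq_len(d[4]),
                   time_s = (seq_len(d[4]) - 0.5) * (dt %||% 1),
                   mean_speed = ms)
    }
  }
  do.call(rbind, rows)
}
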