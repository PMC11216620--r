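#' Physiological percentile thresholding into perfusion chambers
#'
#' Splits one placenta's perfusion values at the 55th percentile at E14.5
#' or the 45th percentile at E17.5 (linear-interpolation quantile), the
#' stereology-based labyrinth/decidua volume proportions at those ages.
#' Voxels strictly below the threshold form the low-perfusion chamber;
#' ties and values above go to the high-perfusion chamber. A constant
#' placenta therefore comes out all-high, with a warning.
#'
#' @param perfusion_values Per-voxel perfusion within one placenta,
#'   mL/min/100 mL.
#' @param age `"E14.5"` or `"E17.5"`.
#' @param placenta_id Optional identifier carried through.
#' @return An object of class `chamber_assignment`: `threshold_value`,
#'   logical `is_low` per input value, `low_fraction`, `high_fraction`.
#' @export
physiological_threshold <- function(perfusion_values, age,
                                    placenta_id = NA_integer_) {
  if (length(perfusion_values) == 0) stopf("empty perfusion value set")
  if (!age %in% c("E14.5", "E17.5"))
    stopf("unknown gestational age label '%s' (expected E14.5 or E17.5)", age)
  p <- if (age == "E14.5") 0.55 else 0.45
  thr <- unname(quantile(perfusion_values, p, type = 7))
  is_low <- perfusion_values < thr
  if (!any(is_low))
    warnf("placenta %s: no voxel below the %g%% percentile threshold (constant values?); all assigned high",
          placenta_id, 100 * p)
  structure(list(placenta_id = placenta_id, age = age,
                 percentile = p, threshold_value = thr,
                 is_low = is_low,
                 low_fraction = mean(is_low),
                 high_fraction = mean(!is_low)),
            class = "chamber_assignment")
}

#' @export
print.chamber_assignment <- function(x, ...) {
  cat(sprintf("Chamber assignment (placenta %s, %s): threshold %.4g (%g%% pct)\n",
              x$placenta_id, x$age, x$threshold_value, 100 * x$percentile))
  cat(sprintf("  low %d voxels (%.1f%%), high %d voxels (%.1f%%)\n",
              sum(x$is_low), 100 * x$low_fraction,
              sum(!x$is_low), 100 * x$high_fraction))
  invisible(x)
}

#' Chamber assignments for every placenta in a label map
#'
#' Applies [physiological_threshold()] per placenta (or, with
#' `pool = "litter"`, with a single threshold computed from the pooled
#' voxels of all placentas) and assembles a chamber label volume.
#'
#' @param pmap A [perfusion_map()] or bare perfusion volume.
#' @param label_map Integer volume; positive placental labels.
#' @param age Gestational age label.
#' @param roles Optional role table; labels with role `"placenta"` are
#'   used (otherwise every label except 0 and `aif_label`).
#' @param pool `"placenta"` (default) or `"litter"`.
#' @return A list of class `chamber_set`: `assignments` (per placenta),
#'   `chamber_map` (0 outside, 1 low, 2 high), `placenta_labels`.
#' @export
assign_chambers <- function(pmap, label_map, age, roles = NULL,
                            pool = c("placenta", "litter")) {
  pool <- match.arg(pool)
  f <- if (inherits(pmap, "perfusion_map")) pmap$f_over_vt else pmap
  if (!identical(dim(f), dim(label_map)))
    stopf("perfusion and label grids differ")
  labs <- if (!is.null(roles)) {
    sort(roles$label[roles$role == "placenta"])
  } else {
    u <- sort(unique(as.integer(label_map)))
    setdiff(u, 0L)
  }
  if (length(labs) == 0) stopf("no placental labels found")
  chamber_map <- array(0L, dim(label_map))
  pooled_thr <- if (pool == "litter") {
    vox <- which(label_map %in% labs)
    p <- if (age == "E14.5") 0.55 else 0.45
    unname(quantile(f[vox], p, type = 7))
  } else NULL
  assignments <- lapply(labs, function(k) {
    vox <- which(label_map == k)
    vals <- f[vox]
    asg <- physiological_threshold(vals, age, placenta_id = k)
    if (!is.null(pooled_thr)) {
      asg$threshold_value <- pooled_thr
      asg$is_low <- vals < pooled_thr
      asg$low_fraction <- mean(asg$is_low)
      asg$high_fraction <- 1 - asg$low_fraction
    }
    asg$voxels <- vox
    chamber_map[vox] <<- ifelse(asg$is_low, 1L, 2L)
    asg
  })
  names(assignments) <- as.character(labs)
  structure(list(assignments = assignments, chamber_map = chamber_map,
                 placenta_labels = labs, age = age, pool = pool),
            class = "chamber_set")
}

#' Per-placenta chamber summaries
#'
#' One row per placenta and chamber (`low`, `high`, `whole`): mean
#' perfusion, voxel count, volume in mL, and the high/low chamber volume
#' ratio.
#'
#' @param pmap A [perfusion_map()] or perfusion volume.
#' @param chambers An [assign_chambers()] result.
#' @param label_map The placental label volume.
#' @param voxel_size_mm Voxel edge lengths, mm.
#' @return A data frame.
#' @export
chamber_summaries <- function(pmap, chambers, label_map,
                              voxel_size_mm = c(0.156, 0.156, 0.85)) {
  f <- if (inherits(pmap, "perfusion_map")) pmap$f_over_vt else pmap
  labs_present <- setdiff(sort(unique(as.integer(label_map))), 0L)
  labs_present <- intersect(labs_present, chambers$placenta_labels)
  missing <- setdiff(chambers$placenta_labels, labs_present)
  vv_ml <- prod(voxel_size_mm) / 1000  # mm^3 -> mL
  rows <- lapply(chambers$placenta_labels, function(k) {
    asg <- chambers$assignments[[as.character(k)]]
    if (is.null(asg)) stopf("no chamber assignment for label %s", k)
    vox <- asg$voxels
    vals <- f[vox]
    idx <- list(low = asg$is_low, high = !asg$is_low,
                whole = rep(TRUE, length(vals)))
    n_low <- sum(asg$is_low); n_high <- sum(!asg$is_low)
    ratio <- if (n_low > 0) n_high / n_low else NA_real_
    do.call(rbind, lapply(names(idx), function(ch) {
      v <- vals[idx[[ch]]]
      data.frame(placenta = k, chamber = ch,
                 mean_perfusion = if (length(v)) mean(v) else NA_real_,
                 n_voxels = length(v), volume_ml = length(v) * vv_ml,
                 hpc_lpc_volume_ratio = ratio,
                 threshold_value = asg$threshold_value)
    }))
  })
  do.call(rbind, rows)
}
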