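#' Configuration of a full analysis run
#'
#' Each session is either a [phantom_spec()] (data are synthesised) or a
#' list with `series` ([dce_series()] or a NIfTI path plus `sidecar`),
#' `label_map` (volume or path), `age`, optional `roles`, `vfa_pre`,
#' `vfa_post`.
#'
#' @param sessions List of sessions as above.
#' @param time_window,closing_length Temporal denoising parameters.
#' @param band_hz Spectral sub-band for motion mapping (default 8-12 mHz).
#' @param phasic_threshold Relative-power cutoff for the phasic flag.
#' @param pool Chamber threshold pooling, `"placenta"` or `"litter"`.
#' @param flow_alpha Horn-Schunck smoothness weight.
#' @param run_motion,run_relaxometry Stage switches.
#' @param seed Root seed for all stochastic steps.
#' @return An object of class `study_config`.
#' @export
study_config <- function(sessions, time_window = 3, closing_length = 3,
                         band_hz = c(0.008, 0.012), phasic_threshold = 0.2,
                         pool = "placenta", flow_alpha = 100,
                         run_motion = TRUE, run_relaxometry = TRUE,
                         seed = 1L) {
  if (!length(sessions)) stopf("at least one session is required")
  for (s in sessions) {
    age <- if (inherits(s, "phantom_spec")) s$gestational_age else s$age
    if (is.null(age) || !age %in% c("E14.5", "E17.5"))
      stopf("every session needs age E14.5 or E17.5")
    if (!inherits(s, "phantom_spec")) {
      for (f in c("series", "label_map"))
        if (is.character(s[[f]]) && !file.exists(s[[f]]))
          stopf("session file does not exist: %s", s[[f]])
    }
  }
  structure(list(sessions = sessions, time_window = time_window,
                 closing_length = closing_length, band_hz = band_hz,
                 phasic_threshold = phasic_threshold, pool = pool,
                 flow_alpha = flow_alpha, run_motion = run_motion,
                 run_relaxometry = run_relaxometry, seed = as.integer(seed)),
            class = "study_config")
}

resolve_session <- function(s, session_id) {
  if (inherits(s, "phantom_spec")) {
    ph <- synthesize_dce(s)
    list(id = session_id, age = s$gestational_age, series = ph$dce,
         label_map = ph$label_map, roles = ph$roles,
         vfa_pre = ph$vfa_pre, vfa_post = ph$vfa_post, phantom = ph)
  } else {
    series <- s$series
    if (is.character(series)) series <- load_dce_series(series, s$sidecar)
    label_map <- s$label_map
    if (is.character(label_map)) label_map <- load_map(label_map)
    list(id = session_id, age = s$age, series = series,
         label_map = label_map, roles = s$roles,
         vfa_pre = s$vfa_pre, vfa_post = s$vfa_post, phantom = NULL)
  }
}

# analysis of one imaging session; internal to run_pipeline but exported
# for interactive use

#' Analyse a single DCE session
#'
#' Runs preprocessing (temporal median + closing, 3x3x3 spatial median),
#' AIF extraction, steepest-slope perfusion mapping, chamber thresholding
#' and summaries, log-perfusion mixture modelling with biomarkers, ABV,
#' optional VFA relaxometry with AGU, and optional optical-flow motion
#' and spectral analysis.
#'
#' @param session List with `series` ([dce_series()]), `label_map`,
#'   `age`, and optionally `roles`, `vfa_pre`, `vfa_post`, `id`.
#' @param config A [study_config()] (sessions field unused here).
#' @return A list with the per-stage results and the per-placenta table.
#' @export
analyze_session <- function(session, config = study_config(list(session))) {
  series <- session$series
  label_map <- session$label_map
  check_grid(series, label_map)
  age <- session$age
  roles <- session$roles
  vs <- series$meta$voxel_size_mm
  vox_ml <- prod(vs) / 1000

  tden <- temporal_denoise(series, config$time_window, config$closing_length)
  den <- spatial_median3(tden)
  # AIF from the temporally denoised series only: ROI averaging already
  # smooths spatially, and a 3x3x3 median bleeds background into the
  # small hilum ROI, biasing peak enhancement downward
  aif <- extract_aif(tden, label_map, roles = roles)
  uptake <- seq(series$meta$injection_frame + 1, aif$peak_index)
  mip <- mean_removed_mip(den, uptake)
  ss <- steepest_slope_map(den)
  pmap <- perfusion_map(ss, aif)
  chambers <- assign_chambers(pmap, label_map, age, roles = roles,
                              pool = config$pool)
  summaries <- chamber_summaries(pmap, chambers, label_map, vs)

  # perfusion-distribution biomarkers on the pooled placental voxels
  pl_vox <- unlist(lapply(chambers$assignments, `[[`, "voxels"))
  pooled <- pmap$f_over_vt[pl_vox]
  pos <- pooled[pooled > 0]
  gmm <- fit_gmm_em(log10(pos))
  biomarkers <- pdf_biomarkers(gmm)

  abv_rows <- do.call(rbind, lapply(chambers$placenta_labels, function(k) {
    asg <- chambers$assignments[[as.character(k)]]
    vals <- pmap$f_over_vt[asg$voxels]
    sets <- list(low = vals[asg$is_low], high = vals[!asg$is_low],
                 whole = vals)
    do.call(rbind, lapply(names(sets), function(ch) {
      v <- sets[[ch]]
      data.frame(placenta = k, chamber = ch,
                 abv_ml_min = if (length(v))
                   apparent_blood_volume(v, vox_ml)$abv_ml_min else NA_real_)
    }))
  }))
  summaries <- merge(summaries, abv_rows, by = c("placenta", "chamber"))
  sslope <- vapply(seq_len(nrow(summaries)), function(i) {
    k <- summaries$placenta[i]
    asg <- chambers$assignments[[as.character(k)]]
    sel <- switch(summaries$chamber[i], low = asg$is_low,
                  high = !asg$is_low, whole = rep(TRUE, length(asg$voxels)))
    mean(ss$slope[asg$voxels[sel]])
  }, numeric(1))
  summaries$mean_steepest_slope <- sslope

  relax <- NULL
  if (isTRUE(config$run_relaxometry) && !is.null(session$vfa_pre) &&
      !is.null(session$vfa_post)) {
    pl_mask <- array(label_map > 0 &
                       label_map %in% chambers$placenta_labels,
                     dim(label_map))
    fit_pre <- fit_t1_vfa(session$vfa_pre, mask = pl_mask)
    fit_post <- fit_t1_vfa(session$vfa_post, mask = pl_mask)
    dr1 <- delta_r1(fit_pre, fit_post)
    agu_rows <- do.call(rbind, lapply(chambers$placenta_labels, function(k) {
      asg <- chambers$assignments[[as.character(k)]]
      masks <- list(low = asg$voxels[asg$is_low],
                    high = asg$voxels[!asg$is_low], whole = asg$voxels)
      do.call(rbind, lapply(names(masks), function(ch) {
        m <- array(FALSE, dim(label_map)); m[masks[[ch]]] <- TRUE
        agu <- tryCatch(apparent_gd_uptake(dr1, m), error = function(e) NA)
        data.frame(placenta = k, chamber = ch,
                   agu = as.numeric(agu),
                   mean_delta_r1 = attr(agu, "mean_delta_r1") %||% NA_real_)
      }))
    }))
    summaries <- merge(summaries, agu_rows, by = c("placenta", "chamber"))
    relax <- list(fit_pre = fit_pre, fit_post = fit_post, delta_r1 = dr1)
  }

  motion <- NULL
  if (isTRUE(config$run_motion)) {
    flow <- flow_series(den, alpha = config$flow_alpha)
    traces <- velocity_traces(flow, label_map, chambers,
                              series$meta$frame_interval_s)
    fs <- 1 / series$meta$frame_interval_s
    # spectral mapping uses the unfiltered series: the temporal median /
    # closing suppresses impulsive artifacts but also attenuates genuine
    # ~10 mHz oscillation, which spans only ~5-6 frames at this frame rate
    sb <- subband_relative_power_map(series, band_hz = config$band_hz,
                                     label_map = label_map,
                                     chambers = chambers)
    phasic <- classify_phasic(sb, config$phasic_threshold)
    whole <- traces[traces$region == "whole", ]
    psds <- lapply(split(whole, whole$placenta), function(tr)
      welch_psd(tr$mean_speed, fs))
    motion <- list(traces = traces, subband = sb, phasic = phasic,
                   psd = psds)
    mt <- stats::aggregate(mean_speed ~ placenta + region, traces, mean)
    names(mt)[3] <- "mean_speed"
    summaries <- merge(summaries, mt,
                       by.x = c("placenta", "chamber"),
                       by.y = c("placenta", "region"), all.x = TRUE)
    sbm <- sb$summary
    names(sbm)[names(sbm) == "region"] <- "chamber"
    summaries <- merge(summaries, sbm, by = c("placenta", "chamber"),
                       all.x = TRUE)
    summaries <- merge(summaries, phasic[, c("placenta", "phasic")],
                       by = "placenta", all.x = TRUE)
  }
  summaries <- cbind(session = session$id %||% NA, age = age, summaries)
  list(session = session$id, age = age, denoised = den, aif = aif,
       mip = mip, steepest_slope = ss, perfusion = pmap,
       chambers = chambers, table = summaries, gmm = gmm,
       biomarkers = biomarkers, relaxometry = relax, motion = motion)
}

#' Run the full analysis pipeline
#'
#' Resolves each configured session (synthesising phantom data where a
#' [phantom_spec()] is given), analyses it with [analyze_session()], and
#' assembles the study report: the per-placenta per-chamber table, the
#' mixture biomarkers per session, and age-group comparisons of mean
#' chamber perfusion. Deterministic given `config$seed`. When `out_dir`
#' is given, per-session results are cached there as RDS and the report
#' tables written as CSV; an existing cache is reused (delete the file to
#' recompute a stage).
#'
#' @param config A [study_config()].
#' @param out_dir Optional output/cache directory.
#' @return An object of class `study_report`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- vector("list", length(config$sessions))
  for (i in seq_along(config$sessions)) {
    cache <- if (!is.null(out_dir))
      file.path(out_dir, sprintf("session_%02d.rds", i)) else NULL
    if (!is.null(cache) && file.exists(cache)) {
      results[[i]] <- readRDS(cache)
      next
    }
    sess <- resolve_session(config$sessions[[i]], i)
    res <- analyze_session(sess, config)
    res$table$session <- i
    if (!is.null(sess$phantom)) res$truth <- sess$phantom$truth
    results[[i]] <- res
    if (!is.null(cache)) saveRDS(res, cache)
  }
  placenta_table <- do.call(rbind, lapply(results, `[[`, "table"))
  gmm_table <- do.call(rbind, lapply(results, function(r) {
    cbind(session = r$session, age = r$age, r$biomarkers)
  }))
  group_table <- tryCatch(
    group_compare(placenta_table, "mean_perfusion", "age"),
    error = function(e) NULL)
  report <- structure(list(placenta_table = placenta_table,
                           gmm_table = gmm_table,
                           group_table = group_table,
                           sessions = results,
                           seed = config$seed,
                           config = config[setdiff(names(config), "sessions")]),
                      class = "study_report")
  if (!is.null(out_dir)) {
    write.csv(placenta_table, file.path(out_dir, "placenta_table.csv"),
              row.names = FALSE)
    write.csv(gmm_table, file.path(out_dir, "gmm_table.csv"),
              row.names = FALSE)
    if (!is.null(group_table))
      write.csv(group_table, file.path(out_dir, "group_table.csv"),
                row.names = FALSE)
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  ages <- unique(x$placenta_table$age)
  cat(sprintf("Study report: %d sessions (%s), %d placenta rows\n",
              length(x$sessions), paste(ages, collapse = ", "),
              nrow(x$placenta_table)))
  agg <- stats::aggregate(mean_perfusion ~ age + chamber,
                          x$placenta_table, mean)
  cat("mean chamber perfusion (mL/min/100 mL):\n")
  print(agg)
  invisible(x)
}

#' @export
summary.study_report <- function(object, ...) {
  print(object)
  if (!is.null(object$group_table)) {
    cat("\ngroup comparisons:\n")
    print(object$group_table)
  }
  invisible(object)
}

#' Group statistics on a report metric
#'
#' Two groups: Welch's unequal-variance t-test. More than two: one-way
#' ANOVA followed by Tukey-Kramer pairwise comparisons. Run separately
#' for each chamber present in the table. Groups with fewer than two
#' observations are skipped with a warning.
#'
#' @param report A `study_report` or its `placenta_table` data frame.
#' @param metric Column to compare (default `"mean_perfusion"`).
#' @param grouping Grouping column (default `"age"`).
#' @return Data frame `(chamber, comparison, difference, statistic,
#'   p_value, method)`.
#' @export
group_compare <- function(report, metric = "mean_perfusion",
                          grouping = "age") {
  df <- if (inherits(report, "study_report")) report$placenta_table else report
  if (!metric %in% names(df)) stopf("no column '%s' in the table", metric)
  chambers <- if ("chamber" %in% names(df)) unique(df$chamber) else "all"
  rows <- list()
  for (ch in chambers) {
    sub <- if (identical(chambers, "all")) df else df[df$chamber == ch, ]
    sub <- sub[is.finite(sub[[metric]]), ]
    groups <- split(sub[[metric]], sub[[grouping]])
    small <- names(groups)[vapply(groups, length, integer(1)) < 2]
    if (length(small)) {
      warnf("groups with < 2 observations skipped: %s",
            paste(small, collapse = ", "))
      groups <- groups[!names(groups) %in% small]
    }
    if (length(groups) < 2) next
    if (length(groups) == 2) {
      tt <- t.test(groups[[1]], groups[[2]], var.equal = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        chamber = ch,
        comparison = paste(names(groups)[1], "vs", names(groups)[2]),
        difference = unname(tt$estimate[1] - tt$estimate[2]),
        statistic = unname(tt$statistic), p_value = tt$p.value,
        method = "Welch t-test")
    } else {
      g <- factor(rep(names(groups), lengths(groups)))
      y <- unlist(groups)
      fit <- aov(y ~ g)
      tk <- TukeyHSD(fit)$g
      rows[[length(rows) + 1]] <- data.frame(
        chamber = ch, comparison = rownames(tk),
        difference = tk[, "diff"], statistic = NA_real_,
        p_value = tk[, "p adj"], method = "ANOVA + Tukey-Kramer")
    }
  }
  if (!length(rows)) stopf("no group had enough observations to compare")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
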