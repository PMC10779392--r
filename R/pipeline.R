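#' Run the full analysis pipeline on a synthetic cohort
#'
#' One call chains the stages in fixed order: simulate (BOLD cohort,
#' atlas phantoms, angiograms) -> region-series preprocessing (band-pass
#' filter, global-signal regression) -> connectome -> difference-matrix
#' analysis and discriminative network -> volumetry -> vascular measures
#' -> group statistics, and returns a single report whose every headline
#' number is also present in a stage output. When `out_dir` is given,
#' stage outputs are written there as CSV/JSON.
#'
#' @param spec a [cohort_spec()] describing the synthetic cohort.
#' @param config a [run_config()]; its seed drives the phantom and
#'   angiogram stages and all permutation tests.
#' @param volume_scalings named list of per-group region-volume scalings
#'   for the phantom stage (see [make_atlas_phantom()]); default plants
#'   a 1.2x enlargement of the last region pair (a medulla analogue) in
#'   the cko group.
#' @param preprocess logical; apply band-pass + global-signal regression
#'   to the simulated region series before correlation (default `TRUE`).
#' @param n_perm permutation draws for pattern p-values (default 1000
#'   here; the standalone functions default to 10000).
#' @param out_dir optional directory for stage outputs.
#' @param blind keep group labels hidden until the difference-matrix and
#'   statistics stages (labels are then attached from metadata); the
#'   simulation itself always knows the truth.
#' @return List of class `pipeline_report`.
#' @export
run_pipeline <- function(spec = cohort_spec(), config = run_config(),
                         volume_scalings = NULL, preprocess = TRUE,
                         n_perm = 1000L, out_dir = NULL, blind = FALSE) {
  validate_run_config(config)
  t0 <- Sys.time()

  ## stage 1: simulate
  cohort <- simulate_bold_cohort(spec)
  n_half <- spec$n_regions %/% 2L
  if (is.null(volume_scalings)) {
    # study-like default: global cko shrinkage with a medulla-analogue
    # region pair enlarged in absolute terms
    cko_scal <- rep(0.8, 2L * n_half)
    cko_scal[c(n_half, 2L * n_half)] <- 1.2
    volume_scalings <- list(control = rep(1, 2L * n_half),
                            cko = cko_scal)
  }
  phantom <- make_atlas_phantom(n_regions_per_hemisphere = n_half,
                                n_control = spec$n_control,
                                n_cko = spec$n_cko,
                                group_scalings = volume_scalings,
                                seed = config$seed)

  ## stage 2: region-series preprocessing
  series <- cohort$series
  if (preprocess) {
    series <- lapply(series, function(rts) {
      m <- bandpass_filter(rts$matrix, tr = rts$tr,
                           passband = config$passband,
                           order = config$filter_order)
      rts$matrix <- global_signal_regress(m,
                                          detrend = config$detrend_global)
      rts
    })
  }

  ## stage 3: connectomes
  connectomes <- lapply(series, compute_connectome)
  if (blind)
    connectomes <- lapply(connectomes, function(cc) {
      cc$group <- "blinded"
      cc
    })
  groups <- cohort$meta$group[!cohort$meta$excluded]

  ## stage 4: difference matrices + discriminative network
  dsets <- difference_matrices(connectomes, groups = groups)
  pat_cc <- class_pattern(dsets$control_control)
  pat_kk <- class_pattern(dsets$cko_cko)
  pat_ck <- class_pattern(dsets$control_cko)
  subj_pattern_cor <- class_pattern_correlation(pat_cc, pat_kk)
  within_ctrl <- pairwise_pattern_r2(dsets$control_control,
                                     n_perm = n_perm, seed = config$seed)
  within_cko <- pairwise_pattern_r2(dsets$cko_cko,
                                    n_perm = n_perm, seed = config$seed)
  between <- pairwise_pattern_r2(dsets$control_control, dsets$cko_cko,
                                 n_perm = n_perm, seed = config$seed)
  net <- group_discriminative_edges(connectomes, groups = groups,
                                    threshold = config$edge_r2_threshold)
  region_summary <- map_edges_to_regions(net, phantom$region_table)

  ## stage 5: volumetry
  vols <- lapply(phantom$atlases, function(a)
    region_volumes(a$labels, phantom$region_table, subject = a$subject))
  vol_cmp <- group_volume_comparison(vols, phantom$meta,
                                     variance = config$ttest_variance)
  brain_row <- vol_cmp[vol_cmp$region == "total_brain", ]

  ## stage 6: vascular (one angiogram per subject; lumen scaled with the
  ## phantom's brain volume so vessel-brain coupling is exercised)
  brain_vols <- vapply(vols, function(v) v$brain_volume_mm3, numeric(1))
  rel <- brain_vols / mean(brain_vols)
  angios <- lapply(seq_along(rel), function(s) {
    len <- max(4L, round(40 * rel[s]))
    tubes <- list(list(axis = 1L, center = c(24, 24), radius = 3,
                       from = 4L, to = 3L + len),
                  list(axis = 2L, center = c(12, 12), radius = 3,
                       from = 4L, to = 3L + len),
                  list(axis = 3L, center = c(36, 36), radius = 3,
                       from = 4L, to = 3L + len))
    simulate_angiogram(grid = c(48L, 48L, 48L), tube_specs = tubes,
                       seed = config$seed + s)
  })
  measures <- lapply(angios, function(a)
    vascular_measures(a$volume, thresholds = config$vascular_thresholds))
  vessel_cor <- vessel_brain_correlation(measures, brain_vols)

  report <- structure(list(
    config = unclass(config),
    spec = list(n_control = spec$n_control, n_cko = spec$n_cko,
                n_regions = spec$n_regions, n_frames = spec$n_frames,
                tr = spec$tr, seed = spec$seed),
    n_subjects = length(connectomes),
    pattern_statistics = list(
      within_control_mean_r2 = within_ctrl$mean_r2,
      within_control_p = within_ctrl$p,
      within_cko_mean_r2 = within_cko$mean_r2,
      within_cko_p = within_cko$p,
      between_mean_r2 = between$mean_r2,
      between_p = between$p,
      class_pattern_r = subj_pattern_cor$r,
      class_pattern_r_squared = subj_pattern_cor$r_squared,
      class_pattern_p = subj_pattern_cor$p),
    network = list(threshold = config$edge_r2_threshold,
                   n_edges = nrow(net$edges),
                   n_regions_implicated = length(net$regions)),
    volumetry = list(
      mean_brain_control = brain_row[[2L]],
      mean_brain_cko = brain_row[[3L]],
      percent_difference = brain_row$percent_difference,
      p = brain_row$p),
    vascular = vessel_cor$summary,
    truth = cohort$truth[c("group_edges", "subject_edges")],
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "pipeline_report")
  report$stage_objects <- list(connectomes = connectomes,
                               difference_sets = dsets, network = net,
                               region_summary = region_summary,
                               volumetry = vols,
                               volume_comparison = vol_cmp,
                               vessel_correlation = vessel_cor)
  if (!is.null(out_dir)) write_pipeline_outputs(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> ", x$n_subjects, " subjects, ",
      x$spec$n_regions, " regions\n", sep = "")
  cat("  network: ", x$network$n_edges, " edges > R2 ",
      x$network$threshold, " over ", x$network$n_regions_implicated,
      " regions\n", sep = "")
  cat("  class patterns: within-control R2 ",
      signif(x$pattern_statistics$within_control_mean_r2, 3),
      ", within-cko R2 ",
      signif(x$pattern_statistics$within_cko_mean_r2, 3),
      ", cross-pattern r ",
      signif(x$pattern_statistics$class_pattern_r, 3), "\n", sep = "")
  cat("  brain volume: ",
      signif(x$volumetry$mean_brain_control, 4), " vs ",
      signif(x$volumetry$mean_brain_cko, 4), " mm3 (",
      x$volumetry$percent_difference, "%)\n", sep = "")
  cat("  vascular: mean R2 ",
      signif(x$vascular$mean_r_squared, 3), " +/- ",
      signif(x$vascular$sd_r_squared, 3), "\n", sep = "")
  invisible(x)
}

# Write the report's stage outputs (CSV + JSON) under out_dir.
write_pipeline_outputs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  so <- report$stage_objects
  for (k in seq_along(so$connectomes))
    write_matrix(so$connectomes[[k]]$matrix,
                 file.path(out_dir, paste0("connectome_",
                                           so$connectomes[[k]]$subject,
                                           ".csv")))
  write_table(so$network$edges, file.path(out_dir, "network_edges.csv"))
  write_table(so$region_summary,
              file.path(out_dir, "network_region_summary.csv"))
  write_table(so$volume_comparison,
              file.path(out_dir, "volume_comparison.csv"))
  write_table(so$vessel_correlation$by_combination,
              file.path(out_dir, "vessel_brain_correlation.csv"))
  headline <- report[setdiff(names(report), "stage_objects")]
  jsonlite::write_json(headline, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
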