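#' Run the full simulated study
#'
#' Executes the whole chain under one seed: generate the template-space
#' cohorts and error maps, smooth all volumes to the scoring FWHM, fit the
#' age-regression reference model on the intensity-normalized reference
#' cohort, score every subject with and without each error map
#' (the subjects x maps cross simulation), and evaluate the endpoints:
#' regional error summaries, PET-score differences, diagnostic accuracy at
#' the fixed cutoffs per error map, error-map ranking, Bland-Altman
#' agreement for the best/worst maps, and the between-institution
#' comparison. Rerunning with the same config reproduces every table
#' exactly.
#'
#' @param config a `study_config`.
#' @param out_dir optional directory; when given, CSV tables and a JSON
#'   manifest are written there.
#' @param quiet suppress progress messages?
#' @return list with `config`, `template`, `subject_table`, `model`,
#'   `score_table`, `regional`, `diffs`, `diagnostics` (per task: original
#'   summary, per-map summaries, ranking), `bland_altman` (best/worst),
#'   `institution_test`, `manifest`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL,
                      quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  say("generating cohorts (", config$n_nc + config$n_ad + config$n_mci,
      " subjects, ", config$n_reference, " references, ",
      config$n_error_maps_a + config$n_error_maps_b, " error maps)")
  coh <- make_cohorts(config)
  template <- coh$template

  say("smoothing volumes to ", config$smoothing_fwhm_mm, " mm FWHM")
  for (i in seq_along(coh$subjects))
    coh$subjects[[i]]$volume <-
      gaussian_smooth(coh$subjects[[i]]$volume, config$smoothing_fwhm_mm)
  ref_sm <- lapply(coh$reference$volumes, gaussian_smooth,
                   fwhm_mm = config$smoothing_fwhm_mm)

  say("fitting reference model (n = ", config$n_reference, ")")
  ref_norm <- lapply(ref_sm, function(v)
    intensity_normalize(v, template$preserved_mask)$volume)
  model <- fit_reference_model(ref_norm, coh$reference$ages,
                               template$brain_mask)

  say("cross simulation: ", length(coh$subjects), " x ",
      length(coh$error_maps), " = ",
      length(coh$subjects) * length(coh$error_maps), " pairs")
  score_table <- run_cross_simulation(coh$subjects, coh$error_maps, model,
                                      template, config)

  regional <- regional_error_summary(coh$error_maps, template)
  diffs <- score_differences(score_table)

  truth <- coh$subject_table
  diagnostics <- list(
    AD_vs_NC = evaluate_task(score_table, truth,
                             subset = truth$group %in% c("AD", "NC"),
                             positive = truth$group == "AD",
                             cutoff = config$cutoff_ad_vs_nc,
                             task = "AD_vs_NC"),
    MCI_conversion = evaluate_task(score_table, truth,
                                   subset = truth$group == "MCI",
                                   positive = truth$converted_24mo,
                                   cutoff = config$cutoff_mci_conversion,
                                   task = "MCI_conversion"))

  # Bland-Altman of the best / worst maps (ranked by AD-vs-NC accuracy)
  base <- score_table[score_table$error_map_id == "none", ]
  baseline_score <- stats::setNames(base$pet_score, base$subject_id)
  ba_for <- function(map_id) {
    sim <- score_table[score_table$error_map_id == map_id, ]
    bland_altman(unname(baseline_score[sim$subject_id]), sim$pet_score)
  }
  rk <- diagnostics$AD_vs_NC$ranking
  ba <- list(best = lapply(stats::setNames(rk$best_ids, rk$best_ids), ba_for),
             worst = lapply(stats::setNames(rk$worst_ids, rk$worst_ids),
                            ba_for))

  inst <- vapply(coh$error_maps, function(e) e$institution, "")
  inst_test <- tryCatch(
    compare_institutions(
      diffs$per_map$mean_diff[match(vapply(coh$error_maps,
                                           function(e) e$map_id, ""),
                                    diffs$per_map$map_id)], inst),
    error = function(e) NULL)   # undefined for degenerate designs

  manifest <- list(
    seed = config$seed,
    n_subjects = length(coh$subjects),
    n_reference = config$n_reference,
    n_error_maps = length(coh$error_maps),
    n_simulated_rows = sum(score_table$error_map_id != "none"),
    n_baseline_rows = sum(score_table$error_map_id == "none"),
    grid_shape = config$grid_shape,
    voxel_size_mm = config$voxel_size_mm)

  res <- list(config = config, template = template,
              subject_table = coh$subject_table, model = model,
              error_maps = coh$error_maps,
              score_table = score_table, regional = regional, diffs = diffs,
              diagnostics = diagnostics, bland_altman = ba,
              institution_test = inst_test, manifest = manifest)
  if (!is.null(out_dir)) write_study_outputs(res, out_dir)
  res
}

evaluate_task <- function(score_table, truth, subset, positive, cutoff,
                          task) {
  ids <- truth$subject_id[subset]
  pos <- stats::setNames(positive[subset], ids)
  one <- function(map_id) {
    rows <- score_table[score_table$error_map_id == map_id &
                          score_table$subject_id %in% ids, ]
    diagnostic_metrics(rows$pet_score, unname(pos[rows$subject_id]), cutoff,
                       task = task,
                       error_map_id = if (map_id == "none") "original"
                                      else map_id)
  }
  original <- one("none")
  map_ids <- setdiff(unique(score_table$error_map_id), "none")
  per_map <- lapply(map_ids, one)
  list(original = original, per_map = per_map,
       ranking = rank_error_maps(per_map))
}

write_study_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  w(res$subject_table, "subjects.csv")
  w(res$score_table, "scores.csv")
  w(res$regional$per_map, "error_map_regional.csv")
  w(res$regional$summary, "error_map_summary.csv")
  w(res$diffs$per_map, "score_diff_per_map.csv")
  for (task in names(res$diagnostics)) {
    d <- res$diagnostics[[task]]
    w(d$ranking$table, paste0("diagnostics_", task, "_per_map.csv"))
    w(d$ranking$across, paste0("diagnostics_", task, "_across.csv"))
    orig <- d$original
    w(data.frame(metric = c("accuracy", "sensitivity", "specificity"),
                 value = c(orig$accuracy, orig$sensitivity,
                           orig$specificity),
                 ci_low = orig$ci["low", ], ci_high = orig$ci["high", ]),
      paste0("diagnostics_", task, "_original.csv"))
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
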