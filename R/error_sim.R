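# Regional percent-deviation stats of an error field: brain, AD-related and
# non-AD (brain minus AD) spatial means, as percent deviation from unity.
error_map_stats <- function(field, template) {
  inbrain <- template$brain_mask$data > 0
  ad <- template$ad_mask$data > 0
  vals <- field$data
  c(brain_pct = 100 * (mean(vals[inbrain]) - 1),
    ad_pct = 100 * (mean(vals[ad]) - 1),
    nonad_pct = 100 * (mean(vals[inbrain & !ad]) - 1))
}

new_error_map <- function(map_id, institution, field, source, template) {
  vals <- field$data
  if (any(vals <= 0 | vals >= 2))
    stop("error_map: field values must lie in (0, 2); range [",
         min(vals), ", ", max(vals), "]")
  structure(list(map_id = map_id, institution = institution, field = field,
                 source = source, stats = error_map_stats(field, template)),
            class = "error_map")
}

#' @export
print.error_map <- function(x, ...) {
  cat(sprintf("<error_map> %s (%s, %s): brain %+.2f%%, AD %+.2f%%, non-AD %+.2f%%\n",
              x$map_id, x$institution, x$source,
              x$stats["brain_pct"], x$stats["ad_pct"], x$stats["nonad_pct"]))
  invisible(x)
}

#' Voxel-wise MRAC/CTAC error map from a measured pair
#'
#' Divides the MRAC-reconstructed PET by the CTAC reconstruction of the same
#' raw data. Voxels where the CTAC value falls below `eps_frac` times the
#' in-mask CTAC mean (and all voxels outside the brain mask) are set to 1;
#' the count of excluded in-mask voxels is attached as attribute
#' `n_excluded`.
#'
#' @param pet_mrac,pet_ctac `volume_grid`s on the same grid.
#' @param brain_mask binary `volume_grid`.
#' @param eps_frac ratio guard in (0, 0.5).
#' @return a `volume_grid` ratio map with attribute `n_excluded`.
#' @export
compute_error_map <- function(pet_mrac, pet_ctac, brain_mask,
                              eps_frac = 0.05) {
  if (!same_grid(pet_mrac, pet_ctac))
    stop_grid_mismatch(pet_mrac, pet_ctac, "compute_error_map")
  if (!same_grid(pet_mrac, brain_mask))
    stop_grid_mismatch(pet_mrac, brain_mask, "compute_error_map")
  if (eps_frac <= 0 || eps_frac >= 0.5)
    stop("compute_error_map: eps_frac must lie in (0, 0.5)")
  inbrain <- brain_mask$data > 0
  ctac_mean <- mean(pet_ctac$data[inbrain])
  if (ctac_mean <= 0)
    stop("compute_error_map: brain-mask mean of CTAC volume is ", ctac_mean)
  thr <- eps_frac * ctac_mean
  ok <- inbrain & pet_ctac$data > thr
  out <- pet_mrac
  out$data <- array(1, dim(pet_mrac$data))
  out$data[ok] <- pet_mrac$data[ok] / pet_ctac$data[ok]
  attr(out, "n_excluded") <- sum(inbrain & !ok)
  out
}

#' Normalize a raw error map to template space
#'
#' Resample with the CTAC-derived transform, smooth to the scoring FWHM,
#' re-apply the brain mask with fill 1, and compute regional stats —
#' producing an `error_map` on the template grid, directly comparable with
#' synthetic fields.
#'
#' @param error_raw `volume_grid` ratio map in subject space.
#' @param ctac_to_template_transform `affine_transform` (fixed = template).
#' @param template a `template_space`.
#' @param fwhm_mm smoothing FWHM (default 12 mm).
#' @param map_id,institution identifiers.
#' @return an `error_map` with `source = "measured-pair"`.
#' @export
normalize_error_map <- function(error_raw, ctac_to_template_transform,
                                template, fwhm_mm = 12,
                                map_id = "map", institution = "InA") {
  res <- resample(error_raw, ctac_to_template_transform, template)
  # out-of-field voxels resample to 0; they are outside the measured volume,
  # not measured-as-zero error, so restore the neutral value before smoothing
  res$data[res$data == 0] <- 1
  sm <- gaussian_smooth(res, fwhm_mm)
  sm <- apply_mask(sm, template$brain_mask, fill = 1)
  new_error_map(map_id, institution, sm, "measured-pair", template)
}

#' Impose a multiplicative error map on a normalized subject volume
#'
#' Plain voxel-wise product — no further smoothing or renormalization at
#' this step; intensity normalization happens per scored pair downstream.
#'
#' @param norm_subject_volume `volume_grid` on the template grid.
#' @param error_map an `error_map` or a `volume_grid`.
#' @return a `volume_grid`.
#' @export
apply_error <- function(norm_subject_volume, error_map) {
  fld <- if (inherits(error_map, "error_map")) error_map$field else error_map
  if (!same_grid(norm_subject_volume, fld))
    stop_grid_mismatch(norm_subject_volume, fld, "apply_error")
  out <- norm_subject_volume
  out$data <- out$data * fld$data
  out
}

#' Cross simulation: every subject times every error map
#'
#' For each (subject, error map) pair, multiplies the spatially normalized,
#' smoothed subject volume by the error field and reruns the scoring chain
#' from intensity normalization onward (steps two to five: value
#' normalization, expected values, t-map, t-sum / PET score). Baseline
#' (no-error) scores are included with `error_map_id = "none"`. The inner
#' loop evaluates only AD-mask and preserved-mask voxels, which the score
#' depends on exclusively; equivalence with the full-volume
#' [score_subject()] path is part of the test suite.
#'
#' @param subjects list of `list(record, volume)` with volumes already
#'   smoothed and in template space.
#' @param error_maps list of `error_map`s.
#' @param model a `reference_model`.
#' @param template a `template_space`.
#' @param config a `study_config`.
#' @return data.frame with columns `subject_id`, `error_map_id`,
#'   `ad_t_sum`, `pet_score`, `normalization_mean`, `flagged` — one baseline
#'   row per subject plus one row per subject x map.
#' @export
run_cross_simulation <- function(subjects, error_maps, model, template,
                                 config = study_config()) {
  pres_idx <- which(template$preserved_mask$data > 0)
  ad_idx <- which(template$ad_mask$data > 0)
  if (!length(ad_idx)) stop("run_cross_simulation: empty AD mask")

  # model restricted to AD-mask voxels (positions within the model mask)
  pos <- match(ad_idx, model$mask_idx)
  if (anyNA(pos))
    stop("run_cross_simulation: AD mask extends outside the model mask")
  a_ad <- model$intercept[pos]; b_ad <- model$slope[pos]
  s_ad <- model$residual_sd[pos]
  ok_sd <- s_ad > 0

  n_sub <- length(subjects); n_map <- length(error_maps)
  U_ad <- vapply(subjects, function(s) s$volume$data[ad_idx],
                 numeric(length(ad_idx)))
  U_pr <- vapply(subjects, function(s) s$volume$data[pres_idx],
                 numeric(length(pres_idx)))
  E_ad <- vapply(error_maps, function(e) e$field$data[ad_idx],
                 numeric(length(ad_idx)))
  E_pr <- vapply(error_maps, function(e) e$field$data[pres_idx],
                 numeric(length(pres_idx)))
  ages <- vapply(subjects, function(s) s$record$age, 0)
  ids <- vapply(subjects, function(s) s$record$subject_id, "")
  map_ids <- vapply(error_maps, function(e) e$map_id, "")

  score_pair <- function(j, e_ad, e_pr) {
    m <- mean(U_pr[, j] * e_pr)
    if (m <= 0) return(list(ts = NA_real_, ps = NA_real_, m = m,
                            flagged = TRUE))
    k <- if (config$t_denominator == "prediction")
      sqrt(1 + 1 / model$n + (ages[j] - model$mean_age)^2 / model$age_ssq)
    else 1
    expected <- a_ad + b_ad * ages[j]
    tv <- numeric(length(ad_idx))
    tv[ok_sd] <- (expected[ok_sd] - U_ad[ok_sd, j] * e_ad[ok_sd] / m) /
      (s_ad[ok_sd] * k)
    if (config$clip_negative_t) tv <- pmax(tv, 0)
    ts <- sum(tv)
    if (ts <= -config$pet_score_denominator)
      return(list(ts = ts, ps = NA_real_, m = m, flagged = TRUE))
    list(ts = ts, ps = pet_score(ts, config$pet_score_denominator), m = m,
         flagged = FALSE)
  }

  n_rows <- n_sub * (n_map + 1)
  col_sid <- character(n_rows); col_map <- character(n_rows)
  col_ts <- numeric(n_rows); col_ps <- numeric(n_rows)
  col_nm <- numeric(n_rows); col_fl <- logical(n_rows)
  ones_ad <- rep(1, length(ad_idx)); ones_pr <- rep(1, length(pres_idx))
  row <- 0L
  fill <- function(j, mid, r) {
    row <<- row + 1L
    col_sid[row] <<- ids[j]; col_map[row] <<- mid
    col_ts[row] <<- r$ts; col_ps[row] <<- r$ps
    col_nm[row] <<- r$m; col_fl[row] <<- r$flagged
  }
  for (j in seq_len(n_sub))             # baselines first
    fill(j, "none", score_pair(j, ones_ad, ones_pr))
  for (i in seq_len(n_map)) {
    e_ad <- E_ad[, i]; e_pr <- E_pr[, i]
    for (j in seq_len(n_sub))
      fill(j, map_ids[i], score_pair(j, e_ad, e_pr))
  }
  data.frame(subject_id = col_sid, error_map_id = col_map,
             ad_t_sum = col_ts, pet_score = col_ps,
             normalization_mean = col_nm, flagged = col_fl,
             stringsAsFactors = FALSE)
}
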