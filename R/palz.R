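#' Intensity normalization to the AD-preserved region
#'
#' Divides every voxel by the mean value inside the preserved mask (voxels
#' whose FDG uptake is typically spared in Alzheimer's disease), making the
#' score invariant to global scanner scaling.
#'
#' @param volume a `volume_grid`.
#' @param preserved_mask binary `volume_grid` on the same grid.
#' @return list with `volume` (normalized `volume_grid`) and `mean` (the
#'   divisor).
#' @export
intensity_normalize <- function(volume, preserved_mask) {
  if (!same_grid(volume, preserved_mask))
    stop_grid_mismatch(volume, preserved_mask, "intensity_normalize")
  m <- mask_mean(volume, preserved_mask)
  if (m <= 0)
    stop("intensity_normalize: preserved-mask mean is ", m,
         " (degenerate image)")
  out <- volume
  out$data <- out$data / m
  list(volume = out, mean = m)
}

#' Fit the voxel-wise age-regression reference model
#'
#' Ordinary least squares of normalized uptake on age at every voxel of the
#' mask: intercept `a_v`, slope `b_v` (per year), residual SD
#' `s_v = sqrt(RSS_v / (n - 2))`, plus the cohort constants (n, mean age,
#' age sum of squares) needed for prediction-interval t-statistics.
#'
#' @param normalized_volumes list of `volume_grid`s (already intensity
#'   normalized and smoothed).
#' @param ages numeric vector, one age per volume, not all equal.
#' @param mask binary `volume_grid`; the model is defined on its voxels.
#' @return a `reference_model`: list with vectors `intercept`, `slope`,
#'   `residual_sd` (over mask voxels), `mask`, `mask_idx`, `n`, `mean_age`,
#'   `age_ssq`, `grid_shape`.
#' @export
fit_reference_model <- function(normalized_volumes, ages, mask) {
  n <- length(normalized_volumes)
  if (n != length(ages))
    stop("fit_reference_model: ", n, " volumes but ", length(ages), " ages")
  if (n < 10)
    stop("fit_reference_model: need >= 10 reference subjects, got ", n)
  if (stats::sd(ages) == 0)
    stop("fit_reference_model: degenerate design (all ages equal)")
  keep <- mask$data > 0
  if (!any(keep)) stop("fit_reference_model: empty mask")
  Y <- vapply(normalized_volumes, function(v) v$data[keep],
              numeric(sum(keep)))           # n_vox x n
  abar <- mean(ages)
  xc <- ages - abar
  sxx <- sum(xc^2)
  b <- as.numeric(Y %*% xc) / sxx
  ybar <- rowMeans(Y)
  a <- ybar - b * abar
  fitted_c <- outer(b, xc)                  # centred fitted values
  rss <- rowSums((Y - ybar - fitted_c)^2)
  s <- sqrt(pmax(rss, 0) / (n - 2))
  # residual SDs at floating-point rounding level are true zero variance
  # (e.g. a noise-free cohort); flooring them avoids 0/0 t-values
  s[s < 1e-9 * mean(abs(Y))] <- 0
  structure(list(intercept = a, slope = b, residual_sd = s,
                 mask = mask, mask_idx = which(keep),
                 n = n, mean_age = abar, age_ssq = sxx,
                 grid_shape = dim(mask$data)),
            class = "reference_model")
}

#' Voxel-wise t-map against the reference model
#'
#' For each model voxel, `t_v = (a_v + b_v age - u_v) / (s_v k)` with
#' `k = sqrt(1 + 1/n + (age - mean_age)^2 / age_ssq)` (the prediction
#' interval for one new observation against a regression database;
#' `t_denominator = "residual"` drops the inflation). Positive t means
#' hypometabolism — uptake below the age-expected value. Voxels with
#' `s_v = 0` get `t = 0` and are counted in the `n_zero_sd` attribute.
#'
#' @param normalized_volume intensity-normalized `volume_grid` on the model
#'   grid.
#' @param age subject age in years.
#' @param model a `reference_model`.
#' @param t_denominator `"prediction"` or `"residual"`.
#' @return a `volume_grid` of t-values (0 outside the model mask) with
#'   attribute `n_zero_sd`.
#' @export
t_map <- function(normalized_volume, age, model,
                  t_denominator = c("prediction", "residual")) {
  t_denominator <- match.arg(t_denominator)
  if (!all(dim(normalized_volume$data) == model$grid_shape))
    stop("t_map: volume grid ", paste(dim(normalized_volume$data),
                                      collapse = "x"),
         " does not match model grid ", paste(model$grid_shape,
                                              collapse = "x"))
  u <- normalized_volume$data[model$mask_idx]
  expected <- model$intercept + model$slope * age
  k <- if (t_denominator == "prediction")
    sqrt(1 + 1 / model$n + (age - model$mean_age)^2 / model$age_ssq)
  else 1
  den <- model$residual_sd * k
  tv <- ifelse(den > 0, (expected - u) / den, 0)
  out <- normalized_volume
  out$data <- array(0, dim(normalized_volume$data))
  out$data[model$mask_idx] <- tv
  attr(out, "n_zero_sd") <- sum(den <= 0)
  out
}

#' AD t-sum
#'
#' Signed sum of voxel t-values over the AD-related mask (negative t-values
#' subtract; set `clip_negative` to clip them at zero first).
#'
#' @param t_volume `volume_grid` of t-values.
#' @param ad_mask binary `volume_grid` on the same grid, nonempty.
#' @param clip_negative clip negative t-values before summing?
#' @return scalar AD t-sum.
#' @export
ad_t_sum <- function(t_volume, ad_mask, clip_negative = FALSE) {
  if (!same_grid(t_volume, ad_mask))
    stop_grid_mismatch(t_volume, ad_mask, "ad_t_sum")
  keep <- ad_mask$data > 0
  if (!any(keep)) stop("ad_t_sum: empty AD mask")
  tv <- t_volume$data[keep]
  if (clip_negative) tv <- pmax(tv, 0)
  sum(tv)
}

#' PET score transform
#'
#' `log2(ad_t_sum / denominator + 1)`; the default denominator 11089 is the
#' 95% prediction limit of the AD t-sum in healthy controls established in
#' the NEST-DD multi-centre trial, so an AD t-sum at that limit maps to a
#' PET score of exactly 1 — the AD-versus-normal decision cutoff.
#'
#' @param ad_t_sum numeric, must exceed `-denominator`.
#' @param denominator positive scaling constant.
#' @return PET score(s).
#' @export
pet_score <- function(ad_t_sum, denominator = 11089) {
  if (any(ad_t_sum <= -denominator))
    stop("pet_score: AD t-sum ", min(ad_t_sum), " <= -", denominator,
         "; log2 argument not positive")
  log2(ad_t_sum / denominator + 1)
}

#' Score one subject with the full PALZ-style chain
#'
#' Pipeline: optional affine spatial normalization, Gaussian smoothing
#' (skip both with `already_normalized = TRUE` for inputs prepared
#' upstream — the cross simulation must not re-smooth), then intensity
#' normalization to the preserved mask, voxel-wise t-map, AD t-sum and PET
#' score.
#'
#' @param volume subject `volume_grid`.
#' @param age subject age in years.
#' @param model a `reference_model`.
#' @param template a `template_space`.
#' @param config a `study_config` (smoothing FWHM, t denominator, negative-t
#'   clipping, PET-score denominator).
#' @param already_normalized input is already in template space and
#'   smoothed?
#' @param transform optional `affine_transform` applied before smoothing.
#' @param subject_id,error_map_id identifiers carried into the result.
#' @return a `score_result`: list with `subject_id`, `error_map_id`,
#'   `ad_t_sum`, `pet_score`, `normalization_mean`, `n_zero_sd`.
#' @export
score_subject <- function(volume, age, model, template,
                          config = study_config(),
                          already_normalized = FALSE, transform = NULL,
                          subject_id = "subject", error_map_id = "none") {
  v <- volume
  if (!already_normalized) {
    if (!is.null(transform)) v <- resample(v, transform, template)
    v <- gaussian_smooth(v, config$smoothing_fwhm_mm)
  }
  norm <- intensity_normalize(v, template$preserved_mask)
  tm <- t_map(norm$volume, age, model, config$t_denominator)
  ts <- ad_t_sum(tm, template$ad_mask, clip_negative = config$clip_negative_t)
  structure(list(subject_id = subject_id, error_map_id = error_map_id,
                 ad_t_sum = ts,
                 pet_score = pet_score(ts, config$pet_score_denominator),
                 normalization_mean = norm$mean,
                 n_zero_sd = attr(tm, "n_zero_sd")),
            class = "score_result")
}
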