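#' Study configuration
#'
#' One configuration object drives the whole simulated study: cohort
#' composition, generator parameters, error-field calibration, scoring
#' options and decision cutoffs. Defaults reproduce the study conditions:
#' 48 NC / 59 AD / 96 MCI subjects (33 MCI converters), 20 + 27 error maps
#' from two institutions, a whole-brain mean multiplicative error of
#' -1.37% with between-map SD 1.98%, and regional offsets placing the
#' AD-mask mean at -0.86% and the non-AD mean at -1.59%.
#'
#' @param n_nc,n_ad,n_mci,n_mci_converters cohort counts.
#' @param n_error_maps_a,n_error_maps_b error maps per institution.
#' @param n_reference size of the normal reference database.
#' @param ad_hypometabolism_fraction fractional uptake reduction in the AD
#'   mask for AD subjects.
#' @param mci_converter_fraction_of_ad_effect,mci_stable_fraction_of_ad_effect
#'   MCI effect sizes as fractions of the AD effect.
#' @param age_slope_per_year relative uptake decline per year of age.
#' @param age_range,age_ref,age_distribution age model; `age_distribution`
#'   is `"uniform"` (default) or `"normal"` (mean 76.0, SD 6.3, truncated
#'   to `age_range`).
#' @param voxel_noise_sd,noise_smoothing_fwhm_mm voxel noise before
#'   smoothing and the noise correlation scale.
#' @param error_global_mean,error_between_map_sd global multiplicative error
#'   level: one draw per map from N(mean, sd).
#' @param error_ad_offset,error_nonad_offset regional offsets added inside /
#'   outside the AD mask (within the brain).
#' @param error_within_map_sd,error_field_fwhm_mm amplitude and correlation
#'   length of the smooth within-map error texture.
#' @param error_clip_range all error-field values clipped to this range.
#' @param grid_shape,voxel_size_mm template geometry (default half-resolution
#'   MNI-like grid, 46x55x46 at 4 mm).
#' @param smoothing_fwhm_mm scoring-chain Gaussian smoothing FWHM.
#' @param t_denominator `"prediction"` (residual SD inflated by the
#'   prediction-interval factor) or `"residual"`.
#' @param clip_negative_t clip negative voxel t-values before summing?
#' @param pet_score_denominator AD t-sum 95% prediction limit used in the
#'   PET-score transform.
#' @param cutoff_ad_vs_nc,cutoff_mci_conversion decision cutoffs.
#' @param eps_frac near-zero denominator guard for measured error maps, as a
#'   fraction of the in-mask mean.
#' @param seed integer master seed; every stage derives a named substream
#'   from it.
#' @return a list of class `study_config`.
#' @export
study_config <- function(n_nc = 48L, n_ad = 59L, n_mci = 96L,
                         n_mci_converters = 33L,
                         n_error_maps_a = 20L, n_error_maps_b = 27L,
                         n_reference = 60L,
                         ad_hypometabolism_fraction = 0.20,
                         mci_converter_fraction_of_ad_effect = 0.6,
                         mci_stable_fraction_of_ad_effect = 0.2,
                         age_slope_per_year = -0.003,
                         age_range = c(55, 90),
                         age_ref = mean(age_range),
                         age_distribution = c("uniform", "normal"),
                         voxel_noise_sd = 0.05,
                         noise_smoothing_fwhm_mm = 6,
                         error_global_mean = -0.0137,
                         error_between_map_sd = 0.0198,
                         error_ad_offset = 0.0051,
                         error_nonad_offset = -0.0022,
                         error_within_map_sd = 0.02,
                         error_field_fwhm_mm = 20,
                         error_clip_range = c(0.7, 1.3),
                         grid_shape = c(46L, 55L, 46L),
                         voxel_size_mm = c(4, 4, 4),
                         smoothing_fwhm_mm = 12,
                         t_denominator = c("prediction", "residual"),
                         clip_negative_t = FALSE,
                         pet_score_denominator = 11089,
                         cutoff_ad_vs_nc = 1.0,
                         cutoff_mci_conversion = 0.79,
                         eps_frac = 0.05,
                         seed = 1L) {
  cfg <- list(
    n_nc = as.integer(n_nc), n_ad = as.integer(n_ad),
    n_mci = as.integer(n_mci), n_mci_converters = as.integer(n_mci_converters),
    n_error_maps_a = as.integer(n_error_maps_a),
    n_error_maps_b = as.integer(n_error_maps_b),
    n_reference = as.integer(n_reference),
    ad_hypometabolism_fraction = ad_hypometabolism_fraction,
    mci_converter_fraction_of_ad_effect = mci_converter_fraction_of_ad_effect,
    mci_stable_fraction_of_ad_effect = mci_stable_fraction_of_ad_effect,
    age_slope_per_year = age_slope_per_year,
    age_range = as.numeric(age_range), age_ref = age_ref,
    age_distribution = match.arg(age_distribution),
    voxel_noise_sd = voxel_noise_sd,
    noise_smoothing_fwhm_mm = noise_smoothing_fwhm_mm,
    error_global_mean = error_global_mean,
    error_between_map_sd = error_between_map_sd,
    error_ad_offset = error_ad_offset,
    error_nonad_offset = error_nonad_offset,
    error_within_map_sd = error_within_map_sd,
    error_field_fwhm_mm = error_field_fwhm_mm,
    error_clip_range = as.numeric(error_clip_range),
    grid_shape = as.integer(rep_len(grid_shape, 3L)),
    voxel_size_mm = as.numeric(rep_len(voxel_size_mm, 3L)),
    smoothing_fwhm_mm = smoothing_fwhm_mm,
    t_denominator = match.arg(t_denominator),
    clip_negative_t = isTRUE(clip_negative_t),
    pet_score_denominator = pet_score_denominator,
    cutoff_ad_vs_nc = cutoff_ad_vs_nc,
    cutoff_mci_conversion = cutoff_mci_conversion,
    eps_frac = eps_frac,
    seed = as.integer(seed))
  validate_study_config(cfg)
  structure(cfg, class = "study_config")
}

validate_study_config <- function(cfg) {
  with(cfg, {
    if (n_nc <= 0 || n_ad <= 0 || n_mci <= 0)
      stop("study_config: cohort counts must be positive")
    if (n_mci_converters > n_mci)
      stop("study_config: n_mci_converters (", n_mci_converters,
           ") exceeds n_mci (", n_mci, ")")
    fr <- c(ad_hypometabolism_fraction, mci_converter_fraction_of_ad_effect,
            mci_stable_fraction_of_ad_effect)
    if (any(fr < 0 | fr > 1))
      stop("study_config: effect fractions must lie in [0, 1]")
    if (error_field_fwhm_mm <= 0)
      stop("study_config: error_field_fwhm_mm must be positive")
    if (cutoff_ad_vs_nc <= 0 || cutoff_mci_conversion <= 0)
      stop("study_config: cutoffs must be positive")
    if (eps_frac <= 0 || eps_frac >= 0.5)
      stop("study_config: eps_frac must lie in (0, 0.5)")
    if (age_range[1] >= age_range[2])
      stop("study_config: degenerate age_range")
  })
  invisible(cfg)
}

#' Write / read a study configuration as YAML
#'
#' Round-trips losslessly: `read_study_config(write_study_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param cfg a `study_config`.
#' @param path file path.
#' @return `write_study_config` returns `path` invisibly;
#'   `read_study_config` returns a `study_config`.
#' @export
write_study_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(study_config, vals)
}

# Deterministic per-stage substream seed derived from the master seed, so
# each stage (subjects, reference, error maps, ...) is independently
# reproducible. Kept below 2^31 - 1.
substream_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 104729
  as.integer((as.numeric(seed) * 48271 + h * 7919 + 12345) %% 2147483647)
}
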