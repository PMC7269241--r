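#' Subject metadata record
#'
#' @param subject_id string id.
#' @param age age in years.
#' @param group one of `"NC"`, `"AD"`, `"MCI"`.
#' @param converted_24mo did an MCI subject convert to AD within 24 months?
#'   Must be `FALSE`/`NA` unless `group == "MCI"`.
#' @param institution `"ADNI"`, `"InA"` or `"InB"`.
#' @return a list of class `subject_record`.
#' @export
subject_record <- function(subject_id, age, group,
                           converted_24mo = NA, institution = "ADNI") {
  group <- match.arg(group, c("NC", "AD", "MCI"))
  if (group != "MCI" && isTRUE(converted_24mo))
    stop("subject_record: converted_24mo defined only for MCI subjects")
  structure(list(subject_id = subject_id, age = as.numeric(age),
                 group = group,
                 converted_24mo = if (group == "MCI") isTRUE(converted_24mo)
                                  else FALSE,
                 institution = institution),
            class = "subject_record")
}

# Fractional AD-mask uptake reduction for a record under the config.
effect_size <- function(record, config) {
  base <- config$ad_hypometabolism_fraction
  switch(record$group,
         NC = 0,
         AD = base,
         MCI = if (record$converted_24mo)
                 base * config$mci_converter_fraction_of_ad_effect
               else base * config$mci_stable_fraction_of_ad_effect,
         stop("effect_size: unknown group '", record$group, "'"))
}

# Baseline uptake by region: 1.0 in gray labels (1-4), 0.25 in the deep
# core (inside brain, label 0), 0 outside the brain.
baseline_uptake <- function(template) {
  b <- array(0, template$grid_shape)
  inbrain <- template$brain_mask$data > 0
  b[inbrain] <- 0.25
  b[template$region_labels$data > 0] <- 1
  b
}

#' Simulate one subject's template-space PET volume
#'
#' Uptake model: `baseline(region) * (1 + slope * (age - age_ref)) *
#' (1 - effect(voxel)) + noise`, where the effect applies inside the AD
#' mask only (full size for AD, configured fractions for MCI converters and
#' stables, zero for NC), and the noise is a smooth Gaussian random field
#' with correlation scale `noise_smoothing_fwhm_mm` and standard deviation
#' `voxel_noise_sd` (white noise smoothed, then rescaled, so the amplitude
#' is independent of the correlation scale). Values are clipped at zero.
#'
#' @param template a `template_space`.
#' @param record a `subject_record`.
#' @param config a `study_config`.
#' @param rng_seed integer seed for this volume's noise.
#' @return a `volume_grid`.
#' @export
sample_subject_volume <- function(template, record, config, rng_seed) {
  if (record$age < config$age_range[1] || record$age > config$age_range[2])
    stop("sample_subject_volume: age ", record$age,
         " outside configured range [",
         paste(config$age_range, collapse = ", "), "]")
  eff <- effect_size(record, config)
  u <- baseline_uptake(template) *
    (1 + config$age_slope_per_year * (record$age - config$age_ref))
  if (eff > 0) {
    adv <- template$ad_mask$data > 0
    u[adv] <- u[adv] * (1 - eff)
  }
  if (config$voxel_noise_sd > 0) {
    set.seed(rng_seed)
    noise <- volume_grid(
      array(stats::rnorm(prod(template$grid_shape)), template$grid_shape),
      template$voxel_size_mm, template$affine)
    noise <- gaussian_smooth(noise, config$noise_smoothing_fwhm_mm)
    # voxel_noise_sd is the amplitude of the smoothed field: rescale after
    # smoothing so the noise level does not depend on the correlation scale
    s <- stats::sd(noise$data)
    u <- u + noise$data * (config$voxel_noise_sd / s)
  }
  volume_grid(pmax(u, 0), template$voxel_size_mm, template$affine)
}

#' Generate the normal reference cohort
#'
#' `n_reference` NC-group volumes with ages drawn from the configured age
#' distribution, the raw material for [fit_reference_model()].
#'
#' @inheritParams sample_subject_volume
#' @param rng_seed integer substream seed.
#' @return list with `volumes` (list of `volume_grid`), `ages` (numeric) and
#'   `records`.
#' @export
build_reference_cohort <- function(template, config, rng_seed) {
  n <- config$n_reference
  if (n < 10)
    stop("build_reference_cohort: n_reference must be >= 10 ",
         "(voxel-wise regression would be under-determined)")
  set.seed(rng_seed)
  ages <- draw_ages(n, config)
  vol_seeds <- sample.int(2^30, n)
  records <- lapply(seq_len(n), function(i)
    subject_record(sprintf("REF%03d", i), ages[i], "NC"))
  volumes <- lapply(seq_len(n), function(i)
    sample_subject_volume(template, records[[i]], config, vol_seeds[i]))
  list(volumes = volumes, ages = ages, records = records)
}

draw_ages <- function(n, config) {
  if (config$age_distribution == "normal") {
    a <- stats::rnorm(n, 76.0, 6.3)
    pmin(pmax(a, config$age_range[1]), config$age_range[2])
  } else {
    stats::runif(n, config$age_range[1], config$age_range[2])
  }
}

#' Sample a synthetic MRAC-like multiplicative error field
#'
#' Inside the brain mask the field is `1 + g + r(v) + o(region)` where `g`
#' is one global draw per map from N(`error_global_mean`,
#' `error_between_map_sd`), `r` is a smooth zero-mean texture (Gaussian
#' white noise smoothed to `error_field_fwhm_mm`, centred over the brain
#' mask and rescaled to within-map SD `error_within_map_sd`), and `o` adds
#' `error_ad_offset` on the AD mask and `error_nonad_offset` on the rest of
#' the brain. Outside the brain the field is exactly 1. Values are clipped
#' to `error_clip_range`.
#'
#' @param template a `template_space`.
#' @param institution `"InA"` or `"InB"`.
#' @param config a `study_config`.
#' @param rng_seed integer seed for this map.
#' @param map_id optional id string.
#' @return an `error_map`: list with `map_id`, `institution`, `field`
#'   (`volume_grid`), `source = "synthetic"` and `stats` (regional percent
#'   means).
#' @export
sample_error_field <- function(template, institution, config, rng_seed,
                               map_id = NULL) {
  institution <- match.arg(institution, c("InA", "InB"))
  set.seed(rng_seed)
  g <- stats::rnorm(1, config$error_global_mean, config$error_between_map_sd)
  inbrain <- template$brain_mask$data > 0
  field <- array(1, template$grid_shape)
  r <- 0
  if (config$error_within_map_sd > 0) {
    rf <- volume_grid(array(stats::rnorm(prod(template$grid_shape)),
                            template$grid_shape),
                      template$voxel_size_mm, template$affine)
    rf <- gaussian_smooth(rf, config$error_field_fwhm_mm)
    rv <- rf$data[inbrain]
    rv <- rv - mean(rv)
    s <- stats::sd(rv)
    r <- array(0, template$grid_shape)
    r[inbrain] <- if (s > 0) rv * (config$error_within_map_sd / s) else 0
    r <- r[inbrain]
  }
  offs <- ifelse(template$ad_mask$data[inbrain] > 0,
                 config$error_ad_offset, config$error_nonad_offset)
  field[inbrain] <- 1 + g + r + offs
  field <- pmin(pmax(field, config$error_clip_range[1]),
                config$error_clip_range[2])
  fld <- volume_grid(field, template$voxel_size_mm, template$affine)
  new_error_map(map_id = map_id %||% sprintf("%s-seed%d", institution, rng_seed),
                institution = institution, field = fld,
                source = "synthetic", template = template)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate the full study inputs
#'
#' Subject cohort (48 NC + 59 AD + 96 MCI by default, the configured number
#' of MCI records flagged as 24-month converters), the normal reference
#' cohort, and the institution-tagged synthetic error maps — everything a
#' pure function of `(config, seed)`.
#'
#' @param config a `study_config`.
#' @param template optional pre-built `template_space` (defaults to the
#'   config geometry).
#' @return list with `template`, `subjects` (list of `list(record, volume)`),
#'   `subject_table` (data.frame), `reference`, `error_maps`.
#' @export
make_cohorts <- function(config, template = NULL) {
  if (is.null(template))
    template <- make_template(config$grid_shape, config$voxel_size_mm)

  # subjects
  set.seed(substream_seed(config$seed, "subjects"))
  groups <- c(rep("NC", config$n_nc), rep("AD", config$n_ad),
              rep("MCI", config$n_mci))
  conv <- rep(FALSE, length(groups))
  mci_idx <- which(groups == "MCI")
  conv[sample(mci_idx, config$n_mci_converters)] <- TRUE
  ages <- draw_ages(length(groups), config)
  vol_seeds <- sample.int(2^30, length(groups))
  subjects <- lapply(seq_along(groups), function(i) {
    rec <- subject_record(sprintf("S%03d", i), ages[i], groups[i],
                          converted_24mo = conv[i])
    list(record = rec,
         volume = sample_subject_volume(template, rec, config, vol_seeds[i]))
  })

  reference <- build_reference_cohort(
    template, config, substream_seed(config$seed, "reference"))

  set.seed(substream_seed(config$seed, "errormaps"))
  inst <- c(rep("InA", config$n_error_maps_a),
            rep("InB", config$n_error_maps_b))
  map_seeds <- sample.int(2^30, length(inst))
  error_maps <- lapply(seq_along(inst), function(i)
    sample_error_field(template, inst[i], config, map_seeds[i],
                       map_id = sprintf("EM%02d-%s", i, inst[i])))

  subject_table <- data.frame(
    subject_id = vapply(subjects, function(s) s$record$subject_id, ""),
    age = vapply(subjects, function(s) s$record$age, 0),
    group = vapply(subjects, function(s) s$record$group, ""),
    converted_24mo = vapply(subjects, function(s) s$record$converted_24mo,
                            FALSE),
    institution = vapply(subjects, function(s) s$record$institution, ""),
    stringsAsFactors = FALSE)

  list(template = template, subjects = subjects,
       subject_table = subject_table, reference = reference,
       error_maps = error_maps)
}
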