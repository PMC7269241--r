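test_that("measured-pair error maps are ratios with a guarded denominator", {
  tpl <- tpl_small
  ctac <- smooth_phantom()
  mrac <- ctac
  expect_true(all(compute_error_map(mrac, ctac, tpl$brain_mask)$data == 1))

  mrac2 <- ctac; mrac2$data <- 0.97 * mrac2$data
  em <- compute_error_map(mrac2, ctac, tpl$brain_mask)
  inb <- tpl$brain_mask$data > 0 &
    ctac$data > 0.05 * mean(ctac$data[tpl$brain_mask$data > 0])
  expect_equal(unique(round(em$data[inb], 12)), 0.97)

  ctac3 <- ctac
  vox <- which(tpl$brain_mask$data > 0)[1]
  ctac3$data[vox] <- 0
  em3 <- compute_error_map(mrac2, ctac3, tpl$brain_mask)
  expect_equal(em3$data[vox], 1)
  n_low <- sum(tpl$brain_mask$data > 0 &
                 ctac3$data <= 0.05 * mean(ctac3$data[tpl$brain_mask$data > 0]))
  expect_identical(attr(em3, "n_excluded"), n_low)
  expect_gte(attr(em3, "n_excluded"), 1L)

  zero <- volume_grid(array(0, dim(ctac$data)), ctac$voxel_size_mm,
                      ctac$affine)
  expect_error(compute_error_map(mrac, zero, tpl$brain_mask), "mean")
})

test_that("normalization to template space preserves constants away from edges", {
  tpl <- tpl_small
  ones <- volume_grid(array(1, tpl$grid_shape), tpl$voxel_size_mm, tpl$affine)
  em <- normalize_error_map(ones, identity_transform(), tpl, fwhm_mm = 12)
  expect_lt(max(abs(em$field$data - 1)), 1e-10)
  expect_equal(unname(em$stats), c(0, 0, 0), tolerance = 1e-8)

  const <- ones; const$data[] <- 0.95
  em2 <- normalize_error_map(const, identity_transform(), tpl, fwhm_mm = 12)
  # smoothing pulls edge voxels toward the outside fill value 1; evaluate
  # eroded interior (the deep core, well inside the brain)
  core <- tpl$brain_mask$data > 0 & tpl$region_labels$data == 0
  expect_lt(max(abs(em2$field$data[core] - 0.95)), 0.005)
  expect_equal(em2$source, "measured-pair")

  # stats stored on the map agree with an independent regional summary
  reg <- regional_error_summary(list(em2), tpl)
  expect_equal(unname(em2$stats["brain_pct"]), reg$per_map$brain_pct[1],
               tolerance = 1e-12)
})

test_that("imposing an error map multiplies voxel-wise and respects score invariances", {
  cfg <- cfg_small
  ref <- build_reference_cohort(tpl_small, cfg, 50)
  refn <- lapply(ref$volumes, function(v)
    intensity_normalize(gaussian_smooth(v, 12), tpl_small$preserved_mask)$volume)
  model <- fit_reference_model(refn, ref$ages, tpl_small$brain_mask)
  subj <- gaussian_smooth(
    sample_subject_volume(tpl_small, subject_record("s", 70, "AD"), cfg, 5),
    12)
  s_base <- score_subject(subj, 70, model, tpl_small, cfg,
                          already_normalized = TRUE)

  ones <- volume_grid(array(1, tpl_small$grid_shape), tpl_small$voxel_size_mm,
                      tpl_small$affine)
  expect_identical(apply_error(subj, ones)$data, subj$data)

  const <- ones; const$data[] <- 0.9
  s_const <- score_subject(apply_error(subj, const), 70, model, tpl_small,
                           cfg, already_normalized = TRUE)
  expect_equal(s_const$pet_score, s_base$pet_score, tolerance = 1e-12)

  # error < 1 confined to the AD mask raises the score
  admap <- ones
  admap$data[tpl_small$ad_mask$data > 0] <- 0.97
  s_ad <- score_subject(apply_error(subj, admap), 70, model, tpl_small,
                        cfg, already_normalized = TRUE)
  expect_gt(s_ad$pet_score, s_base$pet_score)

  small <- volume_grid(array(1, c(4, 4, 4)), c(5, 5, 5))
  expect_error(apply_error(subj, small), "mismatch")
})

test_that("the cross simulation has the right cardinality and matches the full scoring path", {
  cfg <- cfg_small
  coh <- make_cohorts(cfg)
  for (i in seq_along(coh$subjects))
    coh$subjects[[i]]$volume <- gaussian_smooth(coh$subjects[[i]]$volume, 12)
  refn <- lapply(coh$reference$volumes, function(v)
    intensity_normalize(gaussian_smooth(v, 12), tpl_small$preserved_mask)$volume)
  model <- fit_reference_model(refn, coh$reference$ages, tpl_small$brain_mask)
  tab <- run_cross_simulation(coh$subjects, coh$error_maps, model, tpl_small,
                              cfg)
  n_s <- length(coh$subjects); n_m <- length(coh$error_maps)
  expect_identical(nrow(tab), n_s * (n_m + 1L))
  expect_identical(sum(tab$error_map_id == "none"), n_s)

  # row-by-row equivalence with score_subject on the full volume
  for (j in c(1, 4)) for (i in c(1, 3)) {
    sub <- coh$subjects[[j]]
    em <- coh$error_maps[[i]]
    s <- score_subject(apply_error(sub$volume, em), sub$record$age, model,
                       tpl_small, cfg, already_normalized = TRUE)
    row <- tab[tab$subject_id == sub$record$subject_id &
                 tab$error_map_id == em$map_id, ]
    expect_equal(row$ad_t_sum, s$ad_t_sum, tolerance = 1e-9)
    expect_equal(row$pet_score, s$pet_score, tolerance = 1e-9)
    expect_equal(row$normalization_mean, s$normalization_mean,
                 tolerance = 1e-12)
  }

  # identity maps give exactly the baseline scores
  idmap <- coh$error_maps[[1]]
  idmap$field$data[] <- 1
  idmap$map_id <- "identity"
  tab_id <- run_cross_simulation(coh$subjects, list(idmap), model, tpl_small,
                                 cfg)
  d <- score_differences(tab_id)
  expect_true(all(d$per_row$score_diff == 0))

  # shuffling error-map order permutes rows only
  tab_shuf <- run_cross_simulation(coh$subjects, rev(coh$error_maps), model,
                                   tpl_small, cfg)
  key <- function(t) t[order(t$subject_id, t$error_map_id), ]
  a <- key(tab); b <- key(tab_shuf)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("preserved-region underestimation beyond the AD mask depresses scores of AD subjects", {
  cfg <- study_config(grid_shape = c(28L, 32L, 28L), voxel_size_mm = c(5, 5, 5),
                      n_nc = 1L, n_ad = 32L, n_mci = 1L, n_mci_converters = 0L,
                      n_error_maps_a = 1L, n_error_maps_b = 1L,
                      n_reference = 15L, seed = 31L)
  coh <- make_cohorts(cfg)
  for (i in seq_along(coh$subjects))
    coh$subjects[[i]]$volume <- gaussian_smooth(coh$subjects[[i]]$volume, 12)
  refn <- lapply(coh$reference$volumes, function(v)
    intensity_normalize(gaussian_smooth(v, 12), tpl_small$preserved_mask)$volume)
  model <- fit_reference_model(refn, coh$reference$ages, tpl_small$brain_mask)

  # deterministic map: preserved/non-AD error more negative than AD error
  fld <- volume_grid(array(1, tpl_small$grid_shape), tpl_small$voxel_size_mm,
                     tpl_small$affine)
  inb <- tpl_small$brain_mask$data > 0
  fld$data[inb] <- 1 - 0.0159
  fld$data[tpl_small$ad_mask$data > 0] <- 1 - 0.0086
  em <- list(map_id = "worstlike", institution = "InA", field = fld,
             source = "synthetic",
             stats = mracpet:::error_map_stats(fld, tpl_small))
  class(em) <- "error_map"

  ad_subj <- Filter(function(s) s$record$group == "AD", coh$subjects)
  tab <- run_cross_simulation(ad_subj, list(em), model, tpl_small, cfg)
  d <- score_differences(tab)
  expect_gte(length(d$per_row$score_diff), 30)
  # sign test: the underestimation direction dominates
  expect_lt(d$overall$mean, 0)
  expect_gt(mean(d$per_row$score_diff < 0, na.rm = TRUE), 0.75)
})
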