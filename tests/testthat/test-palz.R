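test_that("intensity normalization divides by the preserved-mask mean", {
  d <- c(24, 26, 24)
  tpl <- make_template(d, c(6, 6, 6))
  v <- smooth_phantom(tpl)
  n1 <- intensity_normalize(v, tpl$preserved_mask)
  # scale cancellation
  v2 <- v; v2$data <- v2$data * 41.5
  n2 <- intensity_normalize(v2, tpl$preserved_mask)
  expect_equal(n1$volume$data, n2$volume$data, tolerance = 1e-12)
  # constant volume
  const <- volume_grid(array(5, d), c(6, 6, 6))
  nc <- intensity_normalize(const, tpl$preserved_mask)
  expect_equal(nc$mean, 5)
  expect_true(all(nc$volume$data == 1))
  # two-voxel toy mask: divisor is the mask mean, 3
  toy <- volume_grid(array(c(2, 4, 7, 9, rep(1, prod(d) - 4)), d), c(6, 6, 6))
  mask <- volume_grid(array(c(1, 1, rep(0, prod(d) - 2)), d), c(6, 6, 6))
  nt <- intensity_normalize(toy, mask)
  expect_equal(nt$mean, 3)
  expect_equal(nt$volume$data[1:2], c(2 / 3, 4 / 3))
  # degenerate image
  zero <- volume_grid(array(0, d), c(6, 6, 6))
  expect_error(intensity_normalize(zero, tpl$preserved_mask), "degenerate")
})

test_that("voxel-wise regression matches a scalar least-squares oracle", {
  set.seed(8)
  d <- c(5, 5, 5)
  n <- 14
  ages <- runif(n, 55, 90)
  vols <- lapply(1:n, function(i)
    volume_grid(array(1 + 0.01 * rnorm(prod(d)) - 0.004 * (ages[i] - 70), d),
                c(4, 4, 4)))
  mask <- volume_grid(array(1, d), c(4, 4, 4))
  model <- fit_reference_model(vols, ages, mask)
  expect_equal(model$n, n)
  expect_equal(model$mean_age, mean(ages))
  expect_equal(model$age_ssq, sum((ages - mean(ages))^2))
  vox <- sample(prod(d), 10)
  for (v in vox) {
    y <- vapply(vols, function(vv) vv$data[v], 0)
    fit <- stats::lm(y ~ ages)
    expect_equal(model$intercept[v], unname(coef(fit)[1]), tolerance = 1e-10)
    expect_equal(model$slope[v], unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(model$residual_sd[v],
                 sqrt(sum(resid(fit)^2) / (n - 2)), tolerance = 1e-10)
  }
  expect_error(fit_reference_model(vols[1:2], ages[1:2], mask), ">= 10")
  expect_error(fit_reference_model(vols, rep(70, n), mask), "degenerate")
})

test_that("the t-map equals the prediction-interval formula, hand value and oracle", {
  # single-voxel toy model: t = (1 - 0.8) / (0.1 sqrt(1 + 1/12)) = 1.9215
  d <- c(3, 3, 3)
  mask <- volume_grid(array(c(1, rep(0, 26)), d), c(4, 4, 4))
  model <- structure(list(intercept = 1, slope = 0, residual_sd = 0.1,
                          mask = mask, mask_idx = 1L, n = 12,
                          mean_age = 70, age_ssq = 1000, grid_shape = d),
                     class = "reference_model")
  u <- volume_grid(array(c(0.8, rep(0, 26)), d), c(4, 4, 4))
  tm <- t_map(u, 70, model)
  expect_equal(tm$data[1], 0.2 / (0.1 * sqrt(1 + 1 / 12)), tolerance = 1e-12)
  expect_equal(tm$data[1], 1.92154, tolerance = 1e-5)
  # residual-denominator variant drops the inflation
  tm2 <- t_map(u, 70, model, t_denominator = "residual")
  expect_equal(tm2$data[1], 2, tolerance = 1e-12)
  # age term enters through the prediction interval
  tm3 <- t_map(u, 80, model)
  expect_equal(tm3$data[1], 0.2 / (0.1 * sqrt(1 + 1 / 12 + 100 / 1000)),
               tolerance = 1e-12)

  # full 5^3-grid oracle: independent per-voxel regression + prediction band
  set.seed(9)
  d5 <- c(5, 5, 5); n <- 12
  ages <- runif(n, 55, 90)
  vols <- lapply(1:n, function(i)
    volume_grid(array(rnorm(prod(d5), 1, 0.05), d5), c(4, 4, 4)))
  mask5 <- volume_grid(array(1, d5), c(4, 4, 4))
  model5 <- fit_reference_model(vols, ages, mask5)
  newv <- volume_grid(array(rnorm(prod(d5), 0.95, 0.05), d5), c(4, 4, 4))
  age_new <- 71.3
  tm5 <- t_map(newv, age_new, model5)
  oracle <- vapply(seq_len(prod(d5)), function(v) {
    y <- vapply(vols, function(vv) vv$data[v], 0)
    fit <- stats::lm(y ~ ages)
    s <- sqrt(sum(resid(fit)^2) / (n - 2))
    pred <- sum(coef(fit) * c(1, age_new))
    xb <- mean(ages); sxx <- sum((ages - xb)^2)
    (pred - newv$data[v]) / (s * sqrt(1 + 1 / n + (age_new - xb)^2 / sxx))
  }, 0)
  expect_equal(as.numeric(tm5$data), oracle, tolerance = 1e-10)

  # zero-residual input gives an all-zero map; hypometabolism gives t > 0
  exactv <- volume_grid(array(model5$intercept + model5$slope * age_new, d5),
                        c(4, 4, 4))
  expect_lt(max(abs(t_map(exactv, age_new, model5)$data)), 1e-10)
  lower <- exactv; lower$data <- lower$data - 0.02
  expect_true(all(t_map(lower, age_new, model5)$data > 0))
})

test_that("the AD t-sum is the signed masked sum, with optional clipping", {
  d <- c(6, 6, 6)
  mask <- volume_grid(array(rep(c(1, 0), 108), d), c(4, 4, 4))
  zero <- volume_grid(array(0, d), c(4, 4, 4))
  expect_equal(ad_t_sum(zero, mask), 0)
  ones <- volume_grid(array(1, d), c(4, 4, 4))
  expect_equal(ad_t_sum(ones, mask), sum(mask$data))
  set.seed(3)
  rnd <- volume_grid(array(rnorm(prod(d)), d), c(4, 4, 4))
  expect_equal(ad_t_sum(rnd, mask), sum(rnd$data[mask$data > 0]),
               tolerance = 1e-12)
  expect_equal(ad_t_sum(rnd, mask, clip_negative = TRUE),
               sum(pmax(rnd$data[mask$data > 0], 0)), tolerance = 1e-12)
  empty <- volume_grid(array(0, d), c(4, 4, 4))
  expect_error(ad_t_sum(rnd, empty), "empty")
})

test_that("the PET-score transform hits its landmark values and domain bound", {
  expect_equal(pet_score(11089), 1.0)
  expect_equal(pet_score(0), 0.0)
  expect_equal(pet_score(3 * 11089), 2.0)
  expect_error(pet_score(-11089), "not positive")
  expect_error(pet_score(-20000), "not positive")
})

test_that("scoring is scale invariant, self-consistent and ordered by disease effect", {
  # noise-free self-consistency: intensity normalization removes the global
  # age factor, so every reference is identical and an NC subject scores 0
  ref0 <- build_reference_cohort(tpl_small, cfg_noise_free, 50)
  refn0 <- lapply(ref0$volumes, function(v)
    intensity_normalize(gaussian_smooth(v, 12), tpl_small$preserved_mask)$volume)
  model0 <- fit_reference_model(refn0, ref0$ages, tpl_small$brain_mask)
  nc0 <- sample_subject_volume(tpl_small, subject_record("nc", 72.5, "NC"),
                               cfg_noise_free, 1)
  s0 <- score_subject(nc0, 72.5, model0, tpl_small, cfg_noise_free)
  expect_lt(abs(s0$ad_t_sum), 1e-6)
  expect_lt(abs(s0$pet_score), 1e-9)

  # noisy model for the non-degenerate checks
  ref <- build_reference_cohort(tpl_small, cfg_small, 50)
  refn <- lapply(ref$volumes, function(v)
    intensity_normalize(gaussian_smooth(v, 12), tpl_small$preserved_mask)$volume)
  model <- fit_reference_model(refn, ref$ages, tpl_small$brain_mask)

  nc_vol <- sample_subject_volume(tpl_small, subject_record("nc", 72.5, "NC"),
                                  cfg_small, 1)
  s_nc <- score_subject(nc_vol, 72.5, model, tpl_small, cfg_small)
  expect_gt(abs(s_nc$ad_t_sum), 0)    # non-degenerate score

  scaled <- nc_vol; scaled$data <- scaled$data * 3.7
  s_sc <- score_subject(scaled, 72.5, model, tpl_small, cfg_small)
  expect_equal(s_sc$pet_score, s_nc$pet_score, tolerance = 1e-12)
  expect_equal(s_sc$normalization_mean, s_nc$normalization_mean * 3.7,
               tolerance = 1e-12)

  ad_vol <- sample_subject_volume(tpl_small, subject_record("ad", 72.5, "AD"),
                                  cfg_small, 1)
  s_ad <- score_subject(ad_vol, 72.5, model, tpl_small, cfg_small)
  expect_gt(s_ad$pet_score, s_nc$pet_score)
})

test_that("reducing uptake only inside the AD mask never decreases the t-sum", {
  set.seed(10)
  d5 <- c(5, 5, 5); n <- 12
  ages <- runif(n, 55, 90)
  vols <- lapply(1:n, function(i)
    volume_grid(array(rnorm(prod(d5), 1, 0.05), d5), c(4, 4, 4)))
  mask5 <- volume_grid(array(1, d5), c(4, 4, 4))
  model5 <- fit_reference_model(vols, ages, mask5)
  admask <- volume_grid(array(rep(c(1, 0, 0, 0, 0), 25), d5), c(4, 4, 4))
  base <- volume_grid(array(rnorm(prod(d5), 1, 0.03), d5), c(4, 4, 4))
  t0 <- ad_t_sum(t_map(base, 70, model5), admask)
  for (delta in c(0.01, 0.05, 0.2)) {
    low <- base
    low$data[admask$data > 0] <- low$data[admask$data > 0] - delta
    t1 <- ad_t_sum(t_map(low, 70, model5), admask)
    expect_gte(t1, t0)
  }
})

test_that("AD and NC synthetic groups separate by more than 3 pooled standard errors", {
  cfg <- study_config(grid_shape = c(24L, 26L, 24L), voxel_size_mm = c(6, 6, 6),
                      n_nc = 40L, n_ad = 40L, n_mci = 1L, n_mci_converters = 0L,
                      n_error_maps_a = 1L, n_error_maps_b = 1L,
                      n_reference = 20L, seed = 77L)
  res <- run_study(cfg, quiet = TRUE)
  base <- merge(res$score_table[res$score_table$error_map_id == "none", ],
                res$subject_table)
  ad <- base$pet_score[base$group == "AD"]
  nc <- base$pet_score[base$group == "NC"]
  pooled_se <- sqrt(var(ad) / length(ad) + var(nc) / length(nc))
  expect_gt(mean(ad) - mean(nc), 3 * pooled_se)
})
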