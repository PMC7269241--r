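# Shared small fixtures, built once per test run.

tpl_small <- make_template(c(28, 32, 28), c(5, 5, 5))

cfg_small <- study_config(grid_shape = c(28L, 32L, 28L),
                          voxel_size_mm = c(5, 5, 5),
                          n_nc = 6L, n_ad = 6L, n_mci = 8L,
                          n_mci_converters = 3L,
                          n_error_maps_a = 2L, n_error_maps_b = 3L,
                          n_reference = 12L, seed = 11L)

cfg_noise_free <- study_config(grid_shape = c(28L, 32L, 28L),
                               voxel_size_mm = c(5, 5, 5),
                               voxel_noise_sd = 0, seed = 11L)

# A smooth structured phantom volume for registration/resampling tests.
smooth_phantom <- function(template = tpl_small, fwhm = 8) {
  cfg <- study_config(grid_shape = template$grid_shape,
                      voxel_size_mm = template$voxel_size_mm,
                      voxel_noise_sd = 0)
  gaussian_smooth(
    sample_subject_volume(template, subject_record("ph", 70, "NC"), cfg, 1),
    fwhm)
}

# Maximum world-space displacement (mm) of composed transform A %*% B over
# the brain-mask voxels of a template: the registration-recovery metric.
composed_deviation_mm <- function(mat_a, mat_b, template) {
  comp <- mat_a %*% mat_b
  idx <- which(template$brain_mask$data > 0, arr.ind = TRUE) - 1
  w <- template$affine[1:3, 1:3] %*% t(idx) + template$affine[1:3, 4]
  dev <- comp[1:3, 1:3] %*% w + comp[1:3, 4] - w
  max(sqrt(colSums(dev^2)))
}

# Phantom with asymmetric landmarks: a symmetric smooth ellipsoid is nearly
# rotation-degenerate, so registration accuracy is probed on an image with
# off-centre bumps (as a real brain's asymmetric features would provide).
registration_phantom <- function(template = tpl_small) {
  v <- smooth_phantom(template)
  aff <- template$affine
  gs <- template$grid_shape
  ii <- seq_len(gs[1]) - 1; jj <- seq_len(gs[2]) - 1; kk <- seq_len(gs[3]) - 1
  wx <- array(aff[1, 1] * ii + aff[1, 4], gs)
  wy <- array(rep(aff[2, 2] * jj + aff[2, 4], each = gs[1]), gs)
  wz <- array(rep(aff[3, 3] * kk + aff[3, 4], each = gs[1] * gs[2]), gs)
  bumps <- list(c(25, 12, -14, 9, 0.7), c(-16, 32, 6, 11, 0.5),
                c(6, -28, 22, 8, 0.8), c(-30, -8, -22, 10, 0.6))
  for (b in bumps)
    v$data <- v$data + b[5] *
      exp(-((wx - b[1])^2 + (wy - b[2])^2 + (wz - b[3])^2) / (2 * b[4]^2))
  v
}

# Register `n` random rigid+scale perturbations of a phantom and return the
# composed deviations in voxel units.
registration_recovery_errors <- function(n, seed = 3) {
  vol <- registration_phantom()
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    tr_p <- make_affine_transform(
      translation = stats::runif(3, -10, 10),
      rotation = stats::runif(3, -10, 10) * pi / 180,
      scale = 1 + stats::runif(3, -0.05, 0.05))
    mov <- resample(vol, tr_p)
    tr_r <- affine_register(mov, vol, dof = 9)
    composed_deviation_mm(tr_p$matrix, tr_r$matrix, tpl_small) /
      min(tpl_small$voxel_size_mm)
  }, numeric(1))
}

# The full default-scale study (203 subjects x 47 maps), computed once and
# shared by the acceptance tests.
.study_env <- new.env(parent = emptyenv())
default_study <- function() {
  if (is.null(.study_env$res))
    .study_env$res <- run_study(study_config(seed = 1L), quiet = TRUE)
  .study_env$res
}
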