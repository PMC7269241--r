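#' Build the template space phantom
#'
#' Constructs a deterministic geometric phantom standing in for a PET brain
#' template: an ellipsoidal brain with a low-uptake deep core, a cortical
#' shell split into AD-related and non-AD regions, a superior/central
#' AD-preserved patch used for intensity normalization, and an inferior
#' infratentorial blob (also preserved in AD, so part of the normalization
#' region). The AD-related patches are bilateral posterior/lateral and sized
#' to occupy roughly 30% of the brain mask, the proportion at which the
#' calibrated regional error offsets are mutually consistent with the
#' whole-brain error level.
#'
#' Region labels: 0 background (and deep core inside the brain), 1 non-AD
#' cortex, 2 AD-related cortex, 3 preserved patch, 4 infratentorial.
#' `preserved_mask` is labels {3, 4}; `ad_mask` is label 2.
#'
#' @param grid_shape integer length-3, each >= 24.
#' @param voxel_size_mm numeric length-3, each in [1, 6] mm.
#' @return a `template_space`: list with `grid_shape`, `voxel_size_mm`,
#'   `affine`, `brain_mask`, `ad_mask`, `preserved_mask`, `region_labels`
#'   (all masks are `volume_grid`s).
#' @export
make_template <- function(grid_shape = c(46L, 55L, 46L),
                          voxel_size_mm = c(4, 4, 4)) {
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(grid_shape < 24L))
    stop("make_template: grid_shape must be >= 24 in every axis")
  if (any(voxel_size_mm < 1 | voxel_size_mm > 6))
    stop("make_template: voxel sizes must lie in [1, 6] mm")

  ctr <- (grid_shape - 1) / 2
  semi <- 0.40 * grid_shape              # ellipsoid semi-axes, voxel units
  z1 <- (seq_len(grid_shape[1]) - 1 - ctr[1]) / semi[1]
  z2 <- (seq_len(grid_shape[2]) - 1 - ctr[2]) / semi[2]
  z3 <- (seq_len(grid_shape[3]) - 1 - ctr[3]) / semi[3]
  Z1 <- array(z1, grid_shape)
  Z2 <- array(rep(z2, each = grid_shape[1]), grid_shape)
  Z3 <- array(rep(z3, each = grid_shape[1] * grid_shape[2]), grid_shape)
  r2 <- Z1^2 + Z2^2 + Z3^2

  brain <- r2 <= 1
  infra <- brain & Z3 <= -0.55
  preserved_patch <- brain & !infra & Z3 >= 0.30 & (Z1^2 + Z2^2) <= 0.09
  core <- brain & !infra & !preserved_patch & r2 <= 0.45^2
  ad <- brain & !infra & !preserved_patch & !core &
    Z3 > -0.55 & Z3 <= 0.70 &
    (Z2 >= 0.40 | abs(Z1) >= 0.70)

  labels <- array(0L, grid_shape)
  labels[brain & !core] <- 1L
  labels[ad] <- 2L
  labels[preserved_patch] <- 3L
  labels[infra] <- 4L

  # smoothing headroom: every brain voxel >= 2 voxel layers from the edge
  idx <- which(brain, arr.ind = TRUE)
  margin <- min(idx - 1, sweep(-idx, 2, grid_shape, `+`))
  if (margin < 2)
    stop("make_template: brain mask within 2 voxels of the grid boundary ",
         "(margin = ", margin, "); enlarge the grid")
  for (m in list(ad, preserved_patch | infra)) {
    if (sum(m) < 100)
      stop("make_template: region with ", sum(m),
           " voxels (< 100); enlarge the grid or reduce voxel size")
  }

  as_mask <- function(m) volume_grid(array(as.numeric(m), grid_shape),
                                     voxel_size_mm)
  structure(list(
    grid_shape = grid_shape,
    voxel_size_mm = voxel_size_mm,
    affine = centered_affine(grid_shape, voxel_size_mm),
    brain_mask = as_mask(brain),
    ad_mask = as_mask(ad),
    preserved_mask = as_mask(preserved_patch | infra),
    region_labels = volume_grid(array(as.numeric(labels), grid_shape),
                                voxel_size_mm)
  ), class = "template_space")
}

#' @export
print.template_space <- function(x, ...) {
  nb <- sum(x$brain_mask$data)
  cat("<template_space> ", paste(x$grid_shape, collapse = "x"), " @ ",
      paste(format(x$voxel_size_mm), collapse = "x"), " mm\n", sep = "")
  cat(sprintf("  brain %d voxels; AD-related %d (%.1f%% of brain); preserved %d\n",
              nb, sum(x$ad_mask$data), 100 * sum(x$ad_mask$data) / nb,
              sum(x$preserved_mask$data)))
  invisible(x)
}

# Empty volume on the template grid.
template_volume <- function(template, fill = 0) {
  volume_grid(array(fill, template$grid_shape), template$voxel_size_mm,
              template$affine)
}
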