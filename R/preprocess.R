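#' Convert Gaussian FWHM to sigma
#'
#' @param fwhm_mm full width at half maximum, > 0.
#' @return sigma = fwhm / (2 sqrt(2 ln 2)).
#' @export
fwhm_to_sigma <- function(fwhm_mm) {
  if (any(fwhm_mm <= 0)) stop("fwhm_to_sigma: fwhm must be positive")
  fwhm_mm / (2 * sqrt(2 * log(2)))
}

# Normalized 1D Gaussian kernel sampled at integer voxel offsets.
gauss_kernel_1d <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  w <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  w / sum(w)
}

# 1D convolution along the first array axis with nearest-edge replication,
# implemented as a weighted sum of row-shifted copies.
convolve_axis1 <- function(a, w) {
  d <- dim(a)
  n <- d[1]
  r <- (length(w) - 1L) %/% 2L
  pad_idx <- c(rep(1L, r), seq_len(n), rep(n, r))
  m <- matrix(a, nrow = n)[pad_idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(w))
    out <- out + w[j] * m[j:(j + n - 1L), , drop = FALSE]
  array(out, d)
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian convolution with the kernel width specified as FWHM in
#' millimetres (the convention of PET analysis software); per-axis sigma in
#' voxel units is derived from the voxel size. Boundary handling is
#' nearest-edge replication. `fwhm_mm = 0` is the identity.
#'
#' @param volume a `volume_grid`.
#' @param fwhm_mm scalar or length-3 FWHM in mm, >= 0.
#' @return a `volume_grid` on the same grid.
#' @export
gaussian_smooth <- function(volume, fwhm_mm) {
  fwhm_mm <- rep_len(fwhm_mm, 3L)
  if (any(fwhm_mm < 0)) stop("gaussian_smooth: fwhm must be >= 0")
  if (all(fwhm_mm == 0)) return(volume)
  sigma_vox <- ifelse(fwhm_mm > 0,
                      fwhm_to_sigma(pmax(fwhm_mm, 1e-12)) / volume$voxel_size_mm,
                      0)
  a <- volume$data
  for (ax in 1:3) {
    if (sigma_vox[ax] <= 0) next
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    inv <- order(perm)
    a <- aperm(convolve_axis1(aperm(a, perm), gauss_kernel_1d(sigma_vox[ax])),
               inv)
  }
  out <- volume
  out$data <- a
  out
}

#' Build an affine transform from parameters
#'
#' Composes translation, rotation (about x, y, z in radians), anisotropic
#' scale and shear about a centre point in world coordinates:
#' `M = T(centre) T(translation) Rz Ry Rx S Shear T(-centre)`.
#' The transform maps fixed-space world points to moving-space world points
#' (the pull-back convention used by [resample()]).
#'
#' @param translation,rotation,scale,shear numeric length-3 each.
#' @param center world point the linear part acts about.
#' @return an `affine_transform`: list with `matrix` (4x4) and the
#'   parameters.
#' @export
make_affine_transform <- function(translation = c(0, 0, 0),
                                  rotation = c(0, 0, 0),
                                  scale = c(1, 1, 1),
                                  shear = c(0, 0, 0),
                                  center = c(0, 0, 0)) {
  cx <- cos(rotation[1]); sx <- sin(rotation[1])
  cy <- cos(rotation[2]); sy <- sin(rotation[2])
  cz <- cos(rotation[3]); sz <- sin(rotation[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  S <- diag(scale)
  Sh <- diag(3); Sh[1, 2] <- shear[1]; Sh[1, 3] <- shear[2]; Sh[2, 3] <- shear[3]
  L <- Rz %*% Ry %*% Rx %*% S %*% Sh
  if (det(L) <= 0)
    stop("make_affine_transform: linear part must have positive determinant")
  m <- diag(4)
  m[1:3, 1:3] <- L
  m[1:3, 4] <- translation + center - L %*% center
  structure(list(matrix = m, translation = translation, rotation = rotation,
                 scale = scale, shear = shear, center = center),
            class = "affine_transform")
}

#' @rdname make_affine_transform
#' @export
identity_transform <- function() make_affine_transform()

transform_matrix <- function(transform) {
  if (inherits(transform, "affine_transform")) transform$matrix
  else as.matrix(transform)
}

#' Resample a volume onto a target grid
#'
#' Pull-back trilinear interpolation: each target voxel centre is mapped
#' through `transform` (fixed world -> moving world) into the source volume
#' and interpolated. Out-of-field voxels are set to 0.
#'
#' @param volume source `volume_grid`.
#' @param transform an `affine_transform` or 4x4 matrix.
#' @param target_template a `template_space` or `volume_grid` defining the
#'   output grid; defaults to the source grid.
#' @return a `volume_grid` on the target grid.
#' @export
resample <- function(volume, transform = identity_transform(),
                     target_template = NULL) {
  m <- transform_matrix(transform)
  if (abs(det(m)) < 1e-12) stop("resample: singular transform")
  if (is.null(target_template)) {
    tgt_shape <- dim(volume$data); tgt_aff <- volume$affine
    tgt_vox <- volume$voxel_size_mm
  } else if (inherits(target_template, "template_space")) {
    tgt_shape <- target_template$grid_shape; tgt_aff <- target_template$affine
    tgt_vox <- target_template$voxel_size_mm
  } else {
    tgt_shape <- dim(target_template$data); tgt_aff <- target_template$affine
    tgt_vox <- target_template$voxel_size_mm
  }
  world <- grid_world_coords(tgt_shape, tgt_aff)
  src_world <- m[1:3, 1:3] %*% world + m[1:3, 4]
  src_aff_inv <- solve(volume$affine)
  src_idx <- src_aff_inv[1:3, 1:3] %*% src_world + src_aff_inv[1:3, 4]

  d <- dim(volume$data)
  x <- src_idx[1, ]; y <- src_idx[2, ]; z <- src_idx[3, ]
  # snap coordinates that are integers up to rounding error, so identity and
  # whole-voxel translations reproduce grid samples exactly
  snap <- function(v) { r <- round(v); ifelse(abs(v - r) < 1e-9, r, v) }
  x <- snap(x); y <- snap(y); z <- snap(z)
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  valid <- x0 >= 0 & x0 <= d[1] - 1 & y0 >= 0 & y0 <= d[2] - 1 &
    z0 >= 0 & z0 <= d[3] - 1
  # voxels whose upper interpolation neighbour falls off the grid clamp to
  # the edge sample (consistent with half-open grids: exact boundary indices
  # interpolate to the boundary value)
  x1 <- pmin(x0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1)
  z1 <- pmin(z0 + 1, d[3] - 1)
  strict <- valid & x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 &
    z >= 0 & z <= d[3] - 1
  lin <- function(i, j, k) volume$data[1 + i + d[1] * (j + d[2] * k)]
  out <- numeric(length(x))
  v <- which(strict)
  if (length(v)) {
    i0 <- x0[v]; j0 <- y0[v]; k0 <- z0[v]
    i1 <- x1[v]; j1 <- y1[v]; k1 <- z1[v]
    gx <- fx[v]; gy <- fy[v]; gz <- fz[v]
    out[v] <-
      lin(i0, j0, k0) * (1 - gx) * (1 - gy) * (1 - gz) +
      lin(i1, j0, k0) * gx * (1 - gy) * (1 - gz) +
      lin(i0, j1, k0) * (1 - gx) * gy * (1 - gz) +
      lin(i1, j1, k0) * gx * gy * (1 - gz) +
      lin(i0, j0, k1) * (1 - gx) * (1 - gy) * gz +
      lin(i1, j0, k1) * gx * (1 - gy) * gz +
      lin(i0, j1, k1) * (1 - gx) * gy * gz +
      lin(i1, j1, k1) * gx * gy * gz
  }
  res <- volume_grid(array(out, tgt_shape), tgt_vox, tgt_aff)
  attr(res, "overlap_fraction") <- mean(strict)
  res
}

# MSE registration cost; large penalty when the volumes barely overlap so
# the optimizer is pushed back toward overlap.
register_cost <- function(par, moving, fixed, center, dof) {
  tr <- par_to_transform(par, center, dof)
  r <- resample(moving, tr, fixed)
  ov <- attr(r, "overlap_fraction")
  if (ov < 0.05) return(mean(fixed$data^2) + 10 * (0.05 - ov))
  mean((r$data - fixed$data)^2)
}

par_to_transform <- function(par, center, dof) {
  p <- c(par, rep(0, 12 - length(par)))
  make_affine_transform(translation = p[1:3], rotation = p[4:6],
                        scale = 1 + p[7:9], shear = p[10:12], center = center)
}

#' Affine registration by intensity
#'
#' Estimates the transform aligning `moving` to `fixed` by minimizing the
#' mean squared intensity difference of `moving` resampled onto the fixed
#' grid, with a coarse-to-fine strategy (smoothed/subsampled stage first,
#' staged degrees of freedom: translation, then rigid + scale, then the full
#' 12 parameters if requested). Mono-modal (same tracer/phantom) by design.
#'
#' @param moving,fixed `volume_grid`s overlapping in world space.
#' @param init optional initial parameter vector (length 12).
#' @param dof 6 (rigid), 9 (rigid + scale, default) or 12 (+ shear).
#' @param maxit optimizer iteration cap per stage.
#' @return an `affine_transform` with extra fields `converged`, `cost`,
#'   `overlap_fraction`.
#' @export
affine_register <- function(moving, fixed, init = NULL, dof = 9,
                            maxit = 400) {
  stopifnot(dof %in% c(6, 9, 12))
  center <- as.numeric(fixed$affine %*% c((dim(fixed$data) - 1) / 2, 1))[1:3]
  par <- if (is.null(init)) rep(0, 12) else rep_len(init, 12)
  # volumes that share no world extent at the starting transform violate the
  # overlap precondition; the result is still computed but never claimed
  # converged
  init_overlap <- attr(resample(moving, par_to_transform(par, center, dof),
                                fixed), "overlap_fraction")
  if (is.null(init)) {
    # centroid pre-alignment: initial translation from the intensity
    # centres of mass (pull-back: fixed centroid maps to moving centroid)
    centroid <- function(v) {
      m <- pmax(as.numeric(v$data), 0)
      as.numeric(grid_world_coords(dim(v$data), v$affine) %*% m / sum(m))
    }
    par[1:3] <- centroid(moving) - centroid(fixed)
  }

  # coarse level: smooth and sample on a 2x coarser grid
  coarse_tpl <- volume_grid(
    array(0, pmax(4L, dim(fixed$data) %/% 2L)),
    fixed$voxel_size_mm * 2,
    {a <- fixed$affine; a[1:3, 1:3] <- a[1:3, 1:3] * 2; a})
  fix_c <- resample(gaussian_smooth(fixed, 2 * fixed$voxel_size_mm),
                    identity_transform(), coarse_tpl)
  mov_c <- gaussian_smooth(moving, 2 * moving$voxel_size_mm)
  scales <- c(1, 1, 1, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02)

  run_stage <- function(par, np, mov, fix) {
    fn <- function(p) {
      par2 <- par; par2[seq_len(np)] <- p
      register_cost(par2, mov, fix, center, dof)
    }
    o <- stats::optim(par[seq_len(np)], fn, method = "Nelder-Mead",
                      control = list(maxit = maxit,
                                     parscale = scales[seq_len(np)],
                                     reltol = 1e-9))
    par[seq_len(np)] <- o$par
    list(par = par, cost = o$value)
  }

  s1 <- run_stage(par, 3, mov_c, fix_c)
  s2 <- run_stage(s1$par, min(dof, 9), mov_c, fix_c)
  # near-symmetric objects admit local minima several degrees off; when the
  # coarse fit is poor, retry from deterministic rotation offsets
  if (s2$cost > 2e-3 * mean(fix_c$data^2)) {
    jit <- 7 * pi / 180
    for (axis in 1:3) for (sgn in c(-1, 1)) {
      pj <- s1$par
      pj[3 + axis] <- pj[3 + axis] + sgn * jit
      cand <- run_stage(pj, min(dof, 9), mov_c, fix_c)
      if (cand$cost < s2$cost) s2 <- cand
    }
  }
  s3 <- run_stage(s2$par, dof, moving, fixed)
  # fresh-simplex restart at full resolution polishes a stalled simplex
  s4 <- run_stage(s3$par, dof, moving, fixed)
  par <- s4$par
  cost <- s4$cost
  tr <- par_to_transform(par[seq_len(dof)], center, dof)
  final <- resample(moving, tr, fixed)
  ov <- attr(final, "overlap_fraction")
  base_cost <- mean(fixed$data^2)
  tr$converged <- init_overlap > 0 && ov > 0.5 && is.finite(cost) &&
    cost < 0.5 * base_cost
  tr$cost <- cost
  tr$overlap_fraction <- ov
  tr
}
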