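#' Volumetric image on a fixed lattice
#'
#' A `volume_grid` is the universal carrier for PET images, error maps and
#' masks: a 3D numeric array plus a 4x4 RAS+ affine mapping 0-based voxel
#' indices to world millimetres.
#'
#' @param data 3D numeric array.
#' @param voxel_size_mm numeric length-3, voxel edge lengths in mm.
#' @param affine optional 4x4 matrix; defaults to a diagonal affine with the
#'   world origin at the grid centre.
#' @return an object of class `volume_grid` with elements `data`, `affine`
#'   and `voxel_size_mm`.
#' @export
volume_grid <- function(data, voxel_size_mm, affine = NULL) {
  if (length(dim(data)) != 3L)
    stop("volume_grid: `data` must be a 3D array, got ",
         length(dim(data)), " dimensions")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(voxel_size_mm <= 0)) stop("volume_grid: voxel sizes must be positive")
  if (is.null(affine)) affine <- centered_affine(dim(data), voxel_size_mm)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("volume_grid: affine must be 4x4")
  if (!all(is.finite(data))) stop("volume_grid: non-finite voxel values")
  structure(list(data = data, affine = affine, voxel_size_mm = voxel_size_mm),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(dim(x$data), collapse = "x"),
      " @ ", paste(format(x$voxel_size_mm), collapse = "x"), " mm\n", sep = "")
  cat("  range [", format(min(x$data)), ", ", format(max(x$data)), "]\n",
      sep = "")
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

# Diagonal RAS+ affine with the world origin at the geometric grid centre.
centered_affine <- function(grid_shape, voxel_size_mm) {
  aff <- diag(c(voxel_size_mm, 1))
  aff[1:3, 4] <- -voxel_size_mm * (grid_shape - 1) / 2
  aff
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$affine - b$affine)) < 1e-6
}

stop_grid_mismatch <- function(a, b, what) {
  stop(what, ": grid mismatch (",
       paste(dim(a$data), collapse = "x"), " vs ",
       paste(dim(b$data), collapse = "x"), ")")
}

#' Mask a volume
#'
#' Sets voxels outside `mask` to `fill`. The brain mask is applied to error
#' maps with `fill = 1` (no error outside the brain) and to PET images with
#' `fill = 0`.
#'
#' @param volume,mask `volume_grid`s on the same grid; `mask` is 0/1 or
#'   logical.
#' @param fill value placed outside the mask.
#' @return a `volume_grid`.
#' @export
apply_mask <- function(volume, mask, fill = 0) {
  if (!same_grid(volume, mask)) stop_grid_mismatch(volume, mask, "apply_mask")
  out <- volume
  out$data[!(mask$data > 0)] <- fill
  out
}

# Spatial mean of a volume over a binary mask.
mask_mean <- function(volume, mask) {
  keep <- mask$data > 0
  if (!any(keep)) stop("mask_mean: empty mask")
  mean(volume$data[keep])
}

# World coordinates (3 x N) of all voxel centres of a grid, 0-based indices.
grid_world_coords <- function(grid_shape, affine) {
  ii <- seq_len(grid_shape[1]) - 1
  jj <- seq_len(grid_shape[2]) - 1
  kk <- seq_len(grid_shape[3]) - 1
  idx <- rbind(rep(ii, times = grid_shape[2] * grid_shape[3]),
               rep(rep(jj, each = grid_shape[1]), times = grid_shape[3]),
               rep(kk, each = grid_shape[1] * grid_shape[2]))
  affine[1:3, 1:3] %*% idx + affine[1:3, 4]
}
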