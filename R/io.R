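#' Read / write volumes as NIfTI-1
#'
#' `write_volume` stores the array as float32 with the affine in both qform
#' and sform (code 2); `read_volume` accepts `.nii` and `.nii.gz` and
#' requires a 3D payload. Data and affine round-trip bit-exactly for
#' float32 payloads.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param volume a `volume_grid`.
#' @return `read_volume` returns a `volume_grid`; `write_volume` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("read_volume: expected a 3D volume, got ", length(d),
         " dimensions in ", path)
  aff <- RNifti::xform(img)
  volume_grid(array(as.numeric(img), d),
              voxel_size_mm = RNifti::pixdim(img)[1:3],
              affine = matrix(as.numeric(aff), 4, 4))
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$voxel_size_mm
  RNifti::qform(img) <- structure(volume$affine, code = 2L)
  RNifti::sform(img) <- structure(volume$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Serialize an affine transform to a JSON sidecar
#'
#' @param transform an `affine_transform` or 4x4 matrix.
#' @param path JSON file path.
#' @return `read_transform` returns an `affine_transform` (matrix-only if
#'   parameters were not stored); `write_transform` returns `path`
#'   invisibly.
#' @export
write_transform <- function(transform, path) {
  m <- transform_matrix(transform)
  jsonlite::write_json(list(matrix = m), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  m <- jsonlite::fromJSON(path)$matrix
  structure(list(matrix = matrix(as.numeric(m), 4, 4)),
            class = "affine_transform")
}
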