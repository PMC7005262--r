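#' Rotate a cubic volume about its centre
#'
#' Trilinear-interpolated rotation about the cube centre voxel
#' (0-based index `floor(N/2)` on each axis), zero fill outside the grid.
#' `rotate_volume(v, e)` moves features *by* the rotation `euler_to_matrix(e)`:
#' the output at position `x` samples the input at `R^-1 (x - c) + c`.
#'
#' @param vol 3D numeric array.
#' @param rotation Euler triplet (ZYZ intrinsic, degrees) or 3x3 rotation
#'   matrix.
#' @param shift optional length-3 translation in voxels applied after the
#'   rotation (features move by `+shift`).
#' @return rotated 3D array of the same dimensions.
#' @export
rotate_volume <- function(vol, rotation, shift = c(0, 0, 0)) {
  stopifnot(is.array(vol), length(dim(vol)) == 3)
  R <- if (is.matrix(rotation)) rotation else euler_to_matrix(rotation)
  d <- dim(vol)
  ctr <- centre_voxel(d)
  if (identical(unname(R), diag(3)) && all(shift == 0)) return(vol)
  out <- .resample_affine(as.numeric(vol), d, d, t(R), ctr, ctr, -t(R) %*% shift)
  array(out, d)
}

# out(x) = vol(A (x - c) + c); A need not be a rotation (used by WBP)
affine_resample <- function(vol, A, t = c(0, 0, 0)) {
  d <- dim(vol)
  ctr <- centre_voxel(d)
  array(.resample_affine(as.numeric(vol), d, d, A, ctr, ctr, t), d)
}
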