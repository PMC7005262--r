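#' Fourier-space missing-wedge mask
#'
#' Binary mask of Fourier coefficients sampled by a single-axis tilt series
#' with tilt axis y and beam along z. A coefficient with normalised
#' frequencies `(kx, ky, kz)` is sampled iff `|kz| <= |kx| * tan(max_angle)`
#' (the central-slice union of all tilts); the complementary double cone
#' about kz is the missing wedge. `max_angle = 90` samples everything.
#'
#' @param dims length-3 grid dimensions.
#' @param max_angle maximum tilt in degrees, in (0, 90].
#' @return logical 3D array, TRUE where sampled (in unshifted FFT layout).
#' @export
wedge_fourier_mask <- function(dims, max_angle) {
  stopifnot(max_angle > 0, max_angle <= 90)
  fidx <- function(n) {
    f <- seq_len(n) - 1
    ifelse(f > n / 2, f - n, f) / n
  }
  if (max_angle >= 90) return(array(TRUE, dims))
  kx <- fidx(dims[1])
  kz <- fidx(dims[3])
  ta <- tan(max_angle * pi / 180)
  m2 <- outer(abs(kx) * ta, abs(kz), ">=")      # nx x nz
  aperm(array(m2, c(dims[1], dims[3], dims[2])), c(1, 3, 2))
}

#' Degrade a volume with a single-axis missing wedge
#'
#' Zeroes all Fourier coefficients outside the double-cone sampled by the
#' tilt scheme (the fast degradation path; see [project_and_wbp()] for the
#' explicit projection route). Idempotent up to FFT round-off; output is
#' real-valued and carries the scheme as wedge metadata.
#'
#' @param vol a [tomogram_volume()].
#' @param scheme a [make_tilt_scheme()] with `max_angle <= 90`.
#' @return a `tomogram_volume` with the wedge applied.
#' @export
apply_missing_wedge <- function(vol, scheme) {
  stopifnot(inherits(vol, "tomogram_volume"), inherits(scheme, "tilt_scheme"))
  if (scheme$max_angle > 90) stop("max_angle must be <= 90")
  m <- wedge_fourier_mask(dim(vol$grid), scheme$max_angle)
  f <- stats::fft(vol$grid)
  f[!m] <- 0
  out <- Re(stats::fft(f, inverse = TRUE)) / length(f)
  tomogram_volume(array(out, dim(vol$grid)), vol$voxel_size,
                  origin = vol$origin, wedge = scheme)
}

# wedge mask for a volume's attached wedge metadata ("full" -> all TRUE)
volume_wedge_mask <- function(vol, dims = dim(vol$grid)) {
  if (identical(vol$wedge, "full")) array(TRUE, dims)
  else wedge_fourier_mask(dims, vol$wedge$max_angle)
}

#' Add white Gaussian noise at a target signal-to-noise ratio
#'
#' Additive zero-mean Gaussian noise with variance `var(signal)/snr`
#' (contrast-model-agnostic noise; no CTF).
#'
#' @param vol a [tomogram_volume()].
#' @param snr signal-to-noise variance ratio (> 0).
#' @param seed integer RNG seed for reproducibility.
#' @return a `tomogram_volume` with noise added.
#' @export
add_noise <- function(vol, snr, seed = 1) {
  stopifnot(inherits(vol, "tomogram_volume"))
  if (!is.numeric(snr) || snr <= 0) stop("snr must be > 0")
  sdv <- sqrt(stats::var(as.numeric(vol$grid)) / snr)
  set.seed(seed)
  g <- vol$grid + array(stats::rnorm(length(vol$grid), 0, sdv), dim(vol$grid))
  tomogram_volume(g, vol$voxel_size, origin = vol$origin, wedge = vol$wedge)
}
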