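#' Place a hexagonal receptor array on a membrane surface
#'
#' Generates ground-truth particle positions and orientations for a
#' chemoreceptor array. Two site conventions are supported:
#'
#' * `sites = "honeycomb"`: positions are trimer-of-dimer (ToD) symmetry
#'   axes, two per hexagonal unit cell; on a plane with `jitter_sd = 0` every
#'   interior site has exactly 3 nearest neighbours at `tod_spacing` and 6
#'   second-shell neighbours at `sqrt(3) * tod_spacing` (the array lattice
#'   constant).
#' * `sites = "centers"`: positions are hexagon centres (one CSU-scale
#'   particle per unit cell) forming a triangular lattice with nearest
#'   neighbour distance `sqrt(3) * tod_spacing`.
#'
#' On a sphere-cap the planar lattice is mapped by an azimuthal equidistant
#' projection about the cap axis (radial arc lengths preserved; azimuthal
#' distances compressed by at most ~2 percent at 25 degrees cap radius) and
#' positions are projected exactly onto the sphere. Orientations have their
#' principal (+z reference) axis along the local outward normal. The
#' in-plane (third Euler) angle is, by default, lattice-coherent: arrays are
#' orientationally ordered, so every particle's in-plane frame follows the
#' local lattice direction (the whole lattice is rotated by one random,
#' seeded azimuth per array). `inplane = "random"` draws independent
#' in-plane angles instead, which breaks the physical coupling between
#' particle orientation and lattice direction and is useful only for
#' orientation-agnostic tests.
#'
#' @param surface a [membrane_surface()].
#' @param tod_spacing honeycomb nearest-neighbour (ToD axis) spacing in
#'   Angstrom.
#' @param jitter_sd isotropic positional jitter s.d. in Angstrom (applied in
#'   the surface tangent plane, then re-projected).
#' @param seed integer RNG seed; fixed seed gives identical output.
#' @param sites `"honeycomb"` or `"centers"`.
#' @param inplane `"lattice"` (coherent, default) or `"random"`.
#' @param lattice_azimuth lattice rotation about the cap axis in degrees;
#'   NULL (default) draws it uniformly from the seed.
#' @return a `ground_truth_array`: list with `surface`, `lattice_constant`,
#'   `tod_spacing`, `positions` (n x 3, A), `orientations` (n x 3 Euler ZYZ
#'   degrees), `jitter_sd`.
#' @export
place_hex_array <- function(surface, tod_spacing, jitter_sd = 0, seed = 1,
                            sites = c("honeycomb", "centers"),
                            inplane = c("lattice", "random"),
                            lattice_azimuth = NULL) {
  sites <- match.arg(sites)
  inplane <- match.arg(inplane)
  stopifnot(tod_spacing > 0, jitter_sd >= 0)
  set.seed(seed)
  if (is.null(lattice_azimuth)) lattice_azimuth <- stats::runif(1, 0, 360)
  a <- sqrt(3) * tod_spacing            # hexagonal lattice constant
  if (surface$kind == "plane") {
    hw <- surface$extent / 2
    rmax <- max(hw)
  } else {
    rmax <- surface$radius * surface$extent * pi / 180  # cap arc radius
  }
  if (min(rmax) < a / 2) {
    warning("lattice spacing exceeds surface extent; returning empty array")
    uv <- matrix(numeric(0), ncol = 2)
  } else {
    # triangular lattice of hexagon centres in tangent coordinates
    nmax <- ceiling(2 * rmax / a) + 1
    ij <- expand.grid(i = -nmax:nmax, j = -nmax:nmax)
    u <- a * (ij$i + ij$j / 2)
    v <- a * ij$j * sqrt(3) / 2
    uv <- cbind(u, v)
    if (sites == "honeycomb")
      uv <- rbind(uv, sweep(uv, 2, c(0, tod_spacing), "+"))
    # rotate the whole lattice by the array azimuth
    azr <- lattice_azimuth * pi / 180
    uv <- uv %*% t(matrix(c(cos(azr), sin(azr), -sin(azr), cos(azr)), 2, 2))
    keep <- if (surface$kind == "plane")
      abs(uv[, 1]) <= hw[1] & abs(uv[, 2]) <= hw[2]
    else
      sqrt(rowSums(uv^2)) <= rmax
    uv <- uv[keep, , drop = FALSE]
  }
  n <- nrow(uv)
  if (n > 0 && jitter_sd > 0)
    uv <- uv + matrix(stats::rnorm(2 * n, 0, jitter_sd), n, 2)
  psi_rand <- stats::runif(max(n, 1), 0, 360)[seq_len(n)]

  if (surface$kind == "plane") {
    pos <- cbind(uv[, 1] + surface$center[1], uv[, 2] + surface$center[2],
                 rep(surface$center[3], n))
  } else {
    # azimuthal equidistant about the cap axis, in the cap-local frame
    rho <- sqrt(rowSums(uv^2))
    theta <- rho / surface$radius
    phi <- atan2(uv[, 2], uv[, 1])
    local <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta)) *
      surface$radius
    Rax <- rotation_between(c(0, 0, 1), surface$axis)
    pos <- sweep(local %*% t(Rax), 2, surface$center, "+")
  }
  nrm <- if (n > 0) surface_normals(surface, pos) else matrix(numeric(0), ncol = 3)
  # lattice-coherent in-plane angle: transport the (rotated) lattice x-axis
  # into each particle's tangent plane and measure it in the axis frame
  Rax <- rotation_between(c(0, 0, 1), surface$axis)
  lat_dir <- as.numeric(Rax %*% c(cos(azr <- lattice_azimuth * pi / 180),
                                  sin(azr), 0))
  ori <- t(vapply(seq_len(n), function(i) {
    if (inplane == "random") return(euler_from_axis(nrm[i, ], psi_rand[i]))
    t_i <- lat_dir - sum(lat_dir * nrm[i, ]) * nrm[i, ]
    t_i <- t_i / sqrt(sum(t_i^2))
    Rf <- euler_to_matrix(euler_from_axis(nrm[i, ], 0))
    euler_from_axis(nrm[i, ], atan2(sum(t_i * Rf[, 2]), sum(t_i * Rf[, 1])) *
                      180 / pi)
  }, numeric(3)))
  if (n == 0) ori <- matrix(numeric(0), ncol = 3)
  structure(list(surface = surface, lattice_constant = a,
                 tod_spacing = tod_spacing, positions = pos,
                 orientations = ori, jitter_sd = jitter_sd),
            class = "ground_truth_array")
}

# shortest-arc rotation matrix mapping unit vector a onto unit vector b
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))  # antipodal: flip about x
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' ToD spacing to array lattice constant
#'
#' Converts the nearest-neighbour separation of trimer-of-dimer symmetry axes
#' (honeycomb vertices) into the hexagonal array lattice constant via the
#' honeycomb relation `lattice_constant = sqrt(3) * tod_spacing`.
#' Unit-preserving: pass nm to get nm, Angstrom to get Angstrom.
#'
#' @param tod_spacing ToD axis separation (> 0), any length unit.
#' @return lattice constant in the same unit.
#' @examples
#' tod_to_lattice_constant(7.4)   # nm in, nm out: ~12.8
#' @export
tod_to_lattice_constant <- function(tod_spacing) {
  if (!is.numeric(tod_spacing) || any(tod_spacing <= 0))
    stop("tod_spacing must be positive")
  sqrt(3) * tod_spacing
}
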