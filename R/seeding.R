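#' Seed initial particle positions on a membrane surface
#'
#' Emits an approximately uniform set of positions on the surface with the
#' requested mean spacing (the dense oversampling from which alignment and
#' duplicate collapse later recover the true lattice). On a plane this is a
#' square grid; on a sphere-cap, latitude rings at the grid spacing with
#' golden-angle azimuthal offsets between rings. The construction is
#' deterministic; `seed` is accepted for interface uniformity.
#'
#' @param surface a [membrane_surface()].
#' @param mean_spacing target mean nearest-neighbour distance (A, > 0).
#' @param region optional restriction: angular cap radius in degrees
#'   (sphere-cap) or length-2 lateral extent in Angstrom (plane); defaults to
#'   the surface extent.
#' @param seed unused RNG seed kept for call-signature stability.
#' @return a `seed_set`: [particle_set()] with orientations from
#'   [orientations_from_normals()] and attributes `mean_spacing`, `surface`.
#' @export
sample_seed_positions <- function(surface, mean_spacing, region = NULL,
                                  seed = 1) {
  if (!is.numeric(mean_spacing) || mean_spacing <= 0)
    stop("mean_spacing must be > 0")
  if (is.null(region)) region <- surface$extent
  if (surface$kind == "plane") {
    hw <- rep(region, length.out = 2) / 2
    if (any(hw < mean_spacing / 2)) {
      pos <- matrix(numeric(0), ncol = 3)
    } else {
      xs <- seq(-hw[1] + mean_spacing / 2, hw[1], by = mean_spacing)
      ys <- seq(-hw[2] + mean_spacing / 2, hw[2], by = mean_spacing)
      pos <- cbind(as.matrix(expand.grid(x = xs, y = ys)), 0)
      pos <- sweep(pos, 2, surface$center, "+")
    }
  } else {
    theta_max <- region * pi / 180
    dth <- mean_spacing / surface$radius
    if (theta_max < dth / 2) {
      pos <- matrix(numeric(0), ncol = 3)
    } else {
      golden <- pi * (3 - sqrt(5))
      loc <- list()
      thetas <- seq(dth / 2, theta_max, by = dth)
      for (i in seq_along(thetas)) {
        th <- thetas[i]
        circ <- 2 * pi * surface$radius * sin(th)
        np <- max(1L, as.integer(round(circ / mean_spacing)))
        ph <- (seq_len(np) - 1) * 2 * pi / np + i * golden
        loc[[i]] <- cbind(sin(th) * cos(ph), sin(th) * sin(ph),
                          rep(cos(th), np)) * surface$radius
      }
      local <- do.call(rbind, loc)
      Rax <- rotation_between(c(0, 0, 1), surface$axis)
      pos <- sweep(local %*% t(Rax), 2, surface$center, "+")
    }
  }
  out <- orientations_from_normals(surface, pos)
  attr(out, "mean_spacing") <- mean_spacing
  out
}

#' Orientations from surface normals
#'
#' Assigns each position the orientation whose principal (+z reference) axis
#' is the outward surface normal at the nearest surface point; positions off
#' the surface are projected with a warning. The in-plane (third Euler)
#' angle is set to 0 and left to the angular search.
#'
#' @param surface a [membrane_surface()].
#' @param positions n x 3 matrix, Angstrom.
#' @param tol distance tolerance (A) beyond which the projection warning is
#'   raised.
#' @return a `seed_set` ([particle_set()] with attribute `surface`).
#' @export
orientations_from_normals <- function(surface, positions, tol = 1) {
  positions <- rbind(positions)
  n <- nrow(positions)
  if (n == 0) {
    out <- empty_particle_set()
  } else {
    proj <- surface_project(surface, positions)
    off <- sqrt(rowSums((proj - positions)^2))
    if (any(off > tol))
      warning(sprintf("%d position(s) projected onto the surface (max %.1f A off)",
                      sum(off > tol), max(off)))
    nrm <- surface_normals(surface, proj)
    ori <- t(vapply(seq_len(n), function(i) euler_from_axis(nrm[i, ], 0),
                    numeric(3)))
    out <- particle_set(proj, ori)
  }
  attr(out, "surface") <- surface
  class(out) <- c("seed_set", class(out))
  out
}
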