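#' Membrane surface models
#'
#' Surfaces supported are a spherical cap (`kind = "sphere-cap"`, the minicell
#' membrane geometry: centre, radius, angular extent `theta_max` about the
#' cap axis +z) and a plane (`kind = "plane"`, lateral extent `lx` by `ly`
#' centred on `center`, outward normal +z).
#'
#' @param kind `"sphere-cap"` or `"plane"`.
#' @param center 3-vector, Angstrom.
#' @param radius sphere radius in Angstrom (sphere-cap only, > 0).
#' @param extent for a sphere-cap the angular radius of the cap in degrees;
#'   for a plane a length-2 lateral extent in Angstrom.
#' @param axis cap axis (unit 3-vector, sphere-cap only); the cap is centred
#'   on the point `center + radius * axis`.
#' @return an object of class `membrane_surface`.
#' @export
membrane_surface <- function(kind = c("sphere-cap", "plane"),
                             center = c(0, 0, 0), radius = NULL,
                             extent = NULL, axis = c(0, 0, 1)) {
  kind <- match.arg(kind)
  if (kind == "sphere-cap") {
    if (is.null(radius) || radius <= 0) stop("sphere-cap requires radius > 0")
    if (is.null(extent)) extent <- 90
    stopifnot(length(extent) == 1, extent > 0)
    axis <- axis / sqrt(sum(axis^2))
  } else {
    if (is.null(extent)) stop("plane requires a length-2 extent")
    extent <- rep(extent, length.out = 2)
    axis <- c(0, 0, 1)
  }
  structure(list(kind = kind, center = as.numeric(center),
                 radius = if (kind == "sphere-cap") radius else Inf,
                 extent = extent, axis = axis),
            class = "membrane_surface")
}

#' Outward unit normal of a membrane surface
#'
#' @param surface a [membrane_surface()].
#' @param points n x 3 matrix of Angstrom positions.
#' @return n x 3 matrix of unit normals. For a sphere-cap the outward normal
#'   is radial; for a plane it is +z everywhere.
#' @export
surface_normals <- function(surface, points) {
  points <- rbind(points)
  if (surface$kind == "plane") {
    matrix(rep(c(0, 0, 1), each = nrow(points)), ncol = 3)
  } else {
    d <- sweep(points, 2, surface$center)
    r <- sqrt(rowSums(d^2))
    if (any(r < 1e-9)) stop("point at sphere centre has no normal")
    d / r
  }
}

#' Project points onto a membrane surface
#'
#' Nearest-point projection; for a sphere-cap this is radial rescaling.
#'
#' @inheritParams surface_normals
#' @return n x 3 matrix of projected positions.
#' @export
surface_project <- function(surface, points) {
  points <- rbind(points)
  if (surface$kind == "plane") {
    points[, 3] <- surface$center[3]
    points
  } else {
    d <- sweep(points, 2, surface$center)
    r <- sqrt(rowSums(d^2))
    sweep(d * (surface$radius / r), 2, surface$center, "+")
  }
}

#' Least-squares sphere fit to membrane annotation points
#'
#' Algebraic least-squares fit (linear in centre and `radius^2`) followed by
#' the radial-residual RMS report. Used to model the curved minicell membrane
#' from clicked annotation points before seeding particles on it.
#'
#' @param points n x 3 matrix (n >= 4, non-coplanar), Angstrom.
#' @return a `membrane_surface` of kind sphere-cap with attributes
#'   `residual_rms` (A) and `extent` covering the input points.
#' @export
fit_sphere <- function(points) {
  points <- rbind(points)
  if (nrow(points) < 4) stop("degenerate geometry: need at least 4 points")
  A <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  qrA <- qr(A)
  if (qrA$rank < 4)
    stop("degenerate geometry: points are coplanar or otherwise rank-deficient")
  # guard against numerically near-coplanar input: the plane-fit residual of
  # the points must be resolvably nonzero relative to their spread
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2, ctr), nu = 0, nv = 0)$d
  if (sv[3] < 1e-9 * sv[1])
    stop("degenerate geometry: points are coplanar or otherwise rank-deficient")
  sol <- qr.coef(qrA, b)
  centre <- sol[1:3]
  radius <- sqrt(sol[4] + sum(centre^2))
  resid <- sqrt(rowSums(sweep(points, 2, centre)^2)) - radius
  d <- sweep(points, 2, centre)
  mdir <- colMeans(d / sqrt(rowSums(d^2)))
  if (sqrt(sum(mdir^2)) < 1e-6) {
    axis <- c(0, 0, 1)
    ext <- 179
  } else {
    axis <- mdir / sqrt(sum(mdir^2))
    cosang <- (d %*% axis) / sqrt(rowSums(d^2))
    ext <- min(179, max(5, 180 / pi * acos(max(-1, min(cosang))) * 1.1))
  }
  s <- membrane_surface("sphere-cap", center = centre, radius = radius,
                        extent = ext, axis = axis)
  attr(s, "residual_rms") <- sqrt(mean(resid^2))
  s
}
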