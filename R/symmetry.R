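#' C2 symmetrisation about a refined axis
#'
#' Searches a cone of candidate two-fold axes around the prior (default the
#' map +z through the cube centre), scoring each by the masked Pearson
#' correlation between the map and its 180-degree rotation about the
#' candidate axis. The map is then averaged with its rotation about the best
#' axis, optionally after an in-plane refinement of the axis origin, giving
#' an output invariant under the C2 operation.
#'
#' @param map a [tomogram_volume()] or 3D array.
#' @param axis_prior unit 3-vector prior for the axis direction; default +z.
#' @param cone search cone half-angle in degrees (default 10).
#' @param step axis grid step in degrees (default 1).
#' @param refine_origin logical; also search in-plane origin offsets of
#'   +/- 2 voxels at the best axis (default TRUE).
#' @param min_score abort threshold on the alignment correlation.
#' @return symmetrised map (same class as input) with attributes `axis`
#'   (unit 3-vector), `origin_offset` (voxels) and `score`.
#' @export
symmetrize_c2 <- function(map, axis_prior = c(0, 0, 1), cone = 10, step = 1,
                          refine_origin = TRUE, min_score = 0.2) {
  g <- if (inherits(map, "tomogram_volume")) map$grid else map
  d <- dim(g)
  ax0 <- axis_prior / sqrt(sum(axis_prior^2))
  # correlation mask: central soft sphere
  n <- min(d)
  axs <- lapply(d, function(m) (seq_len(m) - 1) - centre_voxel(m))
  r <- sqrt(array(axs[[1]]^2, d) +
              aperm(array(axs[[2]]^2, d[c(2, 1, 3)]), c(2, 1, 3)) +
              aperm(array(axs[[3]]^2, d[c(3, 1, 2)]), c(2, 3, 1)))
  msk <- r <= (n / 2 - 2)
  gm <- g[msk]
  score_axis <- function(u, off = c(0, 0, 0)) {
    Rpi <- 2 * outer(u, u) - diag(3)        # rotation by pi about u
    rot <- rotate_about(g, Rpi, off)
    suppressWarnings(stats::cor(gm, rot[msk]))
  }
  Rb <- rotation_between(c(0, 0, 1), ax0)
  best <- list(score = -Inf)
  for (dv in seq(0, cone, by = step)) {
    azs <- if (dv == 0) 0 else
      (seq_len(max(1L, round(360 * sin(dv * pi / 180) / step))) - 1) *
        360 / max(1L, round(360 * sin(dv * pi / 180) / step))
    for (az in azs) {
      u <- Rb %*% c(sin(dv * pi / 180) * cos(az * pi / 180),
                    sin(dv * pi / 180) * sin(az * pi / 180),
                    cos(dv * pi / 180))
      s <- score_axis(as.numeric(u))
      if (is.finite(s) && s > best$score)
        best <- list(score = s, axis = as.numeric(u))
    }
  }
  off <- c(0, 0, 0)
  if (refine_origin) {
    # in-plane basis perpendicular to the axis
    e1 <- rotation_between(c(0, 0, 1), best$axis)[, 1]
    e2 <- rotation_between(c(0, 0, 1), best$axis)[, 2]
    for (o1 in -2:2) for (o2 in -2:2) {
      if (o1 == 0 && o2 == 0) next
      cand <- o1 * e1 + o2 * e2
      s <- score_axis(best$axis, cand)
      if (is.finite(s) && s > best$score) {
        best$score <- s
        off <- cand
      }
    }
  }
  if (best$score < min_score)
    stop(sprintf("C2 alignment failed: best correlation %.3f < %.2f",
                 best$score, min_score))
  Rpi <- 2 * outer(best$axis, best$axis) - diag(3)
  sym <- (g + rotate_about(g, Rpi, off)) / 2
  out <- if (inherits(map, "tomogram_volume"))
    tomogram_volume(sym, map$voxel_size, origin = map$origin, wedge = map$wedge)
  else sym
  attr(out, "axis") <- best$axis
  attr(out, "origin_offset") <- off
  attr(out, "score") <- best$score
  out
}

# rotate a grid by matrix R about (centre voxel + off), trilinear
rotate_about <- function(g, R, off = c(0, 0, 0)) {
  d <- dim(g)
  ctr <- centre_voxel(d) + off
  array(.resample_affine(as.numeric(g), d, d, t(R), ctr, ctr, c(0, 0, 0)), d)
}
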