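#' Extract a cubic subvolume around a position
#'
#' Cuts a cube of `round(box / voxel_size)` voxels centred (centre voxel =
#' 0-based index `floor(N/2)`) on the voxel nearest to `position`.
#' Out-of-bounds voxels are zero-padded and the padded fraction reported.
#'
#' @param tomo a [tomogram_volume()].
#' @param position length-3 Angstrom position (must lie inside the volume).
#' @param box cube side in Angstrom.
#' @return a `subvolume`: list with `grid`, `voxel_size`, `source_position`
#'   (A position of the cube centre voxel), `tomo_id`, `wedge`, and attribute
#'   `padding_fraction`.
#' @export
extract_subvolume <- function(tomo, position, box, tomo_id = 1L) {
  stopifnot(inherits(tomo, "tomogram_volume"), box > 0)
  d <- dim(tomo$grid)
  vs <- tomo$voxel_size
  pv <- (position - tomo$origin) / vs
  if (any(pv < -0.5) || any(pv > d - 0.5))
    stop("position outside the tomogram volume")
  nv <- as.integer(round(box / vs))
  q <- round(pv)                      # 0-based centre voxel in the tomogram
  ctr <- centre_voxel(nv)
  lo <- q - ctr                       # 0-based start in tomogram
  hi <- lo + nv - 1
  g <- array(0, rep(nv, 3))
  slo <- pmax(lo, 0); shi <- pmin(hi, d - 1)
  g[(slo[1] - lo[1] + 1):(shi[1] - lo[1] + 1),
    (slo[2] - lo[2] + 1):(shi[2] - lo[2] + 1),
    (slo[3] - lo[3] + 1):(shi[3] - lo[3] + 1)] <-
    tomo$grid[(slo[1] + 1):(shi[1] + 1), (slo[2] + 1):(shi[2] + 1),
              (slo[3] + 1):(shi[3] + 1)]
  pad <- 1 - prod(shi - slo + 1) / nv^3
  structure(list(grid = g, voxel_size = vs,
                 source_position = tomo$origin + q * vs,
                 tomo_id = tomo_id, wedge = tomo$wedge),
            class = "subvolume", padding_fraction = pad)
}

#' Soft cylindrical alignment mask
#'
#' Cylinder about +z spanning `[z_min, z_max]` Angstrom relative to the cube
#' centre, with a raised-cosine edge. Stage-1 masks span the CSU footprint
#' plus the membrane slab; stage-2 masks stop below the membrane.
#'
#' @param box cube side in voxels.
#' @param voxel_size Angstrom per voxel.
#' @param radius cylinder radius (A).
#' @param z_min,z_max axial range (A, relative to cube centre).
#' @param soft_voxels edge width in voxels.
#' @return 3D array in `[0, 1]`.
#' @export
make_cylinder_mask <- function(box, voxel_size, radius, z_min, z_max,
                               soft_voxels = 3) {
  n <- as.integer(box)
  ax <- ((seq_len(n) - 1) - centre_voxel(n)) * voxel_size
  soft <- soft_voxels * voxel_size
  edge <- function(d) {       # 1 inside (d <= 0), cosine rolloff over `soft`
    w <- pmin(pmax(d / soft, 0), 1)
    (1 + cos(pi * w)) / 2
  }
  r <- sqrt(outer(ax^2, ax^2, "+"))
  mr <- edge(r - radius)                                 # n x n (x, y)
  mz <- edge(pmax(ax - z_max, z_min - ax))               # along z
  array(outer(mr, mz), c(n, n, n))
}

# --- internal correlation machinery ---------------------------------------

# Per-subvolume / per-mask precomputation for the masked, wedge-restricted
# normalized cross-correlation. The shift-dependent denominator uses the
# local mean/variance of the subvolume under the mask, computed by FFT.
ncc_precompute <- function(sub_grid, mask, wedge_mask) {
  N <- length(sub_grid)
  P <- sum(mask)
  if (P <= 0) stop("undefined correlation: empty mask")
  Fm <- stats::fft(mask)
  Fs <- stats::fft(sub_grid)
  Fs2 <- stats::fft(sub_grid^2)
  m1 <- Re(stats::fft(Conj(Fm) * Fs, inverse = TRUE)) / N
  m2 <- Re(stats::fft(Conj(Fm) * Fs2, inverse = TRUE)) / N
  vs <- pmax(m2 / P - (m1 / P)^2, 0)
  denom <- sqrt(P * vs)
  valid <- vs > 1e-12 * max(vs)
  if (!any(valid)) stop("undefined correlation: subvolume is constant under the mask")
  list(Fs = Fs, denom = denom, valid = valid, P = P, W = wedge_mask, N = N)
}

# Score one reference candidate (already masked, mean-removed, in the
# subvolume frame) against the precomputed subvolume terms. Returns the
# wrapped correlation map and the reference norm.
ncc_score_map <- function(a, pre) {
  FA <- stats::fft(a)
  if (!is.null(pre$W)) FA[!pre$W] <- 0
  na <- sqrt(sum(Mod(FA)^2) / pre$N)
  if (na <= 0) stop("undefined correlation: reference is empty under the mask")
  cc <- Re(stats::fft(Conj(FA) * pre$Fs, inverse = TRUE)) / pre$N
  sc <- array(-Inf, dim(a))
  sc[pre$valid] <- cc[pre$valid] / (na * pre$denom[pre$valid])
  sc
}

# indices (1-based, per axis) of wrapped shifts within +/- limit voxels
shift_window <- function(n, limit) {
  l <- min(limit, floor((n - 1) / 2))
  c(seq_len(l + 1), if (l > 0) (n - l + 1):n else integer(0))
}

# the mask-local normalization makes a perfect match score exactly 1 with a
# binary mask but can overshoot marginally with soft masks or wedge
# filtering; reported scores are clamped to the defined range (raw values
# are still used to rank candidates)
clamp_score <- function(s) max(-1, min(1, s))

wrapped_shift <- function(idx, n) ifelse(idx - 1 > n / 2, idx - 1 - n, idx - 1)

# parabolic sub-voxel refinement of a correlation peak along each axis
subvoxel_peak <- function(sc, peak_idx) {
  d <- dim(sc)
  out <- numeric(3)
  for (a in 1:3) {
    i <- peak_idx
    im <- i; im[a] <- (i[a] - 2) %% d[a] + 1
    ip <- i; ip[a] <- i[a] %% d[a] + 1
    c0 <- sc[matrix(i, 1)]; cm <- sc[matrix(im, 1)]; cp <- sc[matrix(ip, 1)]
    den <- cm - 2 * c0 + cp
    if (is.finite(cm) && is.finite(cp) && den < 0)
      out[a] <- max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
  }
  out
}

#' Constrained translational alignment by masked, wedge-compensated NCC
#'
#' FFT-based normalized cross-correlation of a reference against a
#' subvolume, evaluated under a real-space mask and restricted to Fourier
#' components inside the subvolume's missing-wedge support. The reference
#' side is mask-weighted and mean-removed (and wedge-filtered); the
#' subvolume side is normalized by its local mean and variance under the
#' mask at every candidate shift, so the score of a perfect match is 1. Only
#' shifts within `shift_limit` Angstrom per axis are considered; the integer
#' peak is refined by parabolic interpolation.
#'
#' @param ref reference: 3D array or [tomogram_volume()], same grid as `sub`.
#' @param sub a [extract_subvolume()] result (its `wedge` drives the
#'   compensation; set `wedge = "full"` for none).
#' @param mask 3D array in `[0, 1]`, reference frame.
#' @param shift_limit allowed translation per axis in Angstrom.
#' @param subvoxel logical; refine the peak below one voxel (default TRUE).
#' @return an `alignment_result`: list with `shift` (A), `rotation` (Euler,
#'   all zero here), `score` in `[-1, 1]`, `iteration = 0L`.
#' @export
constrained_ncc <- function(ref, sub, mask, shift_limit, subvoxel = TRUE) {
  rg <- if (inherits(ref, "tomogram_volume")) ref$grid else ref
  stopifnot(identical(dim(rg), dim(sub$grid)))
  W <- if (identical(sub$wedge, "full")) NULL
       else wedge_fourier_mask(dim(rg), sub$wedge$max_angle)
  pre <- ncc_precompute(sub$grid, mask, W)
  P <- sum(mask)
  a <- mask * (rg - sum(mask * rg) / P)
  if (max(abs(a)) == 0) stop("undefined correlation: reference is constant under the mask")
  sc <- ncc_score_map(a, pre)
  best <- best_shift(sc, sub$voxel_size, shift_limit, subvoxel)
  structure(list(shift = best$shift, rotation = c(0, 0, 0),
                 score = clamp_score(best$score), iteration = 0L),
            class = "alignment_result")
}

best_shift <- function(sc, voxel_size, shift_limit, subvoxel = TRUE) {
  d <- dim(sc)
  lim <- floor(shift_limit / voxel_size)
  if (lim == 0) subvoxel <- FALSE
  wins <- lapply(1:3, function(a) shift_window(d[a], lim))
  sub_sc <- sc[wins[[1]], wins[[2]], wins[[3]], drop = FALSE]
  pk <- which(sub_sc == max(sub_sc), arr.ind = TRUE)[1, ]
  idx <- c(wins[[1]][pk[1]], wins[[2]][pk[2]], wins[[3]][pk[3]])
  sv <- vapply(1:3, function(a) wrapped_shift(idx[a], d[a]), numeric(1))
  frac <- if (subvoxel) subvoxel_peak(sc, idx) else c(0, 0, 0)
  list(shift = (sv + frac) * voxel_size, score = max(sub_sc))
}

# quasi-uniform grid of rotations: axis deviations up to cone_half_angle in
# steps of angular_step (with azimuth count proportional to sin(delta)),
# crossed with an in-plane sweep. Returns a list of lists
# (euler, dev = axis deviation in degrees).
cone_rotation_grid <- function(prior, cone_half_angle, angular_step,
                               inplane_step, inplane_range, sym = 1) {
  Rp <- euler_to_matrix(prior)
  devs <- seq(0, cone_half_angle, by = max(angular_step, 1e-6))
  span <- min(inplane_range, 360 / sym)
  psis <- if (span <= 0) 0
          else seq(-span / 2, span / 2, by = inplane_step)
  if (span >= 360 / sym - 1e-9)  # full sweep: avoid duplicating the endpoints
    psis <- seq(0, span - inplane_step, by = inplane_step)
  grid <- list()
  for (dv in devs) {
    azs <- if (dv == 0) 0 else
      (seq_len(max(1L, round(360 * sin(dv * pi / 180) / angular_step))) - 1) *
        360 / max(1L, round(360 * sin(dv * pi / 180) / angular_step))
    for (az in azs) {
      Rt <- Rp %*% euler_to_matrix(c(az, dv, -az))
      for (ps in psis) {
        eul <- if (dv == 0 && ps == 0) prior
               else matrix_to_euler(Rt %*% euler_to_matrix(c(0, 0, ps)))
        grid[[length(grid) + 1]] <- list(euler = eul, dev = dv)
      }
    }
  }
  grid
}

#' Conically constrained angular search
#'
#' Exhaustive search over a quasi-uniform rotation grid whose principal axis
#' deviates from the prior orientation by at most `cone_half_angle`, crossed
#' with an in-plane sweep, each candidate scored by the constrained NCC of
#' [constrained_ncc()]. The mask is carried with the reference frame: it is
#' rotated by the prior for the subvolume-side normalization, and the
#' mask-weighted reference is rotated per candidate. Ties are broken by the
#' smaller angular distance to the prior, then the lower grid index.
#'
#' @param ref reference 3D array or [tomogram_volume()].
#' @param sub a subvolume from [extract_subvolume()].
#' @param mask 3D array in `[0, 1]` (reference frame).
#' @param prior Euler triplet (ZYZ degrees) of the initial orientation.
#' @param cone_half_angle cone half-angle in degrees, `[0, 180]`.
#' @param angular_step axis grid step in degrees (> 0).
#' @param shift_limit translational freedom per axis (A).
#' @param inplane_step in-plane sweep step (degrees); defaults to
#'   `angular_step`.
#' @param inplane_range in-plane sweep span (degrees, centred on the prior
#'   in-plane angle); default 360 (full sweep).
#' @param sym in-plane symmetry order of the reference (2 for a C2 motif);
#'   the sweep covers `360/sym` degrees.
#' @param context_ref optional larger 3D array (or [tomogram_volume()]):
#'   an unrotated array-model reference with spatial context beyond the
#'   subvolume box. It is rotated to the prior, wedge-filtered at full size
#'   in the tomogram frame and cropped to the box, so the crop carries the
#'   same wedge-smeared out-of-box contributions as the data; candidates are
#'   applied as small residual rotations of the crop. Intended for local
#'   refinement (small cones/in-plane windows).
#' @param context_cache optional environment memoising wedge-filtered
#'   context crops across particles that share a (quantised) prior.
#' @return an `alignment_result` with `rotation` the best Euler triplet and
#'   `shift` in Angstrom.
#' @export
cone_angular_search <- function(ref, sub, mask, prior, cone_half_angle,
                                angular_step, shift_limit,
                                inplane_step = angular_step,
                                inplane_range = 360, sym = 1,
                                context_ref = NULL, context_cache = NULL) {
  stopifnot(cone_half_angle >= 0, cone_half_angle <= 180, angular_step > 0)
  rg <- if (inherits(ref, "tomogram_volume")) ref$grid else ref
  if (is.null(context_ref)) stopifnot(identical(dim(rg), dim(sub$grid)))
  if (cone_half_angle > 0 && angular_step > cone_half_angle) {
    warning("angular_step exceeds cone_half_angle: returning the prior")
    res <- score_at_rotation(rg, sub, mask, prior, shift_limit)
    return(res)
  }
  use_context <- !is.null(context_ref)
  W <- if (identical(sub$wedge, "full")) NULL
       else wedge_fourier_mask(dim(sub$grid), sub$wedge$max_angle)
  mask_p <- pmin(pmax(rotate_volume(mask, prior), 0), 1)
  pre <- ncc_precompute(sub$grid, mask_p, if (use_context) NULL else W)
  if (use_context) {
    cg <- if (inherits(context_ref, "tomogram_volume")) context_ref$grid
          else context_ref
    # particles sharing a (quantised) prior reuse the wedge-filtered crop
    key <- paste(round(prior, 2), collapse = "_")
    if (!is.null(context_cache) && !is.null(context_cache[[key]])) {
      crop0 <- context_cache[[key]]
    } else {
      crop0 <- wedged_context_crop(cg, prior, sub$wedge, dim(sub$grid))
      if (!is.null(context_cache)) context_cache[[key]] <- crop0
    }
    Rp <- euler_to_matrix(prior)
  } else {
    P <- sum(mask)
    a0 <- mask * (rg - sum(mask * rg) / P)
  }
  grid <- cone_rotation_grid(prior, cone_half_angle, angular_step,
                             inplane_step, inplane_range, sym)
  best <- NULL
  for (gi in seq_along(grid)) {
    cand <- grid[[gi]]
    if (use_context) {
      resid <- euler_to_matrix(cand$euler) %*% t(Rp)
      a <- if (identical(cand$euler, prior)) crop0
           else rotate_volume(crop0, resid)
      a <- mask_p * (a - sum(mask_p * a) / sum(mask_p))
    } else {
      a <- rotate_volume(a0, cand$euler)
    }
    sc <- ncc_score_map(a, pre)
    bs <- best_shift(sc, sub$voxel_size, shift_limit, subvoxel = TRUE)
    ad <- angular_distance(prior, cand$euler)
    if (is.null(best) || bs$score > best$score + 1e-12 ||
        (abs(bs$score - best$score) <= 1e-12 && ad < best$angdist - 1e-12)) {
      best <- list(score = bs$score, shift = bs$shift, euler = cand$euler,
                   angdist = ad, index = gi)
    }
  }
  structure(list(shift = best$shift, rotation = best$euler,
                 score = clamp_score(best$score), iteration = 0L),
            class = "alignment_result")
}

# Rotate a large context reference to the prior orientation, apply the
# subvolume's wedge in the tomogram frame at full size, and crop the centre
# to the target box: the crop then contains the wedge-smeared contributions
# of model structure outside the box, like a real subtomogram does.
wedged_context_crop <- function(cg, prior, wedge, out_dim) {
  a <- rotate_volume(cg, prior)
  if (!identical(wedge, "full")) {
    W <- wedge_fourier_mask(dim(cg), wedge$max_angle)
    f <- stats::fft(a)
    f[!W] <- 0
    a <- Re(stats::fft(f, inverse = TRUE)) / length(f)
    dim(a) <- dim(cg)
  }
  crop_centre(a, out_dim)
}

crop_centre <- function(g, out_dim) {
  d <- dim(g)
  stopifnot(all(out_dim <= d))
  lo <- centre_voxel(d) - centre_voxel(out_dim)   # 0-based
  g[(lo[1] + 1):(lo[1] + out_dim[1]),
    (lo[2] + 1):(lo[2] + out_dim[2]),
    (lo[3] + 1):(lo[3] + out_dim[3]), drop = FALSE]
}

# score a single fixed rotation (used for the degenerate-grid fallback and
# by iterative_refine's null steps)
score_at_rotation <- function(rg, sub, mask, rotation, shift_limit) {
  W <- if (identical(sub$wedge, "full")) NULL
       else wedge_fourier_mask(dim(rg), sub$wedge$max_angle)
  mask_p <- pmin(pmax(rotate_volume(mask, rotation), 0), 1)
  pre <- ncc_precompute(sub$grid, mask_p, W)
  P <- sum(mask)
  a <- rotate_volume(mask * (rg - sum(mask * rg) / P), rotation)
  sc <- ncc_score_map(a, pre)
  bs <- best_shift(sc, sub$voxel_size, shift_limit, subvoxel = TRUE)
  structure(list(shift = bs$shift, rotation = rotation,
                 score = clamp_score(bs$score), iteration = 0L),
            class = "alignment_result")
}
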