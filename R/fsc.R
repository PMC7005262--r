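#' Fourier shell correlation between two half-maps
#'
#' Per-shell normalized complex correlation of two maps after multiplying
#' both by a real-space mask. Shells are one Fourier voxel wide.
#'
#' @param map_a,map_b 3D arrays or [tomogram_volume()]s on the same cubic
#'   grid.
#' @param mask optional 3D array in `[0, 1]`; default none.
#' @param voxel_size Angstrom per voxel (taken from `map_a` if it is a
#'   `tomogram_volume`).
#' @return an `fsc_curve`: list with `shell_freq` (1/A, ascending),
#'   `correlation`, `shell_counts`, `voxel_size`.
#' @export
compute_fsc <- function(map_a, map_b, mask = NULL, voxel_size = NULL) {
  ga <- if (inherits(map_a, "tomogram_volume")) map_a$grid else map_a
  gb <- if (inherits(map_b, "tomogram_volume")) map_b$grid else map_b
  if (is.null(voxel_size))
    voxel_size <- if (inherits(map_a, "tomogram_volume")) map_a$voxel_size else 1
  stopifnot(identical(dim(ga), dim(gb)))
  d <- dim(ga)
  if (length(unique(d)) != 1) stop("FSC requires a cubic grid")
  if (!is.null(mask)) { ga <- ga * mask; gb <- gb * mask }
  if (max(abs(ga)) == 0 || max(abs(gb)) == 0)
    stop("undefined correlation: masked map is all zero")
  n <- d[1]
  Fa <- stats::fft(ga)
  Fb <- stats::fft(gb)
  K <- freq_grid(d)                      # cycles/voxel
  shell <- pmin(as.integer(round(sqrt(colSums(K^2)) * n)), n)  # voxel radius
  num <- Re(as.vector(Fa) * Conj(as.vector(Fb)))
  pa <- Mod(as.vector(Fa))^2
  pb <- Mod(as.vector(Fb))^2
  ns <- n %/% 2
  idx <- shell + 1L
  sel <- shell <= ns
  sum_by <- function(v) {
    out <- numeric(ns + 1)
    t <- tapply(v[sel], idx[sel], sum)
    out[as.integer(names(t))] <- t
    out
  }
  corr <- sum_by(num) / sqrt(pmax(sum_by(pa) * sum_by(pb), 1e-300))
  cnt <- sum_by(rep(1, length(shell)))
  structure(list(shell_freq = (0:ns) / (n * voxel_size),
                 correlation = corr, shell_counts = cnt,
                 voxel_size = voxel_size),
            class = "fsc_curve")
}

#' @export
print.fsc_curve <- function(x, ...) {
  r5 <- resolution_at_threshold(x, 0.5, x$voxel_size)
  r143 <- resolution_at_threshold(x, 0.143, x$voxel_size)
  cat(sprintf("fsc_curve: %d shells; FSC=0.5 at %.1f A, FSC=0.143 at %.1f A\n",
              length(x$correlation), r5, r143))
  invisible(x)
}

#' Resolution at an FSC threshold
#'
#' The inverse spatial frequency at which the curve first drops below the
#' threshold, with linear interpolation between the bracketing shells. If
#' the curve never crosses, returns the Nyquist resolution `2 * voxel_size`
#' with attribute `never_crossed = TRUE`.
#'
#' @param curve an `fsc_curve` from [compute_fsc()].
#' @param threshold FSC threshold in (0, 1), e.g. 0.5 or 0.143.
#' @param voxel_size Angstrom per voxel; default from the curve.
#' @return resolution in Angstrom.
#' @export
resolution_at_threshold <- function(curve, threshold,
                                    voxel_size = curve$voxel_size) {
  stopifnot(threshold > 0, threshold < 1)
  co <- curve$correlation
  fr <- curve$shell_freq
  for (i in seq_along(co)[-1]) {
    if (co[i] < threshold && co[i - 1] >= threshold) {
      f <- fr[i - 1] + (fr[i] - fr[i - 1]) *
        (co[i - 1] - threshold) / (co[i - 1] - co[i])
      return(1 / f)
    }
  }
  structure(2 * voxel_size, never_crossed = TRUE)
}

#' Local resolution map from two half-maps
#'
#' Windowed FSC: a soft spherical window (cosine-tapered) is applied to both
#' half-maps around evaluation points on a grid with the given sampling
#' (20 A in the reference protocol), the windowed FSC is thresholded, and
#' resolutions are propagated to the full grid by nearest-neighbour
#' interpolation. Values are floored at the Nyquist resolution
#' `2 * voxel_size`.
#'
#' @param map_a,map_b half-maps (3D arrays or [tomogram_volume()]s).
#' @param voxel_size Angstrom per voxel.
#' @param window window diameter in voxels (>= 4), default 24.
#' @param sampling evaluation grid spacing in Angstrom, default 20.
#' @param threshold FSC threshold for the local estimate, default 0.143.
#' @param mask optional mask; only points where it exceeds 0.5 are evaluated.
#' @return a `local_resolution_map`: list with `grid` (A values), `sampling`,
#'   `window` (A), plus `histogram` (resolutions at evaluated points).
#' @export
local_resolution <- function(map_a, map_b, voxel_size = NULL, window = 24,
                             sampling = 20, threshold = 0.143, mask = NULL) {
  ga <- if (inherits(map_a, "tomogram_volume")) map_a$grid else map_a
  gb <- if (inherits(map_b, "tomogram_volume")) map_b$grid else map_b
  if (is.null(voxel_size))
    voxel_size <- if (inherits(map_a, "tomogram_volume")) map_a$voxel_size else 1
  d <- dim(ga)
  window <- as.integer(window)
  if (window < 4) stop("window must be at least 4 voxels")
  if (any(window > d)) stop("window larger than the map")
  stride <- max(1L, as.integer(round(sampling / voxel_size)))
  hw <- window %/% 2
  ax <- ((seq_len(window) - 1) - centre_voxel(window)) * 1
  r <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
  taper <- pmin(pmax((window / 2 - r) / 3, 0), 1)
  wfun <- (1 - cos(pi * taper)) / 2
  centres <- lapply(d, function(n) seq(hw + 1, n - hw, by = stride))
  resg <- array(NA_real_, d)
  vals <- c()
  for (cz in centres[[3]]) for (cy in centres[[2]]) for (cx in centres[[1]]) {
    if (!is.null(mask) && mask[cx, cy, cz] <= 0.5) next
    ix <- (cx - hw):(cx - hw + window - 1)
    iy <- (cy - hw):(cy - hw + window - 1)
    iz <- (cz - hw):(cz - hw + window - 1)
    wa <- ga[ix, iy, iz] * wfun
    wb <- gb[ix, iy, iz] * wfun
    if (max(abs(wa)) == 0 || max(abs(wb)) == 0) next
    fc <- compute_fsc(wa, wb, voxel_size = voxel_size)
    res <- max(resolution_at_threshold(fc, threshold), 2 * voxel_size)
    resg[cx, cy, cz] <- res
    vals <- c(vals, res)
  }
  # nearest-evaluated-point fill of the full grid
  filled <- fill_nearest(resg, centres, d)
  structure(list(grid = filled, sampling = stride * voxel_size,
                 window = window * voxel_size, voxel_size = voxel_size,
                 histogram = vals),
            class = "local_resolution_map")
}

fill_nearest <- function(resg, centres, d) {
  snap <- function(v, cs) cs[pmin(pmax(round((v - cs[1]) / diff(cs[1:2])) + 1,
                                       1), length(cs))]
  if (any(vapply(centres, length, 1L) < 2))
    snap <- function(v, cs) rep(cs[1], length(v))
  ix <- snap(seq_len(d[1]), centres[[1]])
  iy <- snap(seq_len(d[2]), centres[[2]])
  iz <- snap(seq_len(d[3]), centres[[3]])
  out <- resg[ix, iy, iz, drop = FALSE]
  dim(out) <- d
  # points that were skipped (outside mask): use the median of evaluated ones
  if (anyNA(out)) out[is.na(out)] <- stats::median(resg, na.rm = TRUE)
  out
}

#' Locally filter a map to its estimated resolution
#'
#' Implemented as blended band maps: the map is globally low-passed at a
#' ladder of resolutions spanning the local-resolution map, and each voxel
#' linearly interpolates between the two bracketing bands. A constant
#' resolution map therefore reproduces a single global low-pass.
#'
#' @param map a [tomogram_volume()] (or 3D array).
#' @param resmap a [local_resolution()] result (or 3D array of Angstrom
#'   resolutions on the same grid).
#' @param voxel_size Angstrom per voxel.
#' @param n_bands number of low-pass bands, default 12.
#' @return filtered map, same class as the input `map`.
#' @export
local_filter <- function(map, resmap, voxel_size = NULL, n_bands = 12) {
  g <- if (inherits(map, "tomogram_volume")) map$grid else map
  if (is.null(voxel_size))
    voxel_size <- if (inherits(map, "tomogram_volume")) map$voxel_size else 1
  rg <- if (inherits(resmap, "local_resolution_map")) resmap$grid else resmap
  stopifnot(identical(dim(g), dim(rg)))
  rg <- pmax(rg, 2 * voxel_size)
  levels <- sort(unique(c(min(rg), max(rg),
                          exp(seq(log(min(rg)), log(max(rg)),
                                  length.out = n_bands)))))
  bands <- lapply(levels, function(rs) lowpass_volume(g, rs, voxel_size))
  if (length(levels) == 1) {
    out <- bands[[1]]
  } else {
    out <- array(0, dim(g))
    li <- findInterval(rg, levels, rightmost.closed = TRUE)
    li <- pmin(pmax(li, 1), length(levels) - 1)
    hi <- li + 1
    whi <- (rg - levels[li]) / pmax(levels[hi] - levels[li], 1e-9)
    whi <- pmin(pmax(whi, 0), 1)
    for (b in seq_along(levels)) {
      w <- (li == b) * (1 - whi) + (hi == b) * whi
      if (any(w > 0)) out <- out + w * bands[[b]]
    }
  }
  if (inherits(map, "tomogram_volume"))
    tomogram_volume(out, map$voxel_size, origin = map$origin, wedge = map$wedge)
  else out
}

#' Global low-pass filter at a target resolution
#'
#' Fourier filter passing frequencies below `1/resolution` with a raised
#' cosine rolloff two shells wide.
#'
#' @param g 3D array.
#' @param resolution target resolution in Angstrom.
#' @param voxel_size Angstrom per voxel.
#' @return filtered array.
#' @export
lowpass_volume <- function(g, resolution, voxel_size) {
  d <- dim(g)
  n <- d[1]
  if (resolution <= 2 * voxel_size) return(g)
  K <- freq_grid(d)
  fr <- sqrt(colSums(K^2)) / voxel_size        # 1/A
  fc <- 1 / resolution
  soft <- 2 / (n * voxel_size)                 # two Fourier voxels
  w <- pmin(pmax((fc + soft - fr) / soft, 0), 1)
  w <- (1 - cos(pi * w)) / 2
  array(Re(stats::fft(stats::fft(g) * w, inverse = TRUE)) / length(g), d)
}
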