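#' Wedge-weighted subvolume averaging
#'
#' Each subvolume is transformed back into the reference frame (inverse of
#' its alignment rotation and shift, one trilinear resampling) and its
#' Fourier coefficients accumulated together with its rotated binary wedge
#' support. The accumulated coefficients are divided by the accumulated
#' wedge weight (floored at `eps` to avoid division blow-up where no
#' particle contributed) and returned as a real volume: orientation
#' diversity fills the missing wedge.
#'
#' @param subvols list of [extract_subvolume()] results on one grid.
#' @param results list of alignment results (fields `rotation` Euler ZYZ
#'   degrees and `shift` in Angstrom), one per subvolume: the particle sits
#'   at the extraction centre plus `shift`, oriented by `rotation`.
#' @param eps weight floor (in units of particle counts).
#' @return a [tomogram_volume()] with `wedge = "full"`.
#' @export
average_subvolumes <- function(subvols, results, eps = 0.01) {
  stopifnot(length(subvols) == length(results), length(subvols) >= 1)
  d <- dim(subvols[[1]]$grid)
  N <- prod(d)
  K <- freq_grid(d)
  Fsum <- array(0 + 0i, d)
  wsum <- array(0, d)
  for (i in seq_along(subvols)) {
    sv <- subvols[[i]]
    stopifnot(identical(dim(sv$grid), d))
    R <- euler_to_matrix(results[[i]]$rotation)
    svox <- results[[i]]$shift / sv$voxel_size
    ctr <- centre_voxel(d)
    aligned <- array(.resample_affine(as.numeric(sv$grid), d, d, R, ctr, ctr,
                                      svox), d)
    wk <- if (identical(sv$wedge, "full")) 1 else {
      ta <- tan(sv$wedge$max_angle * pi / 180)
      kr <- R %*% K     # wedge support of the rotated subvolume
      array(abs(kr[3, ]) <= abs(kr[1, ]) * ta, d)
    }
    Fsum <- Fsum + stats::fft(aligned) * wk
    wsum <- wsum + wk
  }
  if (any(wsum == 0))
    warning("Fourier regions with zero wedge weight were eps-regularised")
  avg <- Re(stats::fft(Fsum / pmax(wsum, eps), inverse = TRUE)) / N
  tomogram_volume(array(avg, d), subvols[[1]]$voxel_size, wedge = "full")
}

# 3 x N matrix of normalised frequency coordinates (cycles/voxel) in FFT layout
freq_grid <- function(d) {
  f <- lapply(d, function(n) {
    k <- seq_len(n) - 1
    ifelse(k > n / 2, k - n, k) / n
  })
  rbind(rep(f[[1]], times = d[2] * d[3]),
        rep(rep(f[[2]], each = d[1]), times = d[3]),
        rep(f[[3]], each = d[1] * d[2]))
}

#' Split a particle set into tomogram-disjoint half sets
#'
#' Gold-standard half sets: whole tomograms are partitioned into two groups
#' by a greedy balance of particle counts (largest tomogram first, always
#' into the lighter half), so no tomogram contributes to both maps.
#'
#' @param particles a [particle_set()] with at least 2 distinct `tomo_id`s.
#' @return list of two `particle_set`s (`a`, `b`), disjoint, union = input.
#' @export
split_half_sets <- function(particles) {
  counts <- sort(table(particles$tomo_id), decreasing = TRUE)
  if (length(counts) < 2)
    stop("cannot split by tomogram: need at least 2 distinct tomo_ids")
  na <- 0; nb <- 0
  ga <- character(0); gb <- character(0)
  for (i in seq_along(counts)) {
    if (na <= nb) { ga <- c(ga, names(counts)[i]); na <- na + counts[i] }
    else          { gb <- c(gb, names(counts)[i]); nb <- nb + counts[i] }
  }
  a <- particles[as.character(particles$tomo_id) %in% ga, , drop = FALSE]
  b <- particles[as.character(particles$tomo_id) %in% gb, , drop = FALSE]
  rownames(a) <- rownames(b) <- NULL
  class(a) <- class(b) <- c("particle_set", "data.frame")
  list(a = a, b = b)
}
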