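#' Collapse duplicate particles
#'
#' Particles closer than `threshold` are duplicates of the same lattice
#' position. Clusters are the connected components of the threshold-distance
#' graph (single-linkage); each cluster is replaced by one particle at the
#' unweighted cluster centroid carrying the orientation, tomogram id and
#' score of its best-scoring member. In the rare event that two cluster
#' centroids land back within `threshold` of each other the collapse is
#' re-applied, so the result is idempotent and its minimum pairwise distance
#' always exceeds `threshold`.
#'
#' @param particles a [particle_set()].
#' @param threshold collapse distance in Angstrom (> 0), 10 by default.
#' @return a `particle_set` with one particle per cluster (ids renumbered).
#' @export
collapse_duplicates <- function(particles, threshold = 10) {
  stopifnot(threshold > 0)
  # positions are only comparable within one tomogram
  parts <- split(seq_len(nrow(particles)), particles$tomo_id)
  out_list <- lapply(parts, function(ix) {
    p <- particles[ix, , drop = FALSE]
    repeat {
      out <- collapse_once(p, threshold)
      if (nrow(out) == nrow(p)) return(out)
      p <- out
    }
  })
  out <- do.call(rbind, lapply(out_list, as.data.frame))
  if (is.null(out)) return(particles[0, , drop = FALSE])
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("particle_set", "data.frame")
  out
}

collapse_once <- function(particles, threshold) {
  n <- nrow(particles)
  if (n == 0) return(particles)
  if (n == 1) { particles$id <- 1L; return(particles) }
  pos <- particle_positions(particles)
  # single-linkage clusters cut at the threshold = connected components of
  # the threshold-distance graph
  comp <- stats::cutree(stats::hclust(stats::dist(pos), method = "single"),
                        h = threshold)
  sc <- particles$score
  sc[is.na(sc)] <- -Inf
  keep <- vapply(split(seq_len(n), comp),
                 function(ix) ix[which.max(sc[ix])], integer(1))
  out <- particles[keep, , drop = FALSE]
  cent <- t(vapply(split(seq_len(n), comp),
                   function(ix) colMeans(pos[ix, , drop = FALSE]), numeric(3)))
  out$x <- cent[, 1]; out$y <- cent[, 2]; out$z <- cent[, 3]
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("particle_set", "data.frame")
  out
}

#' Filter particles by lattice-neighbour count
#'
#' Retains exactly those particles that have strictly more than
#' `min_neighbors` *other* particles at a 3D Euclidean distance inside the
#' closed annulus `[expected - tol, expected + tol]`. A single,
#' non-iterative pass over the input set: neighbour counts are taken on the
#' input, not on the survivors.
#'
#' @param particles a [particle_set()].
#' @param expected expected lattice neighbour distance (A), 120 by default.
#' @param tol annulus half-width (A), 20 by default; `expected > tol >= 0`.
#' @param min_neighbors retain if neighbour count > this; 3 by default.
#' @return filtered `particle_set`.
#' @export
neighbor_filter <- function(particles, expected = 120, tol = 20,
                            min_neighbors = 3) {
  stopifnot(expected > tol, tol >= 0)
  n <- nrow(particles)
  if (n == 0) return(particles)
  keep <- logical(n)
  for (ix in split(seq_len(n), particles$tomo_id)) {
    dm <- as.matrix(stats::dist(particle_positions(particles[ix, ,
                                                             drop = FALSE])))
    diag(dm) <- Inf
    cnt <- rowSums(dm >= expected - tol & dm <= expected + tol)
    keep[ix] <- cnt > min_neighbors
  }
  out <- particles[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("particle_set", "data.frame")
  out
}

#' Lattice-spacing statistics of a particle set
#'
#' Nearest-neighbour distances, their kernel-smoothed modal value, and the
#' implied array lattice constant. With `mode = "honeycomb"` the particles
#' are ToD axes and the lattice constant is `sqrt(3)` times the modal
#' spacing; with `mode = "centers"` the particles are hexagon centres and the
#' lattice constant equals the modal spacing.
#'
#' @param particles a [particle_set()] with at least 10 particles.
#' @param mode `"honeycomb"` or `"centers"`.
#' @return a `lattice_stats` list: `nn_distances` (A), `modal_spacing` (A),
#'   `lattice_constant` (A), `neighbor_counts` (table of per-particle
#'   neighbour counts within 1/6 of the modal spacing).
#' @export
estimate_lattice_spacing <- function(particles,
                                     mode = c("honeycomb", "centers")) {
  mode <- match.arg(mode)
  n <- nrow(particles)
  if (n < 10) stop("insufficient data: need at least 10 particles")
  nn <- numeric(0)
  d_all <- numeric(0)
  for (ix in split(seq_len(n), particles$tomo_id)) {
    if (length(ix) < 2) next
    dm <- as.matrix(stats::dist(particle_positions(particles[ix, ,
                                                             drop = FALSE])))
    diag(dm) <- Inf
    nn <- c(nn, apply(dm, 1, min))
    d_all <- c(d_all, dm[is.finite(dm)])
  }
  # the mode is taken from all pairwise distances near the NN scale: the
  # min-of-neighbours statistic is biased low under jitter, the symmetric
  # first peak of the full distance histogram is not
  med_nn <- stats::median(nn)
  d_first <- d_all[d_all > 0.6 * med_nn & d_all < 1.45 * med_nn]
  dens <- stats::density(d_first, bw = "SJ", n = 512)
  modal <- dens$x[which.max(dens$y)]
  tol <- modal / 6
  counts <- integer(0)
  for (ix in split(seq_len(n), particles$tomo_id)) {
    if (length(ix) < 2) next
    dm <- as.matrix(stats::dist(particle_positions(particles[ix, ,
                                                             drop = FALSE])))
    diag(dm) <- Inf
    counts <- c(counts, rowSums(dm >= modal - tol & dm <= modal + tol))
  }
  structure(list(nn_distances = nn, modal_spacing = modal,
                 lattice_constant = if (mode == "honeycomb")
                   sqrt(3) * modal else modal,
                 neighbor_counts = table(counts)),
            class = "lattice_stats")
}

#' @export
print.lattice_stats <- function(x, ...) {
  cat(sprintf("lattice_stats: modal NN spacing %.1f A, lattice constant %.1f A (n = %d)\n",
              x$modal_spacing, x$lattice_constant, length(x$nn_distances)))
  invisible(x)
}
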