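#' Render a ground-truth array into a density volume
#'
#' Forward model for the simulator: the motif is rotated by each particle's
#' orientation and accumulated at each particle position, and a membrane
#' density (spherical shell for a sphere-cap surface, slab for a plane,
#' Gaussian profile across the membrane) is added. The model is linear in the
#' particle list. Particles whose motif support leaves the box are clipped
#' with a warning count.
#'
#' @param truth a [place_hex_array()] result.
#' @param motif a [make_csu_motif()] (resampled on the fly if its voxel size
#'   differs).
#' @param voxel_size output voxel size in Angstrom.
#' @param box output dimensions in voxels (scalar or length 3).
#' @param origin Angstrom position of voxel (0,0,0); default centres the
#'   array laterally and places the membrane at a fixed height.
#' @param membrane_amp peak membrane density relative to motif peak 1;
#'   0 disables the membrane.
#' @param membrane_sd Gaussian half-thickness of the membrane profile (A).
#' @return a [tomogram_volume()] with `wedge = "full"`.
#' @export
render_tomogram <- function(truth, motif, voxel_size, box,
                            origin = NULL, membrane_amp = 0.5,
                            membrane_sd = 14) {
  stopifnot(inherits(truth, "ground_truth_array"),
            inherits(motif, "density_motif"), voxel_size > 0)
  box <- as.integer(rep(box, length.out = 3))
  pos <- truth$positions
  n <- nrow(pos)
  if (is.null(origin)) {
    ctr <- if (n > 0) colMeans(pos) else truth$surface$center
    origin <- ctr - (box - 1) * voxel_size / 2
  }
  g <- array(0, box)
  ratio <- voxel_size / motif$voxel_size
  cm <- centre_voxel(dim(motif$grid))
  clipped <- 0L
  for (i in seq_len(n)) {
    R <- euler_to_matrix(truth$orientations[i, ])
    pv <- (pos[i, ] - origin) / voxel_size
    clipped <- clipped +
      .add_motif(g, box, as.numeric(motif$grid), dim(motif$grid),
                 t(R) * ratio, pv, cm)
  }
  dim(g) <- box
  if (clipped > 0)
    warning(sprintf("%d particle(s) clipped at the box boundary", clipped))
  if (membrane_amp > 0 && n >= 0) {
    g <- g + membrane_amp *
      membrane_density(truth$surface, box, voxel_size, origin, membrane_sd)
  }
  tomogram_volume(g, voxel_size, origin = origin, wedge = "full")
}

# Gaussian-profile membrane density on the simulator grid. For a sphere-cap
# the shell is limited to the cap (soft angular edge); for a plane it is a
# slab at the plane height.
membrane_density <- function(surface, box, voxel_size, origin,
                             membrane_sd = 14) {
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(box[a]) - 1) * voxel_size)
  if (surface$kind == "plane") {
    prof <- exp(-(ax[[3]] - surface$center[3])^2 / (2 * membrane_sd^2))
    return(aperm(array(prof, c(box[3], box[1], box[2])), c(2, 3, 1)))
  }
  dx2 <- (ax[[1]] - surface$center[1])^2
  dy2 <- (ax[[2]] - surface$center[2])^2
  dz2 <- (ax[[3]] - surface$center[3])^2
  r2 <- array(dx2, box) +
    aperm(array(dy2, c(box[2], box[1], box[3])), c(2, 1, 3)) +
    aperm(array(dz2, c(box[3], box[1], box[2])), c(2, 3, 1))
  r <- sqrt(r2)
  shell <- exp(-(r - surface$radius)^2 / (2 * membrane_sd^2))
  # soft cap-edge cutoff on the angle to the cap axis
  axv <- surface$axis
  dot <- array(0, box)
  for (a in 1:3) {
    comp <- ax[[a]] - surface$center[a]
    perm <- switch(a, array(comp, box),
                   aperm(array(comp, c(box[2], box[1], box[3])), c(2, 1, 3)),
                   aperm(array(comp, c(box[3], box[1], box[2])), c(2, 3, 1)))
    dot <- dot + axv[a] * perm
  }
  ang <- acos(pmax(-1, pmin(1, dot / pmax(r, 1e-9)))) * 180 / pi
  edge <- 1 / (1 + exp((ang - surface$extent) / 1.5))
  shell * edge
}

#' Render an alignment reference from a motif
#'
#' Embeds the motif (and optionally its lattice neighbours and a flat
#' membrane slab at the motif membrane height z = 0) at the centre of a cubic
#' box, producing the external reference used for constrained alignment.
#'
#' @param motif a [make_csu_motif()].
#' @param box cube side in voxels.
#' @param voxel_size Angstrom per voxel.
#' @param membrane_amp membrane slab amplitude (0 disables).
#' @param membrane_sd slab Gaussian half-thickness (A).
#' @param neighbours optional n x 2 matrix of in-plane (x, y) Angstrom
#'   offsets of additional motif copies; use
#'   `hex_neighbour_offsets(spacing)` for the six lattice neighbours of a
#'   multi-CSU reference.
#' @return a [tomogram_volume()] with `wedge = "full"`.
#' @export
render_reference <- function(motif, box, voxel_size = motif$voxel_size,
                             membrane_amp = 0.5, membrane_sd = 14,
                             neighbours = NULL) {
  box <- as.integer(rep(box, length.out = 3))
  g <- array(0, box)
  ratio <- voxel_size / motif$voxel_size
  cm <- centre_voxel(dim(motif$grid))
  ctr <- centre_voxel(box)
  offs <- rbind(c(0, 0), neighbours)
  for (i in seq_len(nrow(offs))) {
    pv <- ctr + c(offs[i, 1], offs[i, 2], 0) / voxel_size
    .add_motif(g, box, as.numeric(motif$grid), dim(motif$grid),
               diag(3) * ratio, pv, cm)
  }
  dim(g) <- box
  if (membrane_amp > 0) {
    z <- ((seq_len(box[3]) - 1) - ctr[3]) * voxel_size
    prof <- exp(-z^2 / (2 * membrane_sd^2))
    g <- g + membrane_amp *
      aperm(array(prof, c(box[3], box[1], box[2])), c(2, 3, 1))
  }
  tomogram_volume(g, voxel_size, wedge = "full")
}

#' @rdname render_reference
#' @param spacing lattice nearest-neighbour distance in Angstrom.
#' @export
hex_neighbour_offsets <- function(spacing) {
  ang <- (0:5) * pi / 3
  cbind(spacing * cos(ang), spacing * sin(ang))
}

#' Render a curved multi-CSU array-model reference
#'
#' Builds the initial reference the way the pipeline models it: the motif
#' placed coherently with its lattice neighbours on the (fitted) spherical
#' membrane, rendered with the membrane shell, with the central particle at
#' the cube centre and its normal along +z. Matching the membrane curvature
#' removes the axial bias a flat-slab reference induces when the alignment
#' mask spans neighbouring CSUs; rendered at a box larger than the
#' alignment box, it also serves as the context reference of
#' [cone_angular_search()].
#'
#' @param motif a [make_csu_motif()].
#' @param radius fitted membrane sphere radius (A); `Inf` renders the model
#'   on a planar membrane instead.
#' @param nn_spacing lattice nearest-neighbour distance (A).
#' @param box cube side in voxels.
#' @param voxel_size Angstrom per voxel.
#' @param membrane_amp membrane amplitude relative to motif peak.
#' @return a [tomogram_volume()] reference.
#' @export
make_array_reference <- function(motif, radius, nn_spacing,
                                 box, voxel_size = motif$voxel_size,
                                 membrane_amp = 0.5) {
  box <- as.integer(rep(box, length.out = 3))
  # cover the box diagonal so larger context boxes include further shells
  span <- max(2.6 * nn_spacing, 1.6 * max(box) * voxel_size)
  surf <- if (is.finite(radius))
    membrane_surface("sphere-cap", center = c(0, 0, -radius), radius = radius,
                     extent = span / 2 / radius * 180 / pi)
  else
    membrane_surface("plane", extent = c(span, span))
  truth <- place_hex_array(surf, nn_spacing / sqrt(3), jitter_sd = 0,
                           sites = "centers", inplane = "lattice",
                           lattice_azimuth = 0, seed = 1)
  origin <- -centre_voxel(box) * voxel_size  # particle (0,0,0) at centre voxel
  suppressWarnings(
    render_tomogram(truth, motif, voxel_size, box, origin = origin,
                    membrane_amp = membrane_amp))
}
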