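#' Tomogram volume container
#'
#' A `tomogram_volume` is a 3D scalar density grid with a voxel size in
#' Angstrom, an origin (Angstrom position of the centre of voxel `[1,1,1]`,
#' i.e. 0-based voxel index 0) and attached wedge metadata: either the string
#' `"full"` (isotropically sampled) or the [make_tilt_scheme()] that produced
#' it, from which the missing-wedge geometry follows.
#'
#' @param grid 3D numeric array.
#' @param voxel_size voxel edge length in Angstrom (> 0).
#' @param origin length-3 Angstrom offset of voxel (0,0,0); default zeros.
#' @param wedge `"full"` or a `tilt_scheme`.
#' @return an object of class `tomogram_volume`.
#' @export
tomogram_volume <- function(grid, voxel_size, origin = c(0, 0, 0), wedge = "full") {
  stopifnot(is.array(grid), length(dim(grid)) == 3)
  if (!is.numeric(voxel_size) || voxel_size <= 0) stop("voxel_size must be > 0")
  if (any(dim(grid) < 2)) stop("grid must be at least 2 voxels in each axis")
  if (!(identical(wedge, "full") || inherits(wedge, "tilt_scheme")))
    stop("wedge must be \"full\" or a tilt_scheme")
  structure(list(grid = grid, voxel_size = voxel_size,
                 origin = as.numeric(origin), wedge = wedge),
            class = "tomogram_volume")
}

#' @export
print.tomogram_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("tomogram_volume: %d x %d x %d voxels @ %.3f A, wedge: %s\n",
              d[1], d[2], d[3], x$voxel_size,
              if (identical(x$wedge, "full")) "full"
              else sprintf("+/-%g deg", x$wedge$max_angle)))
  invisible(x)
}

#' Parametric pseudo-CSU density motif
#'
#' A stand-in for the core-signalling-unit density used throughout the test
#' pipeline: two membrane-normal cylinders (the receptor trimer-of-dimer
#' pair of one CSU, separated by `tod_spacing` along x) that span the
#' membrane, plus a cytoplasmic baseplate disc (the CheA/CheW layer). The
#' motif is C2-symmetric about +z, which is the membrane normal; z = 0 at the
#' motif centre is the membrane mid-plane.
#'
#' @param voxel_size Angstrom per voxel, default 4.48 (2.24 A pixels binned
#'   by two).
#' @param box cube side in voxels, default 48.
#' @param tod_spacing separation of the two receptor cylinders in Angstrom.
#' @param cyl_radius receptor cylinder radius (A).
#' @param z_top,z_bottom axial extent of the cylinders relative to the
#'   membrane mid-plane (A); baseplate disc sits at `z_bottom`.
#' @param plate_radius baseplate disc radius (A).
#' @param soft_sd Gaussian edge softening (A).
#' @return a `density_motif`: list with `grid`, `voxel_size`,
#'   `symmetry = "C2"`.
#' @export
make_csu_motif <- function(voxel_size = 4.48, box = 48, tod_spacing = 74,
                           cyl_radius = 14, z_top = 30, z_bottom = -100,
                           plate_radius = 52, soft_sd = 6) {
  n <- as.integer(box)
  c0 <- floor(n / 2)                       # 0-based centre voxel
  ax <- (seq_len(n) - 1 - c0) * voxel_size
  x <- array(ax, c(n, n, n))
  y <- aperm(x, c(2, 1, 3))
  z <- aperm(x, c(3, 2, 1))
  soft <- function(d) exp(-pmax(d, 0)^2 / (2 * soft_sd^2))
  g <- array(0, c(n, n, n))
  for (s in c(-1, 1)) {
    r <- sqrt((x - s * tod_spacing / 2)^2 + y^2)
    zc <- pmax(z - z_top, z_bottom - z, 0)
    g <- g + soft(r - cyl_radius) * soft(zc)
  }
  rp <- sqrt(x^2 + y^2)
  zp <- abs(z - z_bottom) - 8
  g <- g + 0.8 * soft(rp - plate_radius) * soft(zp)
  structure(list(grid = g, voxel_size = voxel_size, symmetry = "C2"),
            class = "density_motif")
}

# 0-based centre voxel index used everywhere (FFT-consistent convention)
centre_voxel <- function(n) floor(n / 2)

#' Read and write MRC2014 volumes
#'
#' Mode-2 (float32) MRC2014 files. The voxel size is stored in the cell
#' dimensions (`cella = m * voxel_size`) and the Angstrom origin in the
#' `origin` header words. Reading validates the `MAP ` magic, mode and
#' dimensions and fails with the offending field named.
#'
#' @param vol a [tomogram_volume()] (its wedge metadata is not persisted).
#' @param path file path.
#' @return `read_mrc` returns a `tomogram_volume` with `wedge = "full"`.
#' @export
write_mrc <- function(vol, path) {
  stopifnot(inherits(vol, "tomogram_volume"))
  d <- dim(vol$grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                       # nx ny nz
  wi(2)                       # mode 2 = float32
  wi(c(0, 0, 0))              # nxstart
  wi(d)                       # mx my mz
  wf(d * vol$voxel_size)      # cella
  wf(c(90, 90, 90))           # cellb
  wi(c(1, 2, 3))              # mapc mapr maps
  g <- vol$grid
  wf(c(min(g), max(g), mean(g)))
  wi(1)                       # ispg: volume
  wi(0)                       # nsymbt
  writeBin(raw(100), con)     # extra
  wf(vol$origin)              # origin (A)
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(stats::sd(g))
  wi(0)                       # nlabl
  writeBin(raw(800), con)     # labels
  writeBin(as.numeric(g), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_mrc
#' @export
read_mrc <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1024) stop("MRC format error: file shorter than header")
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  ri(3)
  m <- ri(3)
  cella <- rf(3)
  rf(3); ri(3); rf(3); ri(1)
  nsymbt <- ri(1)
  readBin(con, "raw", 100)
  origin <- rf(3)
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "MAP ")) stop("MRC format error: missing MAP magic")
  if (any(d < 1) || any(d > 1e4)) stop("MRC format error: bad dimensions nx/ny/nz")
  if (mode != 2) stop("MRC format error: unsupported mode (only mode 2 float32)")
  if (any(m < 1)) stop("MRC format error: bad sampling mx/my/mz")
  vs <- cella / m
  if (max(abs(vs - vs[1])) > 1e-3)
    stop("MRC format error: anisotropic voxel size in cella")
  nvox <- prod(d)
  if (sz < 1024 + nsymbt + 4 * nvox) stop("MRC format error: truncated data block")
  seek(con, 1024 + nsymbt)
  g <- readBin(con, "numeric", nvox, size = 4, endian = "little")
  tomogram_volume(array(g, d), vs[1], origin = origin, wedge = "full")
}
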