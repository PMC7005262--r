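#' Particle set tables
#'
#' A `particle_set` is a data frame with one row per particle and columns
#' `id`, `tomo_id`, `x`, `y`, `z` (Angstrom), `eul1`, `eul2`, `eul3`
#' (ZYZ intrinsic Euler angles, degrees) and `score` (normalised correlation,
#' NA before alignment). This is the object every seeding, alignment and
#' curation stage transforms.
#'
#' @param positions n x 3 matrix, Angstrom.
#' @param orientations n x 3 matrix of Euler triplets (degrees).
#' @param tomo_id tomogram identifier(s), recycled.
#' @param score numeric score(s), recycled; default NA.
#' @param id particle ids; default 1..n.
#' @return a `particle_set` data frame.
#' @export
particle_set <- function(positions, orientations = NULL, tomo_id = 1L,
                         score = NA_real_, id = NULL) {
  positions <- rbind(positions)
  n <- nrow(positions)
  if (is.null(orientations)) orientations <- matrix(0, n, 3)
  orientations <- rbind(orientations)
  stopifnot(nrow(orientations) == n, all(is.finite(positions)))
  if (is.null(id)) id <- seq_len(n)
  if (anyDuplicated(id)) stop("particle ids must be unique")
  df <- data.frame(id = id,
                   tomo_id = rep(tomo_id, length.out = n),
                   x = positions[, 1], y = positions[, 2], z = positions[, 3],
                   eul1 = orientations[, 1], eul2 = orientations[, 2],
                   eul3 = orientations[, 3],
                   score = rep(score, length.out = n))
  class(df) <- c("particle_set", "data.frame")
  df
}

empty_particle_set <- function() {
  particle_set(matrix(numeric(0), ncol = 3))
}

particle_positions <- function(p) as.matrix(p[, c("x", "y", "z")])
particle_orientations <- function(p) as.matrix(p[, c("eul1", "eul2", "eul3")])

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("particle_set: %d particles, %d tomogram(s)\n",
              nrow(x), length(unique(x$tomo_id))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Read and write tab-separated particle tables
#'
#' Lossless round trip of a [particle_set()]. The file carries comment
#' headers stamping the position unit and Euler convention; files declaring
#' `# units: nm` are converted to Angstrom (x10) on read.
#'
#' @param particles a `particle_set`.
#' @param path file path.
#' @return `read_particles` returns a `particle_set`.
#' @export
write_particles <- function(particles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# units: angstrom", "# euler: zyz-intrinsic-deg"), con)
  utils::write.table(as.data.frame(particles), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_particles
#' @export
read_particles <- function(path) {
  hdr <- readLines(path, n = 10)
  unit <- 1
  if (any(grepl("^#\\s*units:\\s*nm", hdr))) unit <- 10
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  req <- c("id", "tomo_id", "x", "y", "z", "eul1", "eul2", "eul3")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("particle table schema error: missing column(s) ",
         paste(miss, collapse = ", "))
  if (!"score" %in% names(df)) df$score <- NA_real_
  particle_set(cbind(df$x, df$y, df$z) * unit,
               cbind(df$eul1, df$eul2, df$eul3),
               tomo_id = df$tomo_id, score = df$score, id = df$id)
}
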