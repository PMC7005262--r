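# smallest integer >= n with prime factors in {2, 3, 5, 7} (fast FFT sizes)
good_fft_size <- function(n) {
  n <- as.integer(n)
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L, 7L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

#' Pipeline configuration
#'
#' All stage parameters of the end-to-end synthetic pipeline, mirroring the
#' module defaults: 573 A boxes, 60 A shifts, 60 degree cone, 10 A duplicate
#' collapse, neighbour filter 120 +/- 20 A with more than 3 neighbours, FSC
#' thresholds 0.5 and 0.143, 20 A local-resolution sampling. Unknown keys in
#' `...` are rejected.
#'
#' @param ... overrides of the defaults listed below.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    rng_seed = 1L,
    # simulator
    n_tomograms = 6L, surface = "sphere-cap", radius = 2000, cap_extent = 19,
    patch_extent = 1200, nn_spacing = 120,
    jitter_sd = 0, snr = 0.3, voxel = 4.48, max_tilt = 60, tilt_step = 2,
    tilt_group = 5L, membrane_amp = 0.5,
    # seeding
    seed_spacing = 30, annotation_sd = 2, n_annotations = 60,
    # alignment
    box = 573, shift_limit = 60, cone = 60, angular_step = 10,
    stage1_iterations = 1L, stage2_iterations = 2L, mask_radius = 120,
    sym = 2L, reference = "motif",
    # curation
    dup_threshold = 10, expected = 120, tol = 20, min_neighbors = 3L,
    # validation
    fsc_thresholds = c(0.5, 0.143), localres_sampling = 20,
    localres_window = 24)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown pipeline_config key(s): ", paste(unknown, collapse = ", "))
  structure(utils::modifyList(cfg, dots), class = "pipeline_config")
}

#' Simulate a set of array tomograms with ground truth
#'
#' One spherical-cap array per tomogram (CSU-scale particles on a triangular
#' lattice with `nn_spacing` nearest-neighbour distance), rendered with the
#' pseudo-CSU motif, degraded by the missing wedge of the configured tilt
#' scheme and by additive noise at the configured SNR.
#'
#' @param config a [pipeline_config()].
#' @param motif optional [make_csu_motif()]; default built at the configured
#'   voxel size.
#' @return list with `tomograms` (named list of [tomogram_volume()]),
#'   `truth` (a [particle_set()] of all true particles), `surfaces` (list of
#'   true [membrane_surface()]s), `scheme`, `motif`.
#' @export
simulate_tomogram_set <- function(config, motif = NULL) {
  if (is.null(motif)) motif <- make_csu_motif(voxel_size = config$voxel)
  scheme <- make_tilt_scheme(config$max_tilt, config$tilt_step,
                             config$tilt_group)
  tomograms <- list()
  surfaces <- list()
  truth_list <- list()
  nv_box <- as.integer(round(config$box / config$voxel))
  for (t in seq_len(config$n_tomograms)) {
    if (identical(config$surface, "plane")) {
      surf <- membrane_surface("plane", center = c(0, 0, 0),
                               extent = rep(config$patch_extent, 2))
      lat <- config$patch_extent / 2
      sag <- 0
    } else {
      surf <- membrane_surface("sphere-cap", center = c(0, 0, -config$radius),
                               radius = config$radius,
                               extent = config$cap_extent)
      lat <- config$radius * sin(config$cap_extent * pi / 180)
      sag <- config$radius * (1 - cos(config$cap_extent * pi / 180))
    }
    truth <- place_hex_array(surf, config$nn_spacing / sqrt(3),
                             jitter_sd = config$jitter_sd,
                             seed = config$rng_seed * 1000L + t,
                             sites = "centers")
    box <- c(rep(2 * lat + nv_box * config$voxel, 2),
             sag + 260 + nv_box * config$voxel) / config$voxel
    box <- vapply(ceiling(box), good_fft_size, integer(1))
    origin <- c(-box[1:2] * config$voxel / 2,
                -(sag + 130 + nv_box * config$voxel / 2))
    vol <- render_tomogram(truth, motif, config$voxel, box, origin = origin,
                           membrane_amp = config$membrane_amp)
    vol <- apply_missing_wedge(vol, scheme)
    if (is.finite(config$snr))
      vol <- add_noise(vol, config$snr, seed = config$rng_seed * 2000L + t)
    tomograms[[as.character(t)]] <- vol
    surfaces[[t]] <- surf
    truth_list[[t]] <- particle_set(truth$positions, truth$orientations,
                                    tomo_id = t)
  }
  truth_all <- do.call(rbind, lapply(truth_list, as.data.frame))
  truth_all$id <- seq_len(nrow(truth_all))
  class(truth_all) <- c("particle_set", "data.frame")
  list(tomograms = tomograms, truth = truth_all, surfaces = surfaces,
       scheme = scheme, motif = motif)
}

#' Simulate a stack of single-particle subvolumes
#'
#' Renders the motif at random orientations (uniform axis on the sphere,
#' uniform in-plane angle) into cubic subvolumes, applies the missing wedge
#' and per-particle noise. The orientational diversity mimics particles
#' picked from a curved membrane and fills the wedge in the average.
#'
#' @param n number of particles.
#' @param motif a [make_csu_motif()].
#' @param box cube side in voxels.
#' @param snr per-particle signal-to-noise ratio (Inf for noise-free).
#' @param scheme a [make_tilt_scheme()] (or NULL for no wedge).
#' @param seed RNG seed.
#' @param tomo_id tomogram ids assigned round-robin (vector).
#' @param max_tilt_axis maximum particle-axis tilt from +z in degrees
#'   (90 = full hemisphere).
#' @return list with `subvols`, `results` (ground-truth alignment results)
#'   and `particles` (a [particle_set()]).
#' @export
simulate_particle_stack <- function(n, motif, box = 48, snr = 0.3,
                                    scheme = make_tilt_scheme(60, 2, 5),
                                    seed = 1, tomo_id = 1:6,
                                    max_tilt_axis = 60) {
  set.seed(seed)
  vs <- motif$voxel_size
  wedge_v <- if (is.null(scheme)) "full" else scheme
  subvols <- vector("list", n)
  results <- vector("list", n)
  eulers <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    ct <- stats::runif(1, cos(max_tilt_axis * pi / 180), 1)
    th <- acos(ct)
    ph <- stats::runif(1, 0, 2 * pi)
    axis <- c(sin(th) * cos(ph), sin(th) * sin(ph), ct)
    eul <- euler_from_axis(axis, stats::runif(1, 0, 360))
    eulers[i, ] <- eul
    g <- array(0, rep(box, 3))
    .add_motif(g, rep(box, 3L), as.numeric(motif$grid), dim(motif$grid),
               t(euler_to_matrix(eul)), centre_voxel(rep(box, 3L)),
               centre_voxel(dim(motif$grid)))
    dim(g) <- rep(box, 3L)
    vol <- tomogram_volume(g, vs)
    if (!is.null(scheme)) vol <- apply_missing_wedge(vol, scheme)
    if (is.finite(snr)) vol <- add_noise(vol, snr, seed = seed * 10000L + i)
    subvols[[i]] <- structure(list(grid = vol$grid, voxel_size = vs,
                                   source_position = c(0, 0, 0),
                                   tomo_id = tomo_id[(i - 1) %% length(tomo_id) + 1],
                                   wedge = wedge_v),
                              class = "subvolume")
    results[[i]] <- list(rotation = eul, shift = c(0, 0, 0), score = NA_real_)
  }
  particles <- particle_set(matrix(0, n, 3), eulers,
                            tomo_id = tomo_id[(seq_len(n) - 1) %% length(tomo_id) + 1])
  list(subvols = subvols, results = results, particles = particles)
}

#' Run the full synthetic pipeline
#'
#' simulate -> fit surface -> seed -> align (stage 1) -> collapse duplicates
#' -> lattice neighbour filter -> local refinement (stage 2) -> half-set
#' split -> wedge-weighted averaging -> FSC -> local resolution -> local
#' filtering -> C2 symmetrisation, writing per-stage artifacts and a
#' machine-readable JSON report. Fully reproducible for a fixed
#' `config$rng_seed`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir artifact directory (created if missing); NULL disables
#'   artifact writing.
#' @return the report (invisibly also written as `report.json`): particle
#'   counts per stage, FSC resolutions, lattice statistics, C2 score.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  report <- list(config_seed = config$rng_seed)

  sim <- stage("simulate", simulate_tomogram_set(config))
  report$simulate <- list(n_tomograms = length(sim$tomograms),
                          n_true_particles = nrow(sim$truth))
  if (!is.null(out_dir))
    write_particles(sim$truth, file.path(out_dir, "truth.tsv"))

  # surface fit from noisy membrane annotations, then dense seeding (a
  # planar world uses the known plane: there is nothing to fit)
  seeds_list <- list()
  surfaces_fit <- list()
  for (t in seq_along(sim$tomograms)) {
    stage("seed-surface", {
      if (identical(config$surface, "plane")) {
        surf <- sim$surfaces[[t]]
      } else {
        set.seed(config$rng_seed * 3000L + t)
        truth_t <- sim$truth[sim$truth$tomo_id == t, , drop = FALSE]
        ann_ix <- sample(nrow(truth_t), min(config$n_annotations,
                                            nrow(truth_t)))
        ann <- particle_positions(truth_t)[ann_ix, , drop = FALSE] +
          matrix(stats::rnorm(3 * length(ann_ix), 0, config$annotation_sd),
                 ncol = 3)
        surf <- fit_sphere(ann)
      }
      surfaces_fit[[t]] <- surf
      # seed the annotated region: the angular radius of the annotation
      # cloud about the fitted cap axis (an extent fixed in degrees would
      # over- or under-cover the array whenever the radius is misfitted)
      region <- NULL
      if (!identical(config$surface, "plane")) {
        dvec <- sweep(ann, 2, surf$center)
        ang <- acos(pmin(1, (dvec %*% surf$axis) /
                           sqrt(rowSums(dvec^2))))
        region <- max(ang) * 180 / pi + 1
      }
      s <- sample_seed_positions(surf, config$seed_spacing, region = region)
      s$tomo_id <- t
      seeds_list[[t]] <- as.data.frame(s)
    })
  }
  seeds <- do.call(rbind, seeds_list)
  seeds$id <- seq_len(nrow(seeds))
  class(seeds) <- c("particle_set", "data.frame")
  report$seed <- list(n_seeds = nrow(seeds),
                      mean_spacing = config$seed_spacing)
  if (!is.null(out_dir)) write_particles(seeds, file.path(out_dir, "seeds.tsv"))

  rcfg <- refinement_config(
    box = config$box, shift_limit = config$shift_limit,
    duplicate_threshold = config$dup_threshold,
    mask_radius = config$mask_radius, sym = config$sym,
    stage1 = list(cone = 0, angular_step = config$angular_step,
                  inplane_step = config$angular_step,
                  iterations = config$stage1_iterations),
    stage2 = list(iterations = config$stage2_iterations,
                  inplane_step = 2, inplane_range = 18,
                  shift_limit = config$shift_limit))
  nv <- as.integer(round(config$box / config$voxel))
  reference <- if (identical(config$reference, "motif")) {
    rad <- if (identical(config$surface, "plane")) Inf
           else mean(vapply(surfaces_fit, function(s) s$radius, numeric(1)))
    ctx <- good_fft_size(as.integer(ceiling(1.5 * nv)))
    make_array_reference(sim$motif, rad, config$expected, ctx, config$voxel,
                         membrane_amp = config$membrane_amp)
  } else NULL

  aligned <- stage("align", {
    res <- iterative_refine(seeds, sim$tomograms, rcfg,
                            reference = reference, stages = 1)
    res$particles
  })
  report$align <- list(n_particles = nrow(aligned),
                       mean_score = mean(aligned$score))
  if (!is.null(out_dir))
    write_particles(aligned, file.path(out_dir, "aligned_stage1.tsv"))

  cleaned <- stage("clean", {
    dedup <- collapse_duplicates(aligned, config$dup_threshold)
    neighbor_filter(dedup, config$expected, config$tol, config$min_neighbors)
  })
  report$clean <- list(n_after_dedup = nrow(collapse_duplicates(
    aligned, config$dup_threshold)), n_after_neighbor = nrow(cleaned))
  lat <- stage("lattice", estimate_lattice_spacing(cleaned, mode = "centers"))
  report$lattice <- list(modal_spacing = lat$modal_spacing,
                         lattice_constant_centers = lat$lattice_constant)
  if (!is.null(out_dir))
    write_particles(cleaned, file.path(out_dir, "cleaned.tsv"))

  refined <- stage("refine", iterative_refine(
    cleaned, sim$tomograms, rcfg, reference = reference,
    surface = stats::setNames(surfaces_fit, names(sim$tomograms)),
    stages = 2))
  # near-duplicates that survived the first collapse because of stage-1
  # position scatter converge onto one spot during local refinement;
  # collapse them again before reconstruction and lattice analysis
  final_particles <- stage("refine", collapse_duplicates(
    refined$particles, config$dup_threshold))
  report$refine <- list(n_particles = nrow(final_particles),
                        n_before_final_dedup = nrow(refined$particles),
                        mean_score = mean(final_particles$score))
  lat2 <- stage("lattice", estimate_lattice_spacing(final_particles,
                                                    mode = "centers"))
  report$lattice_final <- list(modal_spacing = lat2$modal_spacing)
  if (!is.null(out_dir)) {
    write_particles(final_particles, file.path(out_dir, "refined.tsv"))
    write_mrc(refined$average, file.path(out_dir, "average.mrc"))
  }

  halves <- stage("fsc", split_half_sets(final_particles))
  half_avg <- function(p) {
    subs <- lapply(seq_len(nrow(p)), function(i)
      extract_subvolume(sim$tomograms[[as.character(p$tomo_id[i])]],
                        c(p$x[i], p$y[i], p$z[i]), config$box,
                        tomo_id = p$tomo_id[i]))
    res <- lapply(seq_len(nrow(p)), function(i)
      list(rotation = as.numeric(particle_orientations(p)[i, ]),
           shift = c(p$x[i], p$y[i], p$z[i]) - subs[[i]]$source_position))
    average_subvolumes(subs, res)
  }
  map_a <- stage("fsc", half_avg(halves$a))
  map_b <- stage("fsc", half_avg(halves$b))
  fsc_mask <- make_cylinder_mask(nv, config$voxel, config$mask_radius,
                                 -120, -15)
  curve <- stage("fsc", compute_fsc(map_a, map_b, mask = fsc_mask))
  res05 <- resolution_at_threshold(curve, config$fsc_thresholds[1])
  res143 <- resolution_at_threshold(curve, config$fsc_thresholds[2])
  report$fsc <- list(n_half_a = nrow(halves$a), n_half_b = nrow(halves$b),
                     resolution_05 = as.numeric(res05),
                     resolution_0143 = as.numeric(res143))
  if (!is.null(out_dir)) {
    utils::write.table(
      data.frame(freq = curve$shell_freq, fsc = curve$correlation),
      file.path(out_dir, "fsc.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
    write_mrc(map_a, file.path(out_dir, "half_a.mrc"))
    write_mrc(map_b, file.path(out_dir, "half_b.mrc"))
  }

  lres <- stage("localres", local_resolution(
    map_a, map_b, voxel_size = config$voxel,
    window = config$localres_window, sampling = config$localres_sampling,
    mask = fsc_mask))
  report$localres <- list(median = stats::median(lres$histogram),
                          min = min(lres$histogram), max = max(lres$histogram))
  filtered <- stage("localfilter", local_filter(refined$average, lres))
  sym <- stage("symmetrize", symmetrize_c2(filtered))
  report$symmetrize <- list(score = attr(sym, "score"),
                            axis = as.numeric(attr(sym, "axis")))
  if (!is.null(out_dir)) {
    utils::write.table(data.frame(resolution = lres$histogram),
                       file.path(out_dir, "localres_histogram.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_mrc(sym, file.path(out_dir, "final_c2.mrc"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  invisible(report)
}
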