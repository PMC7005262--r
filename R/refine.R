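`%||%` <- function(a, b) if (is.null(a)) b else a

#' Refinement configuration
#'
#' Bundles the two-stage masked iterative alignment parameters. Stage 1
#' aligns inside a soft cylinder covering a multi-CSU footprint plus the
#' membrane slab; stage 2 refines locally inside the same cylinder cropped
#' below the membrane (three CSUs, no membrane) with a tighter cone.
#' Defaults follow the reference protocol: 573 A boxes, 60 A translational
#' freedom per axis, a 60-degree cone at picking, 10 A duplicate collapse.
#'
#' @param box subvolume side in Angstrom.
#' @param shift_limit translational freedom per axis (A).
#' @param duplicate_threshold duplicate collapse distance (A).
#' @param mask_radius alignment cylinder radius (A).
#' @param sym in-plane symmetry order of the reference (2: C2 motif).
#' @param stage1,stage2 per-stage parameter lists; entries `cone`,
#'   `angular_step`, `inplane_step`, `inplane_range`, `iterations`,
#'   `z_range` (mask axial range, A), `renormal` (re-derive the orientation
#'   axis from the fitted surface normal at the aligned position), `bin`
#'   (search binning factor), `context` (use the context-reference path),
#'   `lowpass` (matched low-pass in Angstrom applied to reference and
#'   subvolume before scoring; NULL disables).
#' @param score_tol early-stop tolerance on the mean-score change.
#' @param divergence_tol abort if the mean score drops by more than this.
#' @param update_reference rebuild the reference from the aligned particles
#'   after each iteration.
#' @return a `refinement_config` list.
#' @export
refinement_config <- function(box = 573, shift_limit = 60,
                              duplicate_threshold = 10, mask_radius = 120,
                              sym = 2,
                              stage1 = list(), stage2 = list(),
                              score_tol = 1e-4, divergence_tol = 0.05,
                              update_reference = FALSE) {
  s1 <- utils::modifyList(list(cone = 60, angular_step = 10,
                               inplane_step = 10, inplane_range = 360,
                               iterations = 1, z_range = c(-120, 45),
                               renormal = FALSE, shift_limit = shift_limit,
                               bin = 2L, context = FALSE, lowpass = 40),
                          stage1)
  s2 <- utils::modifyList(list(cone = 0, angular_step = 4, inplane_step = 1,
                               inplane_range = 16, iterations = 1,
                               z_range = c(-120, -15), renormal = TRUE,
                               shift_limit = shift_limit / 4, bin = 1L,
                               context = TRUE, lowpass = NULL),
                          stage2)
  structure(list(box = box, shift_limit = shift_limit,
                 duplicate_threshold = duplicate_threshold,
                 mask_radius = mask_radius, sym = sym,
                 stages = list(s1, s2), score_tol = score_tol,
                 divergence_tol = divergence_tol,
                 update_reference = update_reference),
            class = "refinement_config")
}

#' Two-stage masked iterative subvolume alignment
#'
#' Runs the constrained angular/translational alignment of every particle
#' against a reference, iterating until the mean score change falls below
#' the tolerance or the iteration budget is spent. Stage selection (masks,
#' cone) comes from the [refinement_config()]. With a fitted surface
#' supplied, stages flagged `renormal` re-derive each particle's orientation
#' axis from the surface normal at its aligned position, keeping the fitted
#' in-plane angle (the membrane constrains the axis far better than the
#' per-particle search).
#'
#' @param particles a [particle_set()] of seeded or pre-aligned particles.
#' @param tomograms named list of [tomogram_volume()]s; names are
#'   `tomo_id`s.
#' @param config a [refinement_config()].
#' @param reference external initial reference ([tomogram_volume()] or 3D
#'   array); if NULL, the mean of the seeded subvolumes is used.
#' @param surface optional [membrane_surface()] (or list of surfaces keyed
#'   by `tomo_id`) for `renormal` stages.
#' @param stages which stages of `config$stages` to run (default all).
#' @param verbose print per-iteration mean scores.
#' @return list with `particles` (aligned, scores filled), `average`
#'   (final wedge-weighted average), `history` (mean score per iteration).
#' @export
iterative_refine <- function(particles, tomograms, config, reference = NULL,
                             surface = NULL, stages = seq_along(config$stages),
                             verbose = FALSE) {
  stopifnot(inherits(config, "refinement_config"), nrow(particles) >= 1)
  if (inherits(tomograms, "tomogram_volume")) tomograms <- list(`1` = tomograms)
  vs <- tomograms[[1]]$voxel_size
  nv <- as.integer(round(config$box / vs))
  get_tomo <- function(id) {
    t <- tomograms[[as.character(id)]]
    if (is.null(t)) stop("no tomogram with id ", id)
    t
  }
  extract_all <- function(p) {
    lapply(seq_len(nrow(p)), function(i)
      extract_subvolume(get_tomo(p$tomo_id[i]), c(p$x[i], p$y[i], p$z[i]),
                        config$box, tomo_id = p$tomo_id[i]))
  }
  if (is.null(reference)) {
    subs <- extract_all(particles)
    res0 <- lapply(seq_len(nrow(particles)), function(i)
      list(rotation = as.numeric(particle_orientations(particles)[i, ]),
           shift = c(0, 0, 0)))
    reference <- average_subvolumes(subs, res0)
  }
  # the reference may be larger than the alignment box: the centre crop is
  # used for plain scoring, the full grid for context-bearing refinement
  ref_full <- if (inherits(reference, "tomogram_volume")) reference$grid
              else reference
  stopifnot(all(dim(ref_full) >= nv))
  ref <- crop_centre(ref_full, rep(nv, 3L))
  history <- numeric(0)
  prev_mean <- -Inf
  for (si in stages) {
    st <- config$stages[[si]]
    bin <- max(1L, as.integer(st$bin %||% 1L))
    nb <- (nv %/% bin)
    vb <- vs * bin
    # the mask must fit the box: cap the cylinder radius so its soft edge
    # stays inside the subvolume
    mrad <- min(config$mask_radius, (nb / 2 - 4) * vb)
    zr <- pmax(pmin(st$z_range, (nb / 2 - 4) * vb), -(nb / 2 - 4) * vb)
    mask <- make_cylinder_mask(nb, vb, mrad, zr[1], zr[2])
    ref_st <- if (bin > 1)
      bin_volume(tomogram_volume(ref, vs), bin)$grid else ref
    # anti-overfitting low-pass, applied to both sides of the correlation
    lp <- st$lowpass %||% 0
    if (lp > 2 * vb) ref_st <- lowpass_volume(ref_st, lp, vb)
    ctx_st <- if (isTRUE(st$context)) {
      if (bin > 1) bin_volume(tomogram_volume(ref_full, vs), bin)$grid
      else ref_full
    } else NULL
    ctx_cache <- if (isTRUE(st$context)) new.env(parent = emptyenv()) else NULL
    for (it in seq_len(st$iterations)) {
      for (i in seq_len(nrow(particles))) {
        sub <- extract_subvolume(get_tomo(particles$tomo_id[i]),
                                 c(particles$x[i], particles$y[i],
                                   particles$z[i]),
                                 config$box, tomo_id = particles$tomo_id[i])
        if (bin > 1) {
          bv <- bin_volume(tomogram_volume(sub$grid, sub$voxel_size,
                                           wedge = sub$wedge), bin)
          sub <- structure(list(grid = bv$grid, voxel_size = vb,
                                source_position = sub$source_position +
                                  (bin - 1) * vs / 2,
                                tomo_id = sub$tomo_id, wedge = sub$wedge),
                           class = "subvolume")
        }
        if (lp > 2 * vb) {
          sub$grid <- lowpass_volume(sub$grid, lp, vb)
        }
        prior <- as.numeric(particle_orientations(particles)[i, ])
        res <- cone_angular_search(ref_st, sub, mask, prior,
                                   cone_half_angle = st$cone,
                                   angular_step = st$angular_step,
                                   shift_limit = st$shift_limit,
                                   inplane_step = st$inplane_step,
                                   inplane_range = st$inplane_range,
                                   sym = config$sym, context_ref = ctx_st,
                                   context_cache = ctx_cache)
        newpos <- sub$source_position + res$shift
        if (isTRUE(st$renormal) && !is.null(surface)) {
          surf_i <- if (inherits(surface, "membrane_surface")) surface
                    else surface[[as.character(particles$tomo_id[i])]]
          nrm <- surface_normals(surf_i, matrix(newpos, 1))[1, ]
          Ra <- euler_to_matrix(euler_from_axis(nrm, 0))
          Mrel <- t(Ra) %*% euler_to_matrix(res$rotation)
          psi <- atan2(Mrel[2, 1], Mrel[1, 1]) * 180 / pi
          res$rotation <- euler_from_axis(nrm, psi)
        }
        particles$x[i] <- newpos[1]
        particles$y[i] <- newpos[2]
        particles$z[i] <- newpos[3]
        particles$eul1[i] <- res$rotation[1]
        particles$eul2[i] <- res$rotation[2]
        particles$eul3[i] <- res$rotation[3]
        particles$score[i] <- res$score
      }
      mscore <- mean(particles$score)
      history <- c(history, mscore)
      if (verbose)
        message(sprintf("stage %d iteration %d: mean score %.4f", si, it, mscore))
      if (is.finite(prev_mean) && mscore < prev_mean - config$divergence_tol)
        stop(sprintf(
          "alignment diverged in stage %d iteration %d: mean score %.4f after %.4f",
          si, it, mscore, prev_mean))
      converged <- is.finite(prev_mean) &&
        abs(mscore - prev_mean) < config$score_tol
      prev_mean <- mscore
      if (config$update_reference) {
        subs <- extract_all(particles)   # data-driven reference update

        res_list <- lapply(seq_len(nrow(particles)), function(i)
          list(rotation = as.numeric(particle_orientations(particles)[i, ]),
               shift = c(particles$x[i], particles$y[i], particles$z[i]) -
                 subs[[i]]$source_position))
        ref <- average_subvolumes(subs, res_list)$grid
      }
      if (converged) break
    }
    prev_mean <- -Inf   # stages use different masks; scores not comparable
  }
  subs <- extract_all(particles)
  res_list <- lapply(seq_len(nrow(particles)), function(i)
    list(rotation = as.numeric(particle_orientations(particles)[i, ]),
         shift = c(particles$x[i], particles$y[i], particles$z[i]) -
           subs[[i]]$source_position))
  avg <- average_subvolumes(subs, res_list)
  list(particles = particles, average = avg, history = history)
}
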