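make_sub <- function(grid, wedge = "full", pos = c(0, 0, 0)) {
  structure(list(grid = grid, voxel_size = fix_voxel, source_position = pos,
                 tomo_id = 1L, wedge = wedge), class = "subvolume")
}

test_that("extract_subvolume arithmetic, centring and errors", {
  set.seed(1)
  tomo <- tomogram_volume(array(stats::rnorm(40^3), rep(40, 3)), fix_voxel)
  sv <- extract_subvolume(tomo, c(90, 90, 90), 573)
  expect_equal(dim(sv$grid), rep(128L, 3))            # round(573/4.48) = 128
  # delta voxel maps to the cube centre voxel
  g <- array(0, rep(40, 3)); g[21, 23, 19] <- 7
  tomo2 <- tomogram_volume(g, fix_voxel)
  pos <- (c(21, 23, 19) - 1) * fix_voxel
  sv2 <- extract_subvolume(tomo2, pos, 16 * fix_voxel)
  ctr <- hextomo:::centre_voxel(16) + 1
  expect_equal(sv2$grid[ctr, ctr, ctr], 7)
  expect_equal(sum(sv2$grid != 0), 1)
  expect_equal(sv2$source_position, pos)
  expect_error(extract_subvolume(tomo, c(1e4, 0, 0), 100), "outside")
  # padding fraction reported at the boundary
  sv3 <- extract_subvolume(tomo, c(0, 0, 0), 16 * fix_voxel)
  expect_gt(attr(sv3, "padding_fraction"), 0.5)
})

test_that("rotate_volume contracts: identity, inverse, C2", {
  motif <- fix_motif()
  g <- embed_motif(motif, 32)
  expect_identical(rotate_volume(g, c(0, 0, 0)), g)
  e <- c(40, 25, 10)
  back <- rotate_volume(rotate_volume(g, e), matrix_to_euler(t(euler_to_matrix(e))))
  cm <- central_mask(32, 12)
  expect_gt(masked_cor(back, g, cm), 0.99)
  expect_gt(masked_cor(rotate_volume(g, c(0, 0, 180)), g, cm), 0.99)  # C2 motif
})

test_that("constrained NCC: perfect match, shift recovery, brute force", {
  motif <- fix_motif(24)
  ref <- embed_motif(motif, 32)
  mask <- central_mask(32, 13) * 1
  self <- constrained_ncc(ref, make_sub(ref), mask, shift_limit = 60)
  expect_equal(self$score, 1, tolerance = 1e-6)
  expect_lt(max(abs(self$shift)), 0.05)   # sub-voxel interpolation residual
  # known integer shift, compared against brute-force correlation
  shifted <- embed_motif(motif, 32, off = c(3, -2, 4))
  res <- constrained_ncc(ref, make_sub(shifted), mask, shift_limit = 40,
                         subvoxel = FALSE)
  expect_equal(res$shift / fix_voxel, c(3, -2, 4))
  # brute force over all integer shifts in +/-5 voxels on the same score
  brute_best <- -Inf; brute_shift <- NULL
  P <- sum(mask)
  a <- mask * (ref - sum(mask * ref) / P)
  for (sx in -5:5) for (sy in -5:5) for (sz in -5:5) {
    sh <- embed_motif(motif, 32, off = c(3 - sx, -2 - sy, 4 - sz))
    # direct masked Pearson-style score, same definition as the fast path
    m1 <- sum(mask * sh); m2 <- sum(mask * sh^2)
    vs <- m2 / P - (m1 / P)^2
    sc <- sum(a * sh) / (sqrt(sum(a^2)) * sqrt(P * vs))
    if (sc > brute_best) { brute_best <- sc; brute_shift <- c(sx, sy, sz) }
  }
  expect_equal(brute_shift, c(3, -2, 4))
  expect_equal(brute_best, res$score, tolerance = 1e-6)
  # all-zero input under the mask errors
  expect_error(constrained_ncc(ref, make_sub(array(0, rep(32, 3))), mask, 40),
               "undefined")
})

test_that("wedge compensation never hurts a noise-free wedge-degraded match", {
  motif <- fix_motif(24)
  sch <- make_tilt_scheme(60, 2, 5)
  mask <- central_mask(32, 13) * 1
  set.seed(31)
  worse <- 0
  for (i in 1:10) {
    e <- euler_from_axis(stats::rnorm(3), stats::runif(1, 0, 360))
    ref <- embed_motif(motif, 32, euler = e)
    wg <- apply_missing_wedge(tomogram_volume(ref, fix_voxel), sch)$grid
    on <- constrained_ncc(ref, make_sub(wg, wedge = sch), mask, 30)$score
    off <- constrained_ncc(ref, make_sub(wg, wedge = "full"), mask, 30)$score
    expect_gt(on, 0.99)
    if (on < off) worse <- worse + 1
  }
  expect_equal(worse, 0)
})

test_that("cone search recovers a known rotation and honours the cone", {
  motif <- fix_motif(24)
  ref <- embed_motif(motif, 32)
  mask <- central_mask(32, 13) * 1
  true_e <- matrix_to_euler(euler_to_matrix(c(10, 15, 30)))
  sub <- make_sub(embed_motif(motif, 32, euler = true_e))
  prior <- matrix_to_euler(euler_to_matrix(true_e) %*% euler_to_matrix(c(0, 20, 0)))
  res <- cone_angular_search(ref, sub, mask, prior, cone_half_angle = 30,
                             angular_step = 10, shift_limit = 30, sym = 2)
  expect_lt(angular_distance(res$rotation, true_e, sym = 2), 5) # step/2
  # argmax property: returned score >= score of the prior pose
  prior_sc <- hextomo:::score_at_rotation(ref, sub, mask, prior, 30)$score
  expect_gte(res$score, prior_sc - 1e-9)
  # degenerate cone searches only in-plane rotations of the prior
  res0 <- cone_angular_search(ref, sub, mask, true_e, cone_half_angle = 0,
                              angular_step = 10, shift_limit = 30, sym = 2)
  expect_lt(angular_distance(res0$rotation, true_e, sym = 2), 1e-5)
  # step > cone returns the prior with a warning
  expect_warning(
    resw <- cone_angular_search(ref, sub, mask, prior, cone_half_angle = 5,
                                angular_step = 10, shift_limit = 30),
    "cone")
  expect_equal(resw$rotation, prior)
})

test_that("fast cone search equals the brute-force oracle on tiny volumes", {
  # 16^3, 10-degree in-plane grid, +/-2-voxel shifts: exhaustive oracle
  motif <- make_csu_motif(voxel_size = 2 * fix_voxel, box = 14,
                          tod_spacing = 60, cyl_radius = 12,
                          z_top = 20, z_bottom = -50, plate_radius = 40)
  emb16 <- function(e, off = c(0, 0, 0)) {
    g <- array(0, rep(16, 3))
    hextomo:::.add_motif(g, rep(16L, 3), as.numeric(motif$grid),
                         dim(motif$grid), t(euler_to_matrix(e)),
                         hextomo:::centre_voxel(rep(16, 3)) + off,
                         hextomo:::centre_voxel(dim(motif$grid)))
    dim(g) <- rep(16, 3); g
  }
  ref <- emb16(c(0, 0, 0))
  mask <- central_mask(16, 6.5) * 1
  true_e <- c(0, 0, 40)
  sub_g <- emb16(true_e, off = c(1, -2, 1))
  sub <- structure(list(grid = sub_g, voxel_size = 2 * fix_voxel,
                        source_position = c(0, 0, 0), tomo_id = 1L,
                        wedge = "full"), class = "subvolume")
  fast <- cone_angular_search(ref, sub, mask, c(0, 0, 0), cone_half_angle = 0,
                              angular_step = 10, shift_limit = 2 * 2 * fix_voxel,
                              inplane_step = 10, inplane_range = 360, sym = 1)
  # oracle: direct sums over the same candidate grid and shift window
  P <- sum(mask)
  best <- list(score = -Inf)
  for (psi in seq(0, 350, by = 10)) {
    a0 <- rotate_volume(mask * (ref - sum(mask * ref) / P), c(0, 0, psi))
    na <- sqrt(sum(a0^2))
    for (sx in -2:2) for (sy in -2:2) for (sz in -2:2) {
      sh <- emb16(true_e, off = c(1 - sx, -2 - sy, 1 - sz))
      m1 <- sum(mask * sh); m2 <- sum(mask * sh^2)
      vs <- m2 / P - (m1 / P)^2
      sc <- sum(a0 * sh) / (na * sqrt(P * vs))
      if (sc > best$score)
        best <- list(score = sc, psi = psi, shift = c(sx, sy, sz))
    }
  }
  expect_lt(angular_distance(fast$rotation, c(0, 0, best$psi)), 1e-6)
  expect_equal(fast$shift / (2 * fix_voxel), best$shift, tolerance = 0.5)
})

test_that("null refinement leaves the particle table unchanged", {
  motif <- fix_motif(24)
  g <- embed_motif(motif, 32)
  tomo <- tomogram_volume(g, fix_voxel)
  p <- particle_set(matrix(hextomo:::centre_voxel(c(32, 32, 32)) * fix_voxel, 1),
                    matrix(c(0, 0, 0), 1))
  cfg <- refinement_config(box = 32 * fix_voxel, shift_limit = 0, sym = 1,
                           stage1 = list(cone = 0, inplane_range = 0,
                                         iterations = 1, bin = 1,
                                         shift_limit = 0))
  out <- iterative_refine(p, tomo, cfg, reference = g, stages = 1)
  expect_equal(out$particles$x, p$x)
  expect_equal(out$particles$y, p$y)
  expect_equal(out$particles$z, p$z)
  expect_equal(as.numeric(out$particles[1, c("eul1", "eul2", "eul3")]),
               c(0, 0, 0))
})

test_that("alignment scores are equivariant under a global 180-deg rotation", {
  # rotating tomogram and seeds by 180 degrees about z maps the wedge onto
  # itself and the voxel grid onto itself, so scores must match closely
  motif <- fix_motif(24)
  sch <- make_tilt_scheme(60, 2, 5)
  e <- c(25, 20, 40)
  g <- embed_motif(motif, 32, euler = e)
  wg <- apply_missing_wedge(tomogram_volume(g, fix_voxel), sch)$grid
  mask <- central_mask(32, 13) * 1
  ref <- embed_motif(motif, 32)
  s1 <- hextomo:::score_at_rotation(ref, make_sub(wg, sch), mask, e, 20)$score
  flip <- function(v) {
    out <- v[c(2:dim(v)[1], 1), c(2:dim(v)[2], 1), , drop = FALSE]
    out <- out[rev(seq_len(dim(out)[1])), rev(seq_len(dim(out)[2])), , drop = FALSE]
    out
  }
  e2 <- matrix_to_euler(euler_to_matrix(c(0, 0, 180)) %*% euler_to_matrix(e))
  s2 <- hextomo:::score_at_rotation(ref, make_sub(flip(wg), sch), mask, e2,
                                    20)$score
  expect_equal(s1, s2, tolerance = 1e-3)
})

test_that("higher SNR gives higher mean alignment score (paired)", {
  motif <- fix_motif(24)
  sch <- make_tilt_scheme(60, 2, 5)
  mask <- central_mask(32, 13) * 1
  ref <- embed_motif(motif, 32)
  for (seed in 1:3) {
    scores <- vapply(c(0.05, 0.5), function(snr) {
      set.seed(seed)
      mean(vapply(1:5, function(i) {
        e <- euler_from_axis(stats::rnorm(3), stats::runif(1, 0, 360))
        v <- tomogram_volume(embed_motif(motif, 32, euler = e), fix_voxel)
        v <- add_noise(apply_missing_wedge(v, sch), snr,
                       seed = seed * 100 + i + round(snr * 1000))
        hextomo:::score_at_rotation(ref, make_sub(v$grid, sch), mask, e,
                                    20)$score
      }, numeric(1)))
    }, numeric(1))
    expect_gt(scores[2], scores[1])
  }
})
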