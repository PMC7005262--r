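test_that("average of one identity subvolume is the input", {
  g <- embed_motif(fix_motif(24), 32)
  sv <- list(structure(list(grid = g, voxel_size = fix_voxel,
                            source_position = c(0, 0, 0), tomo_id = 1L,
                            wedge = "full"), class = "subvolume"))
  avg <- average_subvolumes(sv, list(list(rotation = c(0, 0, 0),
                                          shift = c(0, 0, 0))))
  expect_equal(avg$grid, g, tolerance = 1e-10)
})

test_that("duplicating every particle leaves the average unchanged", {
  st <- simulate_particle_stack(6, fix_motif(24), box = 32, snr = 2,
                                seed = 3, max_tilt_axis = 90)
  a1 <- average_subvolumes(st$subvols, st$results)
  a2 <- average_subvolumes(c(st$subvols, st$subvols),
                           c(st$results, st$results))
  expect_equal(a1$grid, a2$grid, tolerance = 1e-9)
})

test_that("orientation diversity fills the wedge: 20 copies recover the motif", {
  motif <- fix_motif(24)
  st <- simulate_particle_stack(20, motif, box = 32, snr = Inf,
                                scheme = make_tilt_scheme(60, 2, 5),
                                seed = 5, max_tilt_axis = 90)
  suppressWarnings(avg <- average_subvolumes(st$subvols, st$results))
  truth <- embed_motif(motif, 32)
  expect_gt(masked_cor(avg$grid, truth, central_mask(32, 13)), 0.99)
})

test_that("split_half_sets balances tomograms greedily and exactly", {
  p <- particle_set(matrix(stats::runif(3 * 60), 60, 3),
                    tomo_id = rep(1:6, each = 10))
  h <- split_half_sets(p)
  expect_equal(nrow(h$a), 30)
  expect_equal(nrow(h$b), 30)
  expect_length(intersect(h$a$id, h$b$id), 0)
  expect_setequal(c(h$a$id, h$b$id), p$id)
  expect_length(intersect(unique(h$a$tomo_id), unique(h$b$tomo_id)), 0)

  # skewed counts {100,1,1,1,1,1}: exhaustive oracle over all 2^6 partitions
  counts <- c(100, 1, 1, 1, 1, 1)
  p2 <- particle_set(matrix(stats::runif(3 * sum(counts)), sum(counts), 3),
                     tomo_id = rep(1:6, counts))
  h2 <- split_half_sets(p2)
  best <- Inf
  for (m in 0:63) {
    sel <- as.logical(bitwAnd(m, 2^(0:5)))
    best <- min(best, abs(sum(counts[sel]) - sum(counts[!sel])))
  }
  expect_equal(abs(nrow(h2$a) - nrow(h2$b)), best)
  expect_error(split_half_sets(particle_set(matrix(1, 3, 3), tomo_id = 1L)),
               "tomogram")
})

test_that("FSC identities: self, negation, independent noise", {
  set.seed(9)
  g <- array(stats::rnorm(48^3), rep(48, 3))
  self <- compute_fsc(g, g, voxel_size = fix_voxel)
  expect_true(all(abs(self$correlation[self$shell_counts > 0] - 1) < 1e-9))
  neg <- compute_fsc(g, -g, voxel_size = fix_voxel)
  expect_true(all(abs(neg$correlation[neg$shell_counts > 0] + 1) < 1e-9))
  a <- array(stats::rnorm(64^3), rep(64, 3))
  b <- array(stats::rnorm(64^3), rep(64, 3))
  fsc <- compute_fsc(a, b, voxel_size = fix_voxel)
  sel <- fsc$shell_counts > 0 & seq_along(fsc$correlation) > 1
  frac <- mean(abs(fsc$correlation[sel]) < 3 / sqrt(fsc$shell_counts[sel]))
  expect_gte(frac, 0.95)
  expect_error(compute_fsc(array(0, rep(16, 3)), array(0, rep(16, 3))),
               "undefined")
})

test_that("a smooth mask keeps the first shells of a self-FSC at 1", {
  g <- embed_motif(fix_motif(24), 32)
  mask <- make_cylinder_mask(32, fix_voxel, 60, -60, 60)
  fsc <- compute_fsc(g, g, mask = mask, voxel_size = fix_voxel)
  expect_gt(fsc$correlation[2], 0.99)
})

test_that("resolution_at_threshold interpolates and flags non-crossing", {
  # linear correlation profile crossing 0.5 exactly at 1/20 per Angstrom
  freqs <- seq(0, 0.1, by = 0.005)
  corr <- 1 - 0.5 * freqs / 0.05
  crv <- structure(list(shell_freq = freqs, correlation = corr,
                        shell_counts = rep(10, length(freqs)),
                        voxel_size = fix_voxel), class = "fsc_curve")
  expect_equal(resolution_at_threshold(crv, 0.5), 20, tolerance = 1e-9)
  # a lower threshold always crosses later (coarser frequency, smaller A)
  expect_lte(resolution_at_threshold(crv, 0.143),
             resolution_at_threshold(crv, 0.5))
  flat <- crv; flat$correlation <- rep(0.9, length(freqs))
  res <- resolution_at_threshold(flat, 0.5)
  expect_equal(as.numeric(res), 2 * fix_voxel)
  expect_true(attr(res, "never_crossed"))
})
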