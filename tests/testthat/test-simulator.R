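# rendering, missing wedge, noise, WBP

test_that("render_tomogram is linear and places single particles exactly", {
  motif <- fix_motif()
  surf <- membrane_surface("plane", extent = c(200, 200))
  empty <- structure(list(surface = surf, lattice_constant = 1,
                          tod_spacing = 1,
                          positions = matrix(numeric(0), ncol = 3),
                          orientations = matrix(numeric(0), ncol = 3),
                          jitter_sd = 0), class = "ground_truth_array")
  v0 <- render_tomogram(empty, motif, fix_voxel, 48, membrane_amp = 0)
  expect_true(all(v0$grid == 0))

  one <- empty
  one$positions <- matrix(c(0, 0, 0), 1)
  one$orientations <- matrix(c(0, 0, 0), 1)
  ctr_origin <- -hextomo:::centre_voxel(c(48, 48, 48)) * fix_voxel
  v1 <- render_tomogram(one, motif, fix_voxel, 48, origin = ctr_origin,
                        membrane_amp = 0)
  ref <- embed_motif(motif, 48)
  expect_lt(max(abs(v1$grid - ref)), 1e-9)    # identity placement is exact

  two <- one
  two$positions <- rbind(c(-30, 0, 0), c(30, 10, 0))
  two$orientations <- rbind(c(0, 0, 30), c(10, 20, 0))
  v2 <- render_tomogram(two, motif, fix_voxel, 48, origin = ctr_origin,
                        membrane_amp = 0)
  va <- one; va$positions <- two$positions[1, , drop = FALSE]
  va$orientations <- two$orientations[1, , drop = FALSE]
  vb <- one; vb$positions <- two$positions[2, , drop = FALSE]
  vb$orientations <- two$orientations[2, , drop = FALSE]
  ga <- render_tomogram(va, motif, fix_voxel, 48, origin = ctr_origin,
                        membrane_amp = 0)$grid
  gb <- render_tomogram(vb, motif, fix_voxel, 48, origin = ctr_origin,
                        membrane_amp = 0)$grid
  expect_equal(v2$grid, ga + gb, tolerance = 1e-12)
})

test_that("missing wedge zeroes the expected double cone", {
  sch <- make_tilt_scheme(60, 2, 5)
  v <- tomogram_volume(array(stats::rnorm(48^3), rep(48, 3)), fix_voxel)
  w <- apply_missing_wedge(v, sch)
  expect_true(is.numeric(w$grid))
  # zeroed fraction within the Nyquist disc of each plane perpendicular to
  # the tilt axis ~ (180 - 2*60)/180 = 1/3
  m <- wedge_fourier_mask(rep(48, 3), 60)
  f <- (0:47); f <- ifelse(f > 24, f - 48, f) / 48
  disc <- outer(f^2, f^2, "+") <= 0.25^2           # kx-kz Nyquist disc
  frac <- mean(!m[, 1, ][disc])
  expect_equal(frac, 1 / 3, tolerance = 0.02)
  # idempotence (up to FFT round-off)
  w2 <- apply_missing_wedge(w, sch)
  expect_lt(max(abs(w2$grid - w$grid)), 1e-10)
  # 90-degree scheme removes nothing
  v90 <- apply_missing_wedge(v, make_tilt_scheme(90, 2, 5))
  expect_lt(max(abs(v90$grid - v$grid)), 1e-10)
})

test_that("add_noise hits the requested SNR and is seeded", {
  v <- tomogram_volume(embed_motif(fix_motif(), 64), fix_voxel)
  n1 <- add_noise(v, 1, seed = 5)
  ratio <- stats::var(as.numeric(n1$grid - v$grid)) /
    stats::var(as.numeric(v$grid))
  expect_equal(ratio, 1, tolerance = 0.05)
  expect_identical(n1$grid, add_noise(v, 1, seed = 5)$grid)
  expect_false(identical(n1$grid, add_noise(v, 1, seed = 6)$grid))
  hi <- add_noise(v, 1e12, seed = 5)
  expect_gt(stats::cor(as.numeric(hi$grid), as.numeric(v$grid)), 0.999999)
  expect_error(add_noise(v, -1), "snr")
})

test_that("weighted back-projection reconstructs and matches the fast path", {
  v <- tomogram_volume(embed_motif(fix_motif(), 48), fix_voxel)
  cm <- central_mask(48, 18)
  full <- project_and_wbp(v, make_tilt_scheme(90, 1, 5))
  expect_gt(masked_cor(full$grid, v$grid, cm), 0.95)
  sch <- make_tilt_scheme(60, 2, 5)
  wbp60 <- project_and_wbp(v, sch)
  fast60 <- apply_missing_wedge(v, sch)
  expect_gt(masked_cor(wbp60$grid, fast60$grid, cm), 0.9)
})

test_that("binning arithmetic", {
  v <- tomogram_volume(array(stats::rnorm(64^3), rep(64, 3)), fix_voxel)
  b <- bin_volume(v, 2)
  expect_equal(dim(b$grid), rep(32, 3))
  expect_equal(b$voxel_size, 2 * fix_voxel)
  expect_equal(b$grid[1, 1, 1], mean(v$grid[1:2, 1:2, 1:2]))
})

test_that("two degraded copies show the wedge-FSC signature", {
  v <- tomogram_volume(embed_motif(fix_motif(), 48), fix_voxel)
  sch <- make_tilt_scheme(60, 2, 5)
  w <- apply_missing_wedge(v, sch)
  a <- add_noise(w, 0.5, seed = 21)
  b <- add_noise(w, 0.5, seed = 22)
  fsc <- compute_fsc(a$grid, b$grid, voxel_size = fix_voxel)
  ns <- length(fsc$correlation)
  expect_gt(mean(fsc$correlation[2:4]), 0.9)       # low-frequency agreement
  expect_lt(mean(fsc$correlation[(ns - 5):ns]),
            mean(fsc$correlation[2:6]))            # decays into the noise band
})
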