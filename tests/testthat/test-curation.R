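test_that("collapse_duplicates merges close pairs and is idempotent", {
  p <- particle_set(rbind(c(0, 0, 0), c(5, 0, 0), c(100, 0, 0)),
                    score = c(0.2, 0.9, 0.5))
  out <- collapse_duplicates(p, 10)
  expect_equal(nrow(out), 2)
  expect_equal(sort(out$x), c(2.5, 100))            # centroid of the pair
  expect_equal(out$score[out$x == 2.5], 0.9)        # best-scoring member
  expect_identical(collapse_duplicates(out, 10), out)
  expect_equal(nrow(collapse_duplicates(particle_set(matrix(numeric(0),
                                                            ncol = 3)), 10)), 0)
})

test_that("collapse_duplicates matches the union-find oracle", {
  for (seed in 1:8) {
    p <- random_particles(200, side = 500, seed = seed)
    pos <- as.matrix(p[, c("x", "y", "z")])
    comp <- oracle_components(pos, 10)
    out <- collapse_duplicates(p, 10)
    expect_equal(nrow(out), length(unique(comp)))
    dm <- stats::dist(as.matrix(out[, c("x", "y", "z")]))
    if (nrow(out) > 1) expect_gt(min(dm), 10)
    expect_identical(collapse_duplicates(out, 10), out)  # idempotence
  }
})

test_that("neighbor_filter reproduces the annulus-count oracle", {
  lat <- triangular_lattice(120, 8, 8)
  pos <- as.matrix(lat[, c("x", "y", "z")])
  keep <- oracle_neighbor_keep(pos, 120, 20, 3)
  out <- neighbor_filter(lat, 120, 20, 3)
  expect_setequal(out$id, lat$id[keep])
  # an interior lattice point has exactly 6 neighbours and is retained
  dm <- as.matrix(stats::dist(pos)); diag(dm) <- Inf
  interior <- which(rowSums(dm >= 100 & dm <= 140) == 6)
  expect_gt(length(interior), 0)
  expect_true(all(lat$id[interior] %in% out$id))
  # an isolated point is removed
  iso <- particle_set(rbind(pos, c(5000, 5000, 5000)))
  expect_false(nrow(neighbor_filter(iso, 120, 20, 3)) == nrow(iso))
  # random sets match the oracle exactly
  for (seed in 1:8) {
    p <- random_particles(100, side = 400, seed = seed + 50)
    pos <- as.matrix(p[, c("x", "y", "z")])
    expect_setequal(neighbor_filter(p, 120, 20, 3)$id,
                    p$id[oracle_neighbor_keep(pos, 120, 20, 3)])
  }
})

test_that("neighbor_filter is monotone in min_neighbors", {
  p <- random_particles(150, side = 600, seed = 77)
  prev <- neighbor_filter(p, 120, 40, 0)$id
  for (mn in 1:5) {
    cur <- neighbor_filter(p, 120, 40, mn)$id
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("estimate_lattice_spacing finds the modal spacing", {
  lat <- triangular_lattice(120, 8, 8)
  st <- estimate_lattice_spacing(lat, mode = "centers")
  expect_equal(st$modal_spacing, 120, tolerance = 3)
  expect_equal(st$lattice_constant, st$modal_spacing)
  st2 <- estimate_lattice_spacing(lat, mode = "honeycomb")
  expect_equal(st2$lattice_constant, sqrt(3) * st2$modal_spacing)
  expect_error(estimate_lattice_spacing(random_particles(9)), "insufficient")
})

test_that("modal spacing is robust to jitter (Monte Carlo)", {
  errs <- vapply(1:20, function(s) {
    surf <- membrane_surface("plane", extent = c(1100, 1100))
    arr <- place_hex_array(surf, 120 / sqrt(3), jitter_sd = 5, seed = s,
                           sites = "centers")
    p <- particle_set(arr$positions)
    abs(estimate_lattice_spacing(p, mode = "centers")$modal_spacing - 120) / 120
  }, numeric(1))
  expect_lt(max(errs), 0.05)
})

test_that("curation chain keeps the lattice and rejects decoys", {
  set.seed(123)
  surf <- membrane_surface("plane", extent = c(1400, 1400))
  arr <- place_hex_array(surf, 120 / sqrt(3), jitter_sd = 5, seed = 5,
                         sites = "centers")
  n_true <- nrow(arr$positions)
  # 50 decoys > 200 A from the lattice (above the membrane plane)
  decoys <- cbind(stats::runif(50, -700, 700), stats::runif(50, -700, 700),
                  stats::runif(50, 250, 600))
  p <- particle_set(rbind(arr$positions, decoys))
  out <- neighbor_filter(collapse_duplicates(p, 10), 120, 20, 3)
  kept_true <- sum(out$id <= n_true)
  kept_decoy <- sum(out$id > n_true)
  expect_equal(kept_decoy, 0)
  # interior truth (>= 4 annulus neighbours) is what the filter can keep
  dm <- as.matrix(stats::dist(arr$positions)); diag(dm) <- Inf
  interior <- sum(rowSums(dm >= 100 & dm <= 140) > 3)
  expect_gte(kept_true / interior, 0.9)
})
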