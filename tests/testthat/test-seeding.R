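test_that("planar seeding hits the target density and spacing", {
  surf <- membrane_surface("plane", extent = c(1000, 1000))
  seeds <- sample_seed_positions(surf, 30)
  n <- nrow(seeds)
  expect_lt(abs(n - (1000 / 30)^2) / (1000 / 30)^2, 0.2)
  pos <- as.matrix(seeds[, c("x", "y", "z")])
  dm <- as.matrix(stats::dist(pos)); diag(dm) <- Inf
  mean_nn <- mean(apply(dm, 1, min))
  expect_gte(mean_nn, 24)       # within 20% of 30 A
  expect_lte(mean_nn, 36)
})

test_that("sphere-cap seeding spacing and surface placement", {
  surf <- membrane_surface("sphere-cap", center = c(0, 0, 0), radius = 2000,
                           extent = 15)
  seeds <- sample_seed_positions(surf, 50)
  pos <- as.matrix(seeds[, c("x", "y", "z")])
  expect_equal(sqrt(rowSums(pos^2)), rep(2000, nrow(pos)), tolerance = 1e-6)
  dm <- as.matrix(stats::dist(pos)); diag(dm) <- Inf
  expect_lt(abs(mean(apply(dm, 1, min)) - 50) / 50, 0.2)
})

test_that("zero-area region gives an empty seed set", {
  surf <- membrane_surface("plane", extent = c(1000, 1000))
  empty <- sample_seed_positions(surf, 30, region = c(0, 0))
  expect_equal(nrow(empty), 0)
  expect_error(sample_seed_positions(surf, -3), "mean_spacing")
})

test_that("seeding density is translation-invariant on the plane", {
  surf <- membrane_surface("plane", extent = c(1200, 1200))
  seeds <- sample_seed_positions(surf, 30)
  n1 <- sum(seeds$x > -500 & seeds$x < -100 & seeds$y > -500 & seeds$y < -100)
  n2 <- sum(seeds$x > 100 & seeds$x < 500 & seeds$y > 100 & seeds$y < 500)
  expect_lt(abs(n1 - n2) / max(n1, n2), 0.05)
})

test_that("orientations_from_normals reproduces normals (round trip)", {
  surf <- membrane_surface("sphere-cap", center = c(0, 0, 0), radius = 1500,
                           extent = 60)
  set.seed(11)
  th <- stats::runif(1000, 0, pi / 3); ph <- stats::runif(1000, 0, 2 * pi)
  pos <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th)) * 1500
  ss <- orientations_from_normals(surf, pos)
  ori <- as.matrix(ss[, c("eul1", "eul2", "eul3")])
  worst <- 0
  for (i in seq_len(nrow(pos))) {
    R <- euler_to_matrix(ori[i, ])
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    ax <- as.numeric(R %*% c(0, 0, 1))
    ang <- acos(min(1, sum(ax * pos[i, ] / 1500))) * 180 / pi
    worst <- max(worst, ang)
  }
  expect_lt(worst, 0.01)
  # pole special case
  pole <- orientations_from_normals(surf, matrix(c(0, 0, 1500), 1))
  expect_equal(as.numeric(pole[1, c("eul1", "eul2", "eul3")]), c(0, 0, 0))
})

test_that("off-surface positions are projected with a warning", {
  surf <- membrane_surface("sphere-cap", center = c(0, 0, 0), radius = 1000,
                           extent = 30)
  expect_warning(ss <- orientations_from_normals(surf, matrix(c(0, 0, 1050), 1)),
                 "projected")
  expect_equal(as.numeric(ss[1, c("x", "y", "z")]), c(0, 0, 1000),
               tolerance = 1e-9)
})
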