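test_that("fractional inhibition recovers injected step amplitudes", {
  tr <- simulate_fret_trace(c(0.1, 0.2, 0.4, 0.8, 2), k_half = 0.4, h = 2.7,
                            adaptation_rate = 0, noise_sd = 0, seed = 1)
  dr <- fractional_inhibition(tr)
  hill <- function(L) L^2.7 / (0.4^2.7 + L^2.7)
  expect_equal(dr$fractional_inhibition[nrow(dr)], 1)   # saturating window
  expect_equal(dr$fractional_inhibition[1:5], hill(c(0.1, 0.2, 0.4, 0.8, 2)),
               tolerance = 0.02)
  # dose-0-like window: a tiny dose produces ~no drop
  tr0 <- simulate_fret_trace(c(1e-6), adaptation_rate = 0, noise_sd = 0)
  expect_lt(fractional_inhibition(tr0)$fractional_inhibition[1], 0.01)
  # monotone in dose for a noise-free trace
  expect_true(all(diff(dr$fractional_inhibition) >= -1e-12))
})

test_that("trace simulator: plateaus, saturation, overshoot, errors", {
  flat <- simulate_fret_trace(c(0.4), adaptation_rate = 0, noise_sd = 0)
  w <- flat$stimulus_windows[1, ]
  inwin <- flat$ratio[flat$time >= w$start & flat$time < w$end]
  expect_lt(stats::sd(inwin), 1e-12)                     # flat plateau
  expect_true(all(flat$ratio <= 1 + 1e-12))              # no overshoot
  ad <- simulate_fret_trace(c(0.4), adaptation_rate = 0.05, noise_sd = 0)
  expect_gt(max(ad$ratio), 1 + 1e-6)                     # overshoot appears
  # dose >> K saturates to the full drop
  big <- simulate_fret_trace(c(1e4), k_half = 0.4, h = 2.7,
                             adaptation_rate = 0, noise_sd = 0, sat_drop = 0.2)
  expect_equal(min(big$ratio), 1 - 0.2, tolerance = 1e-6)
  expect_identical(simulate_fret_trace(c(0.4), seed = 2)$ratio,
                   simulate_fret_trace(c(0.4), seed = 2)$ratio)
})

test_that("hill_fit recovers exact parameters and satisfies the identity", {
  doses <- 10^seq(-2, 1, length.out = 8)
  tab <- data.frame(dose = doses,
                    fractional_inhibition = doses^2 / (1 + doses^2))
  fit <- hill_fit(tab, n_boot = 0)
  expect_equal(fit$k_half, 1, tolerance = 1e-6)
  expect_equal(fit$hill_coefficient, 2, tolerance = 1e-6)
  expect_equal(fit$amplitude, 1, tolerance = 1e-6)
  # f(K)/A = 1/2 for any fit evaluated at its own K
  pred <- stats::predict(fit$fit, newdata = data.frame(L = fit$k_half))
  expect_equal(pred / fit$amplitude, 0.5, tolerance = 1e-9)
  expect_error(hill_fit(data.frame(dose = c(1, 2, 3),
                                   fractional_inhibition = c(.1, .5, .9))),
               "4 distinct")
  expect_error(hill_fit(data.frame(dose = doses,
                                   fractional_inhibition = rep(0.5, 8))),
               "degenerate")
})

test_that("dose scale equivariance: K scales, h invariant", {
  doses <- 10^seq(-1.5, 1, length.out = 9)
  tab <- data.frame(dose = doses,
                    fractional_inhibition = doses^2.7 / (0.4^2.7 + doses^2.7))
  f1 <- hill_fit(tab, n_boot = 0)
  tab2 <- tab; tab2$dose <- tab$dose * 5
  f2 <- hill_fit(tab2, n_boot = 0)
  expect_equal(f2$k_half / f1$k_half, 5, tolerance = 1e-6)
  expect_equal(f2$hill_coefficient, f1$hill_coefficient, tolerance = 1e-6)
  # fitted curve is monotone in dose
  grid <- 10^seq(-2, 2, length.out = 50)
  expect_true(all(diff(stats::predict(f1$fit,
                                      newdata = data.frame(L = grid))) >= 0))
})

test_that("end-to-end trace -> table -> fit covers the generating K (CIs)", {
  # scaled-down version of the 100-seed coverage study (25 seeds, 80 boots):
  # >= 20/25 evidences ~90% nominal coverage within Monte Carlo error
  hits <- 0
  for (s in 1:25) {
    tr <- simulate_fret_trace(c(0.05, 0.1, 0.15, 0.25, 0.4, 0.6, 1, 1.6, 5),
                              k_half = 0.4, h = 2.7, adaptation_rate = 0,
                              noise_sd = 0.003, seed = s)
    fit <- hill_fit(fractional_inhibition(tr), n_boot = 80, seed = s)
    ci <- fit$confidence_intervals["k_half", ]
    if (ci[1] <= 0.4 && 0.4 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 20)
})
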