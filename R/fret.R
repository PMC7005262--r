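#' Simulate a FRET kinase-activity trace
#'
#' Synthetic YFP/CFP emission-ratio time trace for a sequence of attractant
#' stimulus windows. Each window produces a step drop of amplitude
#' `A * dose^h / (k_half^h + dose^h)` relative to the saturating drop;
#' during the stimulus, receptor methylation recovers the signal toward
#' baseline at `adaptation_rate`, and on stimulus removal the accumulated
#' methylation produces a kinase-activity overshoot that decays back to
#' baseline at the same rate.
#'
#' @param doses stimulus concentrations in uM, one per window.
#' @param k_half dose of half-maximal inhibition (uM).
#' @param h Hill coefficient.
#' @param adaptation_rate 1/s; 0 gives flat plateaus and no overshoot.
#' @param noise_sd Gaussian noise s.d. on the ratio.
#' @param seed RNG seed.
#' @param baseline pre-stimulus YFP/CFP ratio.
#' @param sat_drop ratio drop at a saturating dose.
#' @param dt sampling interval (s).
#' @param window_s,gap_s stimulus and recovery durations (s).
#' @param saturating_dose dose treated as saturating (uM); appended as the
#'   final window if not already present.
#' @return a `fret_trace`: list with `time` (s), `ratio`,
#'   `stimulus_windows` (data frame start/end/dose), `saturating_dose`.
#' @export
simulate_fret_trace <- function(doses, k_half = 0.4, h = 2.7,
                                adaptation_rate = 0.02, noise_sd = 0.005,
                                seed = 1, baseline = 1.0, sat_drop = 0.2,
                                dt = 1, window_s = 60, gap_s = 60,
                                saturating_dose = 100) {
  stopifnot(k_half > 0, h > 0, adaptation_rate >= 0, noise_sd >= 0)
  if (!any(doses >= saturating_dose)) doses <- c(doses, saturating_dose)
  nw <- length(doses)
  total <- gap_s + nw * (window_s + gap_s)
  tm <- seq(0, total, by = dt)
  ratio <- rep(baseline, length(tm))
  starts <- gap_s + (seq_len(nw) - 1) * (window_s + gap_s)
  ends <- starts + window_s
  hill <- function(L) L^h / (k_half^h + L^h)
  for (i in seq_len(nw)) {
    drop <- sat_drop * hill(doses[i])
    inwin <- tm >= starts[i] & tm < ends[i]
    trel <- tm[inwin] - starts[i]
    recov <- if (adaptation_rate > 0) 1 - exp(-adaptation_rate * trel) else 0
    ratio[inwin] <- ratio[inwin] - drop * (1 - recov)
    # overshoot: kinase activity above baseline by the adapted amount
    post <- tm >= ends[i] & tm < ends[i] + gap_s
    if (adaptation_rate > 0 && any(post)) {
      gained <- drop * (1 - exp(-adaptation_rate * window_s))
      ratio[post] <- ratio[post] +
        gained * exp(-adaptation_rate * 2 * (tm[post] - ends[i]))
    }
  }
  set.seed(seed)
  ratio <- ratio + stats::rnorm(length(ratio), 0, noise_sd)
  structure(list(time = tm, ratio = ratio,
                 stimulus_windows = data.frame(start = starts, end = ends,
                                               dose = doses),
                 saturating_dose = saturating_dose),
            class = "fret_trace")
}

#' Fractional kinase inhibition from a FRET trace
#'
#' For each stimulus window, the response is the drop from the pre-stimulus
#' baseline (median of the `baseline_s` seconds before the window) to the
#' in-stimulus plateau (median of the final half of the window). Fractional
#' inhibition is the drop normalised by the drop at the saturating dose and
#' clipped to `[0, 1]`.
#'
#' @param trace a `fret_trace` (fields `time`, `ratio`, `stimulus_windows`
#'   with columns start/end/dose, `saturating_dose`).
#' @param baseline_s baseline averaging span before each window (s).
#' @param min_samples minimum samples required in baseline and plateau.
#' @return a `dose_response_table`: data frame with columns `dose` (uM) and
#'   `fractional_inhibition`.
#' @export
fractional_inhibition <- function(trace, baseline_s = 20, min_samples = 3) {
  w <- trace$stimulus_windows
  if (!any(w$dose >= trace$saturating_dose))
    stop("trace contains no saturating-dose window")
  drops <- numeric(nrow(w))
  for (i in seq_len(nrow(w))) {
    base_ix <- trace$time >= w$start[i] - baseline_s & trace$time < w$start[i]
    mid <- (w$start[i] + w$end[i]) / 2
    plat_ix <- trace$time >= mid & trace$time < w$end[i]
    if (sum(base_ix) < min_samples || sum(plat_ix) < min_samples)
      stop("baseline or plateau shorter than the minimum sample count")
    drops[i] <- stats::median(trace$ratio[base_ix]) -
      stats::median(trace$ratio[plat_ix])
  }
  sat <- max(drops[w$dose >= trace$saturating_dose])
  if (sat <= 0) stop("saturating-dose drop is not positive")
  fi <- pmin(pmax(drops / sat, 0), 1)
  structure(data.frame(dose = w$dose, fractional_inhibition = fi),
            class = c("dose_response_table", "data.frame"))
}

#' Multi-site Hill fit of a dose-response table
#'
#' Least-squares fit of `f(L) = A * L^h / (K^h + L^h)` to fractional
#' inhibition versus dose, reported as the response K1/2 (receptor
#' sensitivity) and Hill coefficient (response cooperativity), with
#' residual-resampling bootstrap confidence intervals.
#'
#' @param table a data frame with columns `dose` and `fractional_inhibition`
#'   (>= 4 distinct doses).
#' @param n_boot bootstrap replicates for the CIs (0 disables).
#' @param seed RNG seed for the bootstrap.
#' @return a `hill_fit` list: `k_half` (uM), `hill_coefficient`, `amplitude`,
#'   `residual_rms`, `confidence_intervals` (95 percent, rows K/h/A), `fit`
#'   (the `nls` object).
#' @export
hill_fit <- function(table, n_boot = 200, seed = 1) {
  L <- table$dose
  y <- table$fractional_inhibition
  keep <- L > 0
  if (length(unique(L[keep])) < 4)
    stop("need at least 4 distinct non-zero doses")
  if (stats::sd(y) < 1e-12) stop("degenerate data: all responses equal")
  fit1 <- function(L, y) {
    A0 <- max(y)
    K0 <- tryCatch(stats::approx(y, L, xout = A0 / 2, ties = "ordered")$y,
                   error = function(e) NA)
    if (!is.finite(K0) || K0 <= 0) K0 <- exp(mean(log(L[L > 0])))
    stats::nls(y ~ A * L^h / (K^h + L^h),
               data = data.frame(L = L, y = y),
               start = list(A = max(A0, 0.1), K = K0, h = 1.5),
               lower = c(A = 1e-6, K = 1e-9, h = 0.05),
               upper = c(A = 10, K = 1e6, h = 25),
               algorithm = "port",
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE))
  }
  fit <- tryCatch(fit1(L[keep], y[keep]),
                  error = function(e) stop("Hill fit did not converge: ",
                                           conditionMessage(e)))
  cf <- stats::coef(fit)
  resid <- y[keep] - stats::predict(fit)
  ci <- NULL
  if (n_boot > 0) {
    set.seed(seed)
    bs <- matrix(NA_real_, n_boot, 3)
    yhat <- stats::predict(fit)
    # inflate residuals for the 3 fitted parameters so the resampled noise
    # matches the data noise (classic n/(n-p) correction)
    nr <- length(resid)
    rs <- resid * sqrt(nr / max(nr - 3, 1))
    for (b in seq_len(n_boot)) {
      yb <- yhat + sample(rs, replace = TRUE)
      fb <- tryCatch(stats::coef(fit1(L[keep], yb)), error = function(e) NULL)
      if (!is.null(fb)) bs[b, ] <- fb[c("K", "h", "A")]
    }
    ci <- t(apply(bs, 2, stats::quantile, c(0.025, 0.975), na.rm = TRUE))
    rownames(ci) <- c("k_half", "hill_coefficient", "amplitude")
  }
  structure(list(k_half = unname(cf["K"]), hill_coefficient = unname(cf["h"]),
                 amplitude = unname(cf["A"]),
                 residual_rms = sqrt(mean(resid^2)),
                 confidence_intervals = ci, fit = fit),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("hill_fit: K1/2 = %.3g uM, h = %.3g, A = %.3g (residual rms %.3g)\n",
              x$k_half, x$hill_coefficient, x$amplitude, x$residual_rms))
  invisible(x)
}
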