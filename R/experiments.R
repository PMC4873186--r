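#' Full parameter grids for the response-normalization sweeps
#'
#' The full-scale grids: 11 dot densities log-spaced from 0.01 to 5.12,
#' 30 RF sizes (sigma) in `[0.01, 0.3]` degrees, 11 refresh rates from 1 to
#' 100 Hz, dot radius 0.09 degrees.  Desk-scale runs default to 3x3
#' subgrids of these.
#'
#' @return Named list of grid vectors.
#' @export
sweep_grids <- function() {
  list(densities = exp(seq(log(0.01), log(5.12), length.out = 11)),
       sigmas = seq(0.01, 0.3, length.out = 30),
       refresh_rates = exp(seq(log(1), log(100), length.out = 11)),
       dot_radius = 0.09)
}

## R_norm and its delta-method SE from per-pattern (hm, corr, unc)
## response triplets; the triplets may be correlated (common-random-number
## class coupling), so the full covariance enters.
rnorm_with_se <- function(hm, corr, unc) {
  n <- length(hm)
  m_hm <- mean(hm); m_co <- mean(corr); m_un <- mean(unc)
  den <- m_co - m_un
  if (den <= 0) return(c(R_norm = NA_real_, se = NA_real_))
  num <- m_hm - m_un
  r <- num / den
  g <- c(1 / den, -num / den^2, num / den^2 - 1 / den)
  S <- stats::cov(cbind(hm, corr, unc)) / n
  c(R_norm = r, se = sqrt(drop(t(g) %*% S %*% g)))
}

rnorm_grad <- function(hm, corr, unc) {
  den <- mean(corr) - mean(unc)
  num <- mean(hm) - mean(unc)
  c(1 / den, -num / den^2, num / den^2 - 1 / den)
}

## Difference of two R_norm estimates computed on shared stimuli (paired
## samples): value and delta-method SE using the full 6x6 covariance.
rnorm_diff_se <- function(a, b) {
  r <- function(x) (mean(x$hm) - mean(x$unc)) / (mean(x$corr) - mean(x$unc))
  g <- c(rnorm_grad(a$hm, a$corr, a$unc), -rnorm_grad(b$hm, b$corr, b$unc))
  X <- cbind(a$hm, a$corr, a$unc, b$hm, b$corr, b$unc)
  S <- stats::cov(X) / nrow(X)
  c(diff = r(a) - r(b), se = sqrt(drop(t(g) %*% S %*% g)))
}

#' Normalized half-matched response over a density x RF-size grid
#'
#' Static (space-only) squared-BEM cell probed at its preferred disparity
#' with correlated, half-matched and uncorrelated patterns; reports
#' `R_norm` per (density, sigma) cell.  Low density and small relative RF
#' size (`sigma / r`) increase the local-correlation variability and hence
#' the half-matched response.
#'
#' @param densities,sigmas Grid values (defaults: desk-scale 3x3 subgrid).
#' @param dot_radius_deg Dot radius r, degrees.
#' @param dx Preferred disparity of the probe cell (stimulus disparity
#'   equals it).
#' @param n_patterns Patterns per class per cell.
#' @param params Base stimulus geometry.
#' @param seed Optional integer seed.
#' @return Data frame with columns `density`, `sigma`, `sigma_over_r`,
#'   `R_norm`, `se`, `n`, of class `rnorm_sweep`.  All RF sizes are
#'   evaluated on the same stimuli, so within-cell contrasts between
#'   adjacent sigma values are paired; their differences and paired SEs
#'   are attached as attribute `"sigma_contrasts"`.
#' @export
sweep_density_rf <- function(densities = sweep_grids()$densities[c(4, 6, 8)],
                             sigmas = c(0.06, 0.10, 0.17),
                             dot_radius_deg = 0.09, dx = 0.1,
                             n_patterns = 1000,
                             params = stim_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  units <- lapply(sigmas, function(sg) bem_unit(dx = dx, sigma = sg))
  p0 <- params
  p0$dot_radius_deg <- dot_radius_deg
  p0$disparity_deg <- dx
  bank <- build_filter_bank(units, p0)
  rows <- list(); contrasts <- list()
  for (dens in densities) {
    p <- p0; p$density <- dens
    cls <- engine_static_classes(units, p, n_patterns, bank = bank)
    per_sigma <- lapply(seq_along(sigmas), function(j)
      list(hm = cls$hm[, j]^2, corr = cls$corr[, j]^2, unc = cls$unc[, j]^2))
    for (j in seq_along(sigmas)) {
      rs <- rnorm_with_se(per_sigma[[j]]$hm, per_sigma[[j]]$corr,
                          per_sigma[[j]]$unc)
      rows[[length(rows) + 1L]] <-
        data.frame(density = dens, sigma = sigmas[j],
                   sigma_over_r = sigmas[j] / dot_radius_deg,
                   R_norm = rs[["R_norm"]], se = rs[["se"]],
                   n = n_patterns)
      if (j > 1) {
        dd <- rnorm_diff_se(per_sigma[[j - 1]], per_sigma[[j]])
        contrasts[[length(contrasts) + 1L]] <-
          data.frame(density = dens, sigma_lo = sigmas[j - 1],
                     sigma_hi = sigmas[j], diff = dd[["diff"]],
                     se = dd[["se"]])
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "sigma_contrasts") <- do.call(rbind, contrasts)
  class(out) <- c("rnorm_sweep", "data.frame")
  out
}

#' Normalized half-matched response over a refresh-rate x RF-size grid
#'
#' As [sweep_density_rf()] but with the biphasic temporal kernel active and
#' dynamic stereograms: increasing the pattern refresh rate makes the cell
#' integrate more dots in time, reducing correlation variability and the
#' half-matched response.
#'
#' @param refresh_rates,sigmas Grid values.
#' @param duration_s Trial duration (desk-scale default 2 s).
#' @param n_trials Trials per class per cell.
#' @param kernel Temporal kernel shared by all probes.
#' @inheritParams sweep_density_rf
#' @return Data frame with columns `refresh_hz`, `sigma`, `sigma_over_r`,
#'   `R_norm`, `se`, `n`, of class `rnorm_sweep`, with paired sigma
#'   contrasts in attribute `"sigma_contrasts"` as for
#'   [sweep_density_rf()].
#' @export
sweep_refresh_rf <- function(refresh_rates = sweep_grids()$refresh_rates[c(5, 8, 11)],
                             sigmas = c(0.04, 0.08, 0.16),
                             dot_radius_deg = 0.09, dx = 0.1,
                             n_trials = 1000, duration_s = 2,
                             kernel = temporal_kernel(),
                             params = stim_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  units <- lapply(sigmas, function(sg)
    bem_unit(dx = dx, sigma = sg, kernel = kernel))
  p0 <- params
  p0$dot_radius_deg <- dot_radius_deg
  p0$disparity_deg <- dx
  p0$duration_s <- duration_s
  bank <- build_filter_bank(units, p0)
  rows <- list(); contrasts <- list()
  for (hz in refresh_rates) {
    p <- p0; p$refresh_rate_hz <- hz
    cls <- engine_temporal_classes(units, p, kernel, n_trials, bank = bank)
    per_sigma <- lapply(seq_along(sigmas), function(j)
      list(hm = cls$hm[, j], corr = cls$corr[, j], unc = cls$unc[, j]))
    for (j in seq_along(sigmas)) {
      rs <- rnorm_with_se(per_sigma[[j]]$hm, per_sigma[[j]]$corr,
                          per_sigma[[j]]$unc)
      rows[[length(rows) + 1L]] <-
        data.frame(refresh_hz = hz, sigma = sigmas[j],
                   sigma_over_r = sigmas[j] / dot_radius_deg,
                   R_norm = rs[["R_norm"]], se = rs[["se"]],
                   n = n_trials)
      if (j > 1) {
        dd <- rnorm_diff_se(per_sigma[[j - 1]], per_sigma[[j]])
        contrasts[[length(contrasts) + 1L]] <-
          data.frame(refresh_hz = hz, sigma_lo = sigmas[j - 1],
                     sigma_hi = sigmas[j], diff = dd[["diff"]],
                     se = dd[["se"]])
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "sigma_contrasts") <- do.call(rbind, contrasts)
  class(out) <- c("rnorm_sweep", "data.frame")
  out
}

#' @export
plot.rnorm_sweep <- function(x, ...) {
  xvar <- if (!is.null(x$density)) "density" else "refresh_hz"
  sg <- unique(x$sigma)
  cols <- grDevices::hcl.colors(length(sg), "viridis")
  graphics::plot(range(x[[xvar]]), range(x$R_norm, na.rm = TRUE),
                 type = "n", log = "x", xlab = xvar,
                 ylab = "normalized half-matched response", ...)
  for (i in seq_along(sg)) {
    s <- x[x$sigma == sg[i], ]
    graphics::lines(s[[xvar]], s$R_norm, col = cols[i], lwd = 2)
  }
  graphics::legend("topright", legend = sprintf("sigma/r = %.2f",
                                                unique(x$sigma_over_r)),
                   col = cols, lwd = 2, bty = "n")
  invisible(x)
}

## Shared experiment plumbing: build a population, estimate normalization
## constants and calibrate kappa at a reference condition.
prepare_population <- function(params, exponent = 2, kernel = NULL,
                               spec = population_spec(), n_norm = 200) {
  pop <- build_population(spec, params, exponent = exponent, kernel = kernel)
  estimate_norm_constants(pop, n_patterns = n_norm)
}

#' Correlation psychometric functions at fine and coarse disparity
#'
#' Proportion correct as a function of binocular correlation for fine
#' (+-0.03 deg) and coarse (+-0.48 deg) disparities, with the static
#' (space-only) opponent population updated at 21.25 Hz for 1.5 s.  The
#' noise magnitude is calibrated to the target accuracy for fully
#' correlated fine-disparity stimuli.
#'
#' @param correlations Binocular correlations to probe.
#' @param disparities Disparity magnitudes, degrees.
#' @param n_trials Trials per condition.
#' @param n_cal Stimulus trials used for calibration.
#' @param target Calibration accuracy target.
#' @param params Base stimulus parameters.
#' @param seed Optional integer seed.
#' @return A `psychometric` data frame (all conditions); the calibrated
#'   kappa is in the `kappa` column.
#' @export
correlation_disparity_experiment <- function(correlations = seq(-1, 1, 0.2),
                                             disparities = c(0.03, 0.48),
                                             n_trials = 1000, n_cal = 400,
                                             target = 0.95,
                                             params = stim_params(),
                                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params$refresh_rate_hz <- 21.25
  params$duration_s <- 1.5
  pop <- prepare_population(params)
  cal <- params
  cal$match_level <- 1; cal$disparity_deg <- 0.03
  kap <- calibrate_kappa(pop, target = target, params = cal,
                         n_trials = n_cal)
  cond <- expand.grid(correlation = correlations,
                      disparity_deg = disparities)
  run_psychometric(pop, cond, n_trials = n_trials, kappa = as.numeric(kap))
}

#' Correlation psychometric functions at low and high refresh rate
#'
#' Proportion correct as a function of binocular correlation at fine
#' disparity for two pattern refresh rates, with the biphasic temporal
#' kernel active; the noise magnitude is calibrated per refresh rate at
#' full correlation.
#'
#' @param refresh_rates Refresh rates, Hz.
#' @param disparity_deg Disparity magnitude, degrees.
#' @param kernel Temporal kernel.
#' @inheritParams correlation_disparity_experiment
#' @return A `psychometric` data frame; per-rate kappas in the `kappa`
#'   column.
#' @export
correlation_refresh_experiment <- function(correlations = seq(-1, 1, 0.2),
                                           refresh_rates = c(5.3, 42.5),
                                           disparity_deg = 0.03,
                                           n_trials = 1000, n_cal = 400,
                                           target = 0.95,
                                           kernel = temporal_kernel(),
                                           params = stim_params(),
                                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params$duration_s <- 1.5
  pop <- prepare_population(params, kernel = kernel)
  out <- NULL
  for (hz in refresh_rates) {
    cal <- params
    cal$match_level <- 1; cal$disparity_deg <- disparity_deg
    cal$refresh_rate_hz <- hz
    kap <- calibrate_kappa(pop, target = target, params = cal,
                           n_trials = n_cal)
    cond <- data.frame(correlation = correlations,
                       disparity_deg = disparity_deg,
                       refresh_rate_hz = hz)
    res <- run_psychometric(pop, cond, n_trials = n_trials,
                            kappa = as.numeric(kap))
    out <- if (is.null(out)) res else rbind(out, res)
  }
  class(out) <- c("psychometric", "data.frame")
  out
}

#' Effect of dot size on half-matched depth discrimination
#'
#' Proportion correct for half-matched and fully correlated dynamic
#' stereograms at three dot radii (21.25 Hz refresh, 500 ms, +-0.075 deg,
#' density 24%).  A single noise magnitude is used for all conditions,
#' the smallest that holds every *reachable* correlated condition at or
#' above the target accuracy (human observers are at or above 95% correct
#' for correlated stereograms at every dot size).  At +-0.075 deg the fine
#' cells operate beyond their quarter-cycle limit, and for the smallest
#' dots the summed opponent signal to correlated patterns reverses sign —
#' no noise level can reach the target there, so that condition is
#' excluded from calibration with a warning (see the methods vignette).
#'
#' @param dot_sizes Dot radii, degrees.
#' @param match_levels Match levels probed (0.5 = half-matched, 1 =
#'   correlated).
#' @param disparity_deg Disparity magnitude.
#' @param kernel Temporal kernel.
#' @inheritParams correlation_disparity_experiment
#' @return A `psychometric` data frame with a `dot_radius_deg` column.
#' @export
dot_size_experiment <- function(dot_sizes = c(0.025, 0.05, 0.075),
                                match_levels = c(0.5, 1),
                                disparity_deg = 0.075,
                                n_trials = 1000, n_cal = 300,
                                target = 0.95,
                                kernel = temporal_kernel(),
                                params = stim_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params$refresh_rate_hz <- 21.25
  params$duration_s <- 0.5
  params$density <- 0.24
  pop <- prepare_population(params, kernel = kernel)
  kaps <- vapply(dot_sizes, function(r) {
    cal <- params
    cal$match_level <- 1; cal$disparity_deg <- disparity_deg
    cal$dot_radius_deg <- r
    tryCatch(as.numeric(calibrate_kappa(pop, target = target, params = cal,
                                        n_trials = n_cal)),
             error = function(e) {
               warning("dot size ", r,
                       " deg excluded from calibration: ",
                       conditionMessage(e))
               NA_real_
             })
  }, numeric(1))
  if (all(is.na(kaps)))
    stop("no correlated condition can reach the calibration target")
  kap <- min(kaps, na.rm = TRUE)
  cond <- expand.grid(correlation = 2 * match_levels - 1,
                      dot_radius_deg = dot_sizes)
  cond$disparity_deg <- disparity_deg
  run_psychometric(pop, cond, n_trials = n_trials, kappa = kap)
}

#' Alternating-correlation psychophysics
#'
#' Proportion correct on the near/far task for alternating-correlation
#' stereograms (120 Hz pattern refresh, 500 ms, density 200%, surround
#' following the center, randomized start phase) as a function of the
#' correlation alternation rate.  The band-pass (biphasic) kernel model
#' performs well at slow alternation and falls to chance as the rate
#' increases; a binocularly linear population (`exponent = 1`) is at
#' chance at every rate.
#'
#' @param alternation_rates Alternation rates, Hz.
#' @param disparity_deg Disparity magnitude.
#' @param kernel_kind `"biphasic"` or `"lowpass"`.
#' @param exponent Output exponent (2 = squared model; 1 = linear
#'   pure-correlation control).
#' @inheritParams correlation_disparity_experiment
#' @return A `psychometric` data frame with an `alternation_rate_hz`
#'   column.
#' @export
alternation_experiment <- function(alternation_rates = c(3.75, 7.5, 15, 30, 60),
                                   disparity_deg = 0.03,
                                   kernel_kind = c("biphasic", "lowpass"),
                                   exponent = 2,
                                   n_trials = 1000, n_cal = 300,
                                   target = 0.95,
                                   params = stim_params(density = 2,
                                                        refresh_rate_hz = 120,
                                                        duration_s = 0.5,
                                                        surround_mode = "same_as_center"),
                                   seed = NULL) {
  kernel_kind <- match.arg(kernel_kind)
  if (!is.null(seed)) set.seed(seed)
  kernel <- temporal_kernel(kind = kernel_kind)
  pop <- prepare_population(params, exponent = exponent, kernel = kernel)
  cal <- params
  cal$match_level <- 1; cal$disparity_deg <- disparity_deg
  kap <- tryCatch(as.numeric(calibrate_kappa(pop, target = target,
                                             params = cal,
                                             n_trials = n_cal)),
                  error = function(e) {
                    warning("calibration failed (", conditionMessage(e),
                            "); using kappa = 0")
                    0
                  })
  cond <- data.frame(alternation_rate_hz = alternation_rates,
                     disparity_deg = disparity_deg)
  run_psychometric(pop, cond, n_trials = n_trials, kappa = kap)
}

#' Disparity tuning of the population cell types
#'
#' Mean correlated-stereogram tuning curves for one representative cell of
#' each preferred disparity (fine/coarse, near/far), normalized so all
#' peaks are comparable.
#'
#' @param spec A [population_spec()].
#' @param disparities Stimulus disparities probed.
#' @param n_patterns Patterns per disparity.
#' @param params Stimulus parameters.
#' @param seed Optional integer seed.
#' @return A `bem_tuning`-like data frame with a `dx` column per cell type.
#' @export
population_tuning <- function(spec = population_spec(),
                              disparities = seq(-1, 1, length.out = 21),
                              n_patterns = 500,
                              params = stim_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (d in spec$preferred_disparities) {
    u <- bem_unit(dx = d, sigma = sigma_rule(spec, d),
                  f = spec$freq_c / sigma_rule(spec, d))
    tc <- tuning_curve(u, params, disparities, classes = "correlated",
                       n_patterns = n_patterns)
    tc$dx <- d
    rows[[length(rows) + 1L]] <- as.data.frame(tc)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("population_tuning", "data.frame")
  out
}

#' @export
plot.population_tuning <- function(x, ...) {
  dxs <- unique(x$dx)
  cols <- ifelse(abs(dxs) < 0.1, "darkgreen", "brown")
  lty <- ifelse(dxs > 0, 2, 1)
  graphics::plot(range(x$disparity), range(x$mean_C2), type = "n",
                 xlab = "stimulus disparity (deg)", ylab = "mean C^2", ...)
  for (i in seq_along(dxs)) {
    s <- x[x$dx == dxs[i], ]
    graphics::lines(s$disparity, s$mean_C2, col = cols[i], lty = lty[i],
                    lwd = 2)
  }
  graphics::legend("topright", legend = sprintf("dx = %+.2f", dxs),
                   col = cols, lty = lty, lwd = 2, bty = "n")
  invisible(x)
}
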