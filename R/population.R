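#' Opponent population specification
#'
#' Layout of the model population: four preferred disparities, a fixed
#' number of cells per disparity, receptive-field size scaling with
#' disparity magnitude (the size-disparity correlation,
#' `sigma = a + b * |dx|`), and carrier frequency scaling inversely with RF
#' size (`f = c / sigma`).  Every neuron has an antineuron at the same
#' retinal location with opposite-sign preferred disparity.
#'
#' @param preferred_disparities Preferred disparities, degrees.  Must be
#'   sign-symmetric (each value's negative also present).
#' @param n_per_disparity Cells per disparity (default 40, so 160 total
#'   for the default four disparities).
#' @param sigma_a,sigma_b RF-size rule intercept/slope, degrees.
#' @param freq_c Frequency rule constant, cycles.
#' @param spacing_sigma Minimum centre spacing within a same-disparity
#'   group, in units of sigma ("non-overlapping" receptive fields).  If a
#'   group cannot be packed into the disk at this spacing, the spacing is
#'   relaxed geometrically until placement succeeds (the realized spacing
#'   is recorded in the built population).
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(preferred_disparities = c(-0.48, -0.03, 0.03, 0.48),
                            n_per_disparity = 40L,
                            sigma_a = 0.023, sigma_b = 0.41,
                            freq_c = 0.3125, spacing_sigma = 2) {
  d <- sort(preferred_disparities)
  if (!isTRUE(all.equal(d, sort(-d))))
    stop("preferred_disparities must be sign-symmetric (neuron/antineuron pairs)")
  structure(list(preferred_disparities = preferred_disparities,
                 n_per_disparity = as.integer(n_per_disparity),
                 sigma_a = sigma_a, sigma_b = sigma_b, freq_c = freq_c,
                 spacing_sigma = spacing_sigma),
            class = "population_spec")
}

#' RF size implied by the size-disparity rule
#'
#' @param spec A [population_spec()].
#' @param dx Preferred disparity, degrees.
#' @return Envelope SD sigma in degrees.
#' @export
sigma_rule <- function(spec, dx) spec$sigma_a + spec$sigma_b * abs(dx)

## Greedy dart-throwing with geometric spacing relaxation.  Returns the
## centre coordinates and the realized spacing.
place_centres <- function(n, radius, min_dist, max_attempts = 400L) {
  s <- min_dist
  repeat {
    xs <- numeric(0); ys <- numeric(0)
    fails <- 0L
    while (length(xs) < n && fails < max_attempts * n) {
      p <- runif_disk(1L, radius)
      if (length(xs) == 0 ||
          min((xs - p[1])^2 + (ys - p[2])^2) >= s^2) {
        xs <- c(xs, p[1]); ys <- c(ys, p[2]); fails <- 0L
      } else fails <- fails + 1L
    }
    if (length(xs) == n)
      return(list(x = xs, y = ys, spacing = s))
    s <- s * 0.85
    if (s < 1e-6)
      stop("cannot place ", n, " receptive fields in the disk ",
           "(spacing rule exhausted)")
  }
}

#' Build the opponent BEM population
#'
#' Places `n_per_disparity` receptive-field centres per disparity-magnitude
#' group uniformly inside the disparity-defined disk, with centres within a
#' group at least `spacing_sigma * sigma` apart (relaxed if geometrically
#' infeasible); each location hosts a neuron (+|dx|) and its antineuron
#' (-|dx|), otherwise identical.
#'
#' @param spec A [population_spec()].
#' @param params Stimulus geometry ([stim_params()]).
#' @param exponent Output exponent of every unit (2 = squared model,
#'   1 = binocularly linear reference).
#' @param kernel A shared [temporal_kernel()] or `NULL` for the static
#'   (space-only) model.
#' @param phi Carrier phase of the first subunit, radians.
#' @param seed Optional integer seed for the placement.
#' @return An object of class `bem_population`: unit table (`units`), unit
#'   objects, precomputed filter bank, and slots for normalization
#'   constants (`norm_const`) filled by [estimate_norm_constants()].
#' @export
build_population <- function(spec = population_spec(),
                             params = stim_params(),
                             exponent = 2, kernel = NULL, phi = 0,
                             seed = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.null(seed)) set.seed(seed)
  radius <- params$disk_diameter_deg / 2
  mags <- sort(unique(abs(spec$preferred_disparities)))
  rows <- list(); spacings <- numeric(0)
  pair <- 0L
  for (m in mags) {
    sg <- sigma_rule(spec, m)
    pl <- place_centres(spec$n_per_disparity, radius, spec$spacing_sigma * sg)
    spacings[as.character(m)] <- pl$spacing
    for (j in seq_len(spec$n_per_disparity)) {
      pair <- pair + 1L
      for (sgn in c(1, -1)) {
        rows[[length(rows) + 1L]] <-
          data.frame(pair = pair, sign = sgn, dx = sgn * m, sigma = sg,
                     f = spec$freq_c / sg, x0 = pl$x[j], y0 = pl$y[j])
      }
    }
  }
  units_df <- do.call(rbind, rows)
  units_df$id <- seq_len(nrow(units_df))
  unit_objs <- lapply(seq_len(nrow(units_df)), function(i) {
    r <- units_df[i, ]
    bem_unit(r$x0, r$y0, r$dx, r$sigma, r$f, phi = phi,
             exponent = exponent, kernel = kernel)
  })
  bank <- build_filter_bank(unit_objs, params)
  structure(list(spec = spec, params = params, units = units_df,
                 unit_objs = unit_objs, bank = bank, exponent = exponent,
                 kernel = kernel, norm_const = NULL,
                 norm_const_refresh_hz = NA_real_,
                 realized_spacing = spacings),
            class = "bem_population")
}

#' @export
print.bem_population <- function(x, ...) {
  cat(sprintf("BEM population: %d units (%d neuron/antineuron pairs), exponent %d, %s\n",
              nrow(x$units), max(x$units$pair), x$exponent,
              if (is.null(x$kernel)) "static" else
                paste(x$kernel$kind, "temporal kernel")))
  agg <- unique(x$units[, c("dx", "sigma", "f")])
  agg <- agg[order(agg$dx), ]
  print(agg, row.names = FALSE)
  cat(sprintf("  normalization constants: %s\n",
              if (is.null(x$norm_const)) "not estimated"
              else sprintf("estimated at %.4g Hz", x$norm_const_refresh_hz)))
  invisible(x)
}

## Per-trial summed responses of all population units to one condition.
## Returns matrices (n_trials x n_units) of time-summed C and C^2, plus the
## number of time points per trial.
population_trial_sums <- function(pop, params, n_trials, match_fun = NULL,
                                  uncorrelated = FALSE) {
  if (is.null(pop$kernel)) {
    sch <- frame_schedule(params$refresh_rate_hz, params$duration_s)
    nu <- nrow(pop$units)
    sumC <- matrix(0, n_trials, nu); sumC2 <- matrix(0, n_trials, nu)
    per <- 32L  # frames per engine batch chunk is handled inside engine
    for (tr in seq_len(n_trials)) {
      ml <- if (is.null(match_fun)) params$match_level else match_fun(sch$n_frames)
      p <- params; p$match_level <- ml[1]
      dots <- gen_dots(p, sch$n_frames, match_level = ml,
                       uncorrelated = uncorrelated)
      M <- frame_responses(pop$bank, params, dots)
      C <- frames_to_C(M)
      sumC[tr, ] <- colSums(C)
      sumC2[tr, ] <- colSums(C * C)
    }
    list(sumC = sumC, sumC2 = sumC2, n_t = sch$n_frames)
  } else {
    engine_temporal(pop$unit_objs, params, pop$kernel, n_trials,
                    match_fun = match_fun, uncorrelated = uncorrelated,
                    bank = pop$bank)
  }
}

## Summed response on the model's output scale (C^2 or C).
output_sums <- function(pop, sums) {
  if (pop$exponent == 2) sums$sumC2 else sums$sumC
}

#' Estimate response normalization constants
#'
#' For each unit, the mean per-time-point output response to 100%
#' correlated stereograms at the unit's preferred disparity, presented at
#' the reference refresh rate (21.25 Hz).  Dividing responses by these
#' constants gives every cell the same mean response (1) to preferred
#' correlated stimuli; the constants are held fixed across all conditions.
#'
#' @param pop A [build_population()] object.
#' @param n_patterns Minimum number of distinct dot patterns contributing
#'   per unit (at least 100 recommended).
#' @param refresh_rate_hz Reference refresh rate.
#' @param duration_s Duration of each estimation trial.
#' @param seed Optional integer seed.
#' @return The population with `norm_const` filled.
#' @export
estimate_norm_constants <- function(pop, n_patterns = 200,
                                    refresh_rate_hz = 21.25,
                                    duration_s = 1, seed = NULL) {
  stopifnot(inherits(pop, "bem_population"))
  if (!is.null(seed)) set.seed(seed)
  params <- pop$params
  params$refresh_rate_hz <- refresh_rate_hz
  params$duration_s <- duration_s
  params$match_level <- 1
  sch <- frame_schedule(refresh_rate_hz, duration_s)
  n_trials <- max(2L, ceiling(n_patterns / sch$n_frames))
  const <- numeric(nrow(pop$units))
  for (d in unique(pop$units$dx)) {
    p <- params; p$disparity_deg <- d
    sums <- population_trial_sums(pop, p, n_trials)
    resp <- output_sums(pop, sums) / sums$n_t
    sel <- pop$units$dx == d
    const[sel] <- colMeans(resp)[sel]
  }
  if (any(const <= 0)) stop("non-positive normalization constant estimated")
  pop$norm_const <- const
  pop$norm_const_refresh_hz <- refresh_rate_hz
  pop
}

#' Noisy scaled response of one unit
#'
#' The literal noise model: `P_k = c_k + kappa * eps_k` with
#' `c_k = C2_k / norm_const` the normalized response and
#' `eps_k ~ N(0, c_k)` independent across time points (the noise variance
#' is proportional to the instantaneous response).
#'
#' @param C2_trace Raw output-response trace of a unit (one value per time
#'   point).
#' @param norm_const The unit's normalization constant.
#' @param kappa Noise magnitude (>= 0).
#' @return Noisy normalized response trace `P`.
#' @export
noisy_response <- function(C2_trace, norm_const, kappa) {
  if (kappa < 0) stop("'kappa' must be >= 0")
  stopifnot(norm_const > 0, all(C2_trace >= 0))
  c_k <- C2_trace / norm_const
  c_k + kappa * sqrt(c_k) * stats::rnorm(length(c_k))
}

check_normalized <- function(pop) {
  if (is.null(pop$norm_const))
    stop("population has no normalization constants; run estimate_norm_constants() first")
}

#' Single-trial opponent decision
#'
#' Runs the full literal decision pipeline on one stimulus: per-unit
#' normalized responses at every time point, independent Gaussian noise per
#' unit and time point (variance proportional to the instantaneous
#' response), opponent sums `R(i)` over neuron/antineuron pairs, and the
#' near/far readout: `Psi = 1` (far) iff `sum_i R(i) > 0`, else 0 (near) —
#' an exact zero sum reads out as near.
#'
#' @param pop A normalized [build_population()] object.
#' @param seq A `stereo_frames` stimulus (its geometry must match the
#'   population's).
#' @param kappa Noise magnitude.
#' @return List with `R_per_pair`, `decision` (0 near / 1 far), `correct`
#'   (given the stimulus disparity sign), and the decision variable `D`.
#' @export
decide_trial <- function(pop, seq, kappa = 0) {
  stopifnot(inherits(pop, "bem_population"), inherits(seq, "stereo_frames"))
  check_normalized(pop)
  if (kappa < 0) stop("'kappa' must be >= 0")
  params <- seq$params
  nf <- dim(seq$left)[3]
  bank <- pop$bank
  nfilt <- bank$n_filt
  M <- matrix(0, nf, nfilt)
  for (f in seq_len(nf))
    M[f, ] <- bank_eval_images(bank, seq$left[, , f], seq$right[, , f])
  if (is.null(pop$kernel)) {
    C <- frames_to_C(M)
  } else {
    k <- sample_kernel(pop$kernel)
    H <- build_hold_matrix(k, seq$frame_times, params$duration_s)
    nu <- nfilt %/% 4L
    i4 <- (seq_len(nu) - 1L) * 4L
    U1 <- H %*% (M[, i4 + 1L, drop = FALSE] + M[, i4 + 2L, drop = FALSE])
    U2 <- H %*% (M[, i4 + 3L, drop = FALSE] + M[, i4 + 4L, drop = FALSE])
    C <- U1 * U1 + U2 * U2
  }
  resp <- if (pop$exponent == 2) C * C else C
  cnorm <- sweep(resp, 2, pop$norm_const, "/")
  P <- cnorm + kappa * sqrt(cnorm) *
    matrix(stats::rnorm(length(cnorm)), nrow(cnorm))
  s <- colSums(P)
  pos <- pop$units$sign > 0
  ord_p <- order(pop$units$pair[pos]); ord_n <- order(pop$units$pair[!pos])
  R_pair <- s[pos][ord_p] - s[!pos][ord_n]
  D <- sum(R_pair)
  decision <- as.integer(D > 0)
  list(R_per_pair = R_pair, decision = decision,
       correct = if (params$disparity_deg == 0) NA else
         (decision == 1) == (params$disparity_deg > 0),
       D = D)
}

## Per-trial decision statistics for a batch of simulated trials:
## signal S_j = sum_i sign_i * s_ij and noise variance V_j = kappa^2 *
## sum_i s_ij, where s_ij is unit i's normalized time-summed response.
## The per-time-point, per-unit Gaussian noise of the model sums to exactly
## this law, so one draw per trial reproduces the decision distribution.
trial_decision_stats <- function(pop, params, n_trials, match_fun = NULL,
                                 uncorrelated = FALSE) {
  check_normalized(pop)
  sums <- population_trial_sums(pop, params, n_trials,
                                match_fun = match_fun,
                                uncorrelated = uncorrelated)
  snorm <- sweep(output_sums(pop, sums), 2, pop$norm_const, "/")
  list(S = as.numeric(snorm %*% pop$units$sign),
       V = rowSums(snorm))
}

#' Simulate decision-model trials
#'
#' Draws `nsim` independent stimulus realizations of one condition and runs
#' the opponent decision model on each.
#'
#' @param object A normalized [build_population()] object.
#' @param nsim Number of trials.
#' @param seed Optional integer seed.
#' @param params Stimulus condition ([stim_params()]); defaults to the
#'   population's build geometry.
#' @param kappa Noise magnitude.
#' @param ... Unused.
#' @return Data frame with per-trial decision variable `D`, `decision`
#'   and `correct`.
#' @export
simulate.bem_population <- function(object, nsim = 1, seed = NULL,
                                    params = object$params, kappa = 0, ...) {
  if (!is.null(seed)) set.seed(seed)
  st <- trial_decision_stats(object, params, nsim)
  D <- st$S + kappa * sqrt(st$V) * stats::rnorm(nsim)
  decision <- as.integer(D > 0)
  data.frame(D = D, decision = decision,
             correct = if (params$disparity_deg == 0) NA else
               (decision == 1) == (params$disparity_deg > 0))
}

#' Calibrate the noise magnitude to a target accuracy
#'
#' Finds `kappa` such that the model's proportion correct at a reference
#' condition equals `target`.  Stimulus trials are simulated once; because
#' the trial noise enters the decision variable as a single Gaussian with
#' known variance, the expected accuracy at any `kappa` is
#' `mean(Phi(g_j S_j / (kappa sqrt(V_j))))` over the simulated trials
#' (`g_j` the disparity sign), a smooth monotone function solved by root
#' finding.  Accuracy decreases monotonically in `kappa` towards chance.
#'
#' @param pop A normalized [build_population()] object.
#' @param target Target proportion correct, in (0.5, 1).
#' @param params Reference condition; defaults to 100% correlated,
#'   +-0.03 deg, 21.25 Hz, 1.5 s.
#' @param n_trials Stimulus trials used to estimate the accuracy curve.
#' @param bounds Search bounds for `kappa`.
#' @param seed Optional integer seed.
#' @return The calibrated `kappa`, with the noise-free ceiling accuracy as
#'   attribute `"ceiling"`.
#' @export
calibrate_kappa <- function(pop, target = 0.95, params = NULL,
                            n_trials = 400, bounds = c(1e-4, 1e4),
                            seed = NULL) {
  stopifnot(target > 0.5, target < 1)
  check_normalized(pop)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(params)) {
    params <- pop$params
    params$match_level <- 1
    params$refresh_rate_hz <- 21.25
    params$duration_s <- 1.5
    params$disparity_deg <- 0.03
  }
  half <- n_trials %/% 2
  g <- rep(c(1, -1), length.out = 2 * half)
  S <- numeric(2 * half); V <- numeric(2 * half)
  for (sgn in c(1, -1)) {
    p <- params; p$disparity_deg <- sgn * abs(params$disparity_deg)
    st <- trial_decision_stats(pop, p, half)
    sel <- which(g == sgn)
    S[sel] <- st$S; V[sel] <- st$V
  }
  acc <- function(kap) mean(stats::pnorm(g * S / (kap * sqrt(pmax(V, 1e-300)))))
  ceiling_acc <- mean(g * S > 0)
  if (ceiling_acc < target)
    stop(sprintf(paste0("target accuracy %.3f unreachable: noise-free ",
                        "ceiling is %.3f at this condition"),
         target, ceiling_acc))
  lo <- bounds[1]; hi <- bounds[2]
  if (acc(lo) < target || acc(hi) > target)
    stop(sprintf("target not bracketed: acc(%g) = %.3f, acc(%g) = %.3f",
                 lo, acc(lo), hi, acc(hi)))
  kap <- stats::uniroot(function(k) acc(k) - target, c(lo, hi),
                        tol = 1e-6)$root
  attr(kap, "ceiling") <- ceiling_acc
  kap
}

#' Simulated psychophysics over a condition grid
#'
#' For each row of `conditions`, simulates `n_trials` near/far trials
#' (balanced between the two disparity signs) through the opponent decision
#' model and reports the proportion correct with exact binomial 95%
#' confidence intervals.
#'
#' @param pop A normalized [build_population()] object.
#' @param conditions Data frame; recognized columns (all optional):
#'   `correlation` (binocular correlation, -1..1), `disparity_deg`
#'   (magnitude), `refresh_rate_hz`, `duration_s`, `dot_radius_deg`,
#'   `density`, `alternation_rate_hz` (alternating-correlation stimulus
#'   with randomized start phase), `uncorrelated` (logical).
#' @param n_trials Trials per condition row.
#' @param kappa Noise magnitude (scalar or one per row).
#' @param seed Optional integer seed.
#' @return A `psychometric` data frame: the conditions plus
#'   `proportion_correct`, `ci_lo`, `ci_hi`, `n_trials`, `kappa`.
#' @export
run_psychometric <- function(pop, conditions, n_trials = 1000, kappa = 0,
                             seed = NULL) {
  stopifnot(inherits(pop, "bem_population"), n_trials >= 2)
  check_normalized(pop)
  if (!is.null(seed)) set.seed(seed)
  kappa <- rep_len(kappa, nrow(conditions))
  out <- conditions
  out$proportion_correct <- NA_real_
  out$ci_lo <- NA_real_; out$ci_hi <- NA_real_
  out$n_trials <- NA_integer_; out$kappa <- kappa
  for (i in seq_len(nrow(conditions))) {
    cd <- conditions[i, , drop = FALSE]
    params <- pop$params
    if (!is.null(cd$correlation) && !is.na(cd$correlation))
      params$match_level <- (cd$correlation + 1) / 2
    for (fld in c("disparity_deg", "refresh_rate_hz", "duration_s",
                  "dot_radius_deg", "density"))
      if (!is.null(cd[[fld]]) && !is.na(cd[[fld]]))
        params[[fld]] <- cd[[fld]]
    uncorr <- isTRUE(cd$uncorrelated)
    match_fun <- NULL
    if (!is.null(cd$alternation_rate_hz) && !is.na(cd$alternation_rate_hz)) {
      params$surround_mode <- "same_as_center"
      ap <- alternation_params(params, cd$alternation_rate_hz)
      match_fun <- function(nf)
        alternation_match_levels(ap, nf, stats::runif(1) < 0.5)
    }
    half <- n_trials %/% 2
    n_used <- as.integer(2 * half)
    correct <- logical(0)
    for (sgn in c(1, -1)) {
      p <- params
      p$disparity_deg <- sgn * abs(params$disparity_deg)
      st <- trial_decision_stats(pop, p, half, match_fun = match_fun,
                                 uncorrelated = uncorr)
      D <- st$S + kappa[i] * sqrt(st$V) * stats::rnorm(half)
      correct <- c(correct, (D > 0) == (sgn > 0))
    }
    x <- sum(correct)
    ci <- binomial_ci(x, n_used)
    out$proportion_correct[i] <- x / n_used
    out$ci_lo[i] <- ci[1]; out$ci_hi[i] <- ci[2]
    out$n_trials[i] <- n_used
  }
  class(out) <- c("psychometric", "data.frame")
  out
}

#' @export
print.psychometric <- function(x, ...) {
  cat("Simulated psychophysics (proportion correct, exact binomial 95% CI)\n")
  print.data.frame(as.data.frame(x), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
summary.psychometric <- function(object, ...) {
  cat(sprintf("%d condition(s), %d trials each\n", nrow(object),
              object$n_trials[1]))
  cat(sprintf("proportion correct: min %.3f, max %.3f\n",
              min(object$proportion_correct), max(object$proportion_correct)))
  if (!is.null(object$correlation) && all(!is.na(object$correlation)) &&
      length(unique(object$correlation)) > 2) {
    fa <- fractional_area(object)
    cat(sprintf("fractional area (odd-symmetry of the fitted curve): %.3f\n", fa))
  }
  invisible(object)
}

#' @export
plot.psychometric <- function(x, xvar = NULL, ...) {
  if (is.null(xvar)) {
    for (cand in c("correlation", "dot_radius_deg", "alternation_rate_hz",
                   "refresh_rate_hz"))
      if (!is.null(x[[cand]]) && length(unique(x[[cand]])) > 1) {
        xvar <- cand; break
      }
    if (is.null(xvar)) xvar <- names(x)[1]
  }
  graphics::plot(x[[xvar]], x$proportion_correct, ylim = c(0, 1), pch = 16,
                 xlab = xvar, ylab = "proportion correct", ...)
  graphics::arrows(x[[xvar]], x$ci_lo, x[[xvar]], x$ci_hi, length = 0.02,
                   angle = 90, code = 3)
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}
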