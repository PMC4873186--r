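#' Exact binomial confidence interval
#'
#' Clopper-Pearson interval for a binomial proportion, via the beta-quantile
#' form: `lo = qbeta(a/2, x, n - x + 1)`, `hi = qbeta(1 - a/2, x + 1, n - x)`
#' with `lo = 0` at `x = 0` and `hi = 1` at `x = n`.
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials.
#' @param level Confidence level (default 0.95).
#' @return Length-2 vector `c(lo, hi)`; attribute `"method"` records the
#'   interval type.
#' @export
binomial_ci <- function(successes, n, level = 0.95) {
  stopifnot(n >= 1, successes >= 0, successes <= n, level > 0, level < 1)
  a <- 1 - level
  lo <- if (successes == 0) 0 else
    stats::qbeta(a / 2, successes, n - successes + 1)
  hi <- if (successes == n) 1 else
    stats::qbeta(1 - a / 2, successes + 1, n - successes)
  structure(c(lo, hi), method = "Clopper-Pearson")
}

#' Monte-Carlo dispersion test for binomial proportions
#'
#' Tests whether proportions measured in several groups (e.g. proportion
#' correct at several dot sizes) vary more than binomial sampling predicts
#' — a resampling analogue of one-way ANOVA for binomial data.  Under the
#' null every group shares the success probability `p0 = mean(props)`;
#' each resample draws one binomial count per group at `p0` and measures
#' the across-group variance in proportion.  The p-value is the fraction
#' of resamples whose variance reaches the observed variance, with the
#' (+1)/(+1) small-sample correction:
#' `p = (1 + #\{var* >= var_obs\}) / (n_resamples + 1)`.
#'
#' @param props Observed proportions per group.
#' @param n_per_group Trials per group (scalar or vector).
#' @param n_resamples Number of null resamples (>= 1000 recommended; a
#'   warning is issued below that).
#' @param seed Optional integer seed.
#' @return The p-value, with the observed variance as attribute
#'   `"statistic"`.
#' @export
mc_proportion_test <- function(props, n_per_group, n_resamples = 1e5,
                               seed = NULL) {
  stopifnot(length(props) >= 2, all(props >= 0 & props <= 1),
            all(n_per_group >= 1))
  if (n_resamples < 1000)
    warning("fewer than 1000 resamples: p-value resolution is coarse")
  if (!is.null(seed)) set.seed(seed)
  g <- length(props)
  n_per_group <- rep_len(n_per_group, g)
  p0 <- mean(props)
  v_obs <- stats::var(props)
  draws <- matrix(stats::rbinom(g * n_resamples, n_per_group, p0) /
                    n_per_group, nrow = g)
  m <- colMeans(draws)
  v_null <- (colSums(draws^2) - g * m^2) / (g - 1)
  p <- (1 + sum(v_null >= v_obs - 1e-15)) / (n_resamples + 1)
  structure(p, statistic = v_obs)
}

#' Fractional area of a psychometric function of correlation
#'
#' Quantifies the odd-symmetry of a proportion-correct-vs-correlation
#' curve.  A monotone shape-preserving spline is interpolated through the
#' condition means on correlation in `[-1, 1]`, clipped to `[0, 1]`, and
#' the areas of its deviation from chance are integrated on each side of
#' zero: `A- = integral over [-1, 0] of |fit - 0.5|`, `A+ = the same over
#' [0, 1]`; the fractional area is `A- / A+`.  A value of 1 means the
#' deviations from chance are symmetric for anticorrelated and correlated
#' stimuli; 0 means all of the different-from-chance performance occurs at
#' positive correlations.
#'
#' @param x A `psychometric` data frame with a `correlation` column, or a
#'   numeric vector of correlations (then give `prop`).
#' @param prop Proportions correct matching `x` when `x` is numeric.
#' @param n_grid Integration grid size.
#' @param raw Also compute the trapezoid-on-raw-points variant (returned
#'   as attribute `"raw"`).
#' @return Fractional area in `[0, Inf)` (undefined, `NA`, if `A+ = 0`);
#'   attribute `"definition"` records the formula.
#' @export
fractional_area <- function(x, prop = NULL, n_grid = 2001L, raw = TRUE) {
  if (is.data.frame(x)) {
    stopifnot(!is.null(x$correlation))
    prop <- x$proportion_correct
    x <- x$correlation
  }
  stopifnot(length(x) == length(prop), length(x) >= 3)
  o <- order(x)
  x <- x[o]; prop <- prop[o]
  if (min(x) > -1 + 1e-9 || max(x) < 1 - 1e-9)
    stop("curve must cover correlation in [-1, 1]")
  fit <- stats::splinefun(x, prop, method = "monoH.FC")
  area <- function(a, b) {
    g <- seq(a, b, length.out = n_grid)
    y <- abs(pmin(pmax(fit(g), 0), 1) - 0.5)
    sum((y[-1] + y[-n_grid]) / 2) * (b - a) / (n_grid - 1)
  }
  a_neg <- area(-1, 0); a_pos <- area(0, 1)
  fa <- if (a_pos <= 0) NA_real_ else a_neg / a_pos
  if (raw) {
    trap <- function(xx, yy) sum(diff(xx) * (abs(yy - 0.5)[-1] +
                                             abs(yy - 0.5)[-length(yy)]) / 2)
    neg <- x <= 0; pos <- x >= 0
    ap <- trap(x[pos], prop[pos])
    attr(fa, "raw") <- if (ap <= 0) NA_real_ else trap(x[neg], prop[neg]) / ap
  }
  attr(fa, "definition") <-
    "A-/A+ with A± = ∫ |fit - 0.5| over [-1,0] / [0,1], monotone spline fit clipped to [0,1]"
  fa
}
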