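test_that("exact binomial intervals hit their boundary cases", {
  expect_equal(binomial_ci(10, 10)[2], 1)
  expect_equal(binomial_ci(0, 10)[1], 0)
  ci <- binomial_ci(20, 40)
  expect_lt(ci[1], 0.5)
  expect_gt(ci[2], 0.5)
  expect_error(binomial_ci(11, 10), "successes")
})

test_that("binomial intervals match an exhaustive tail-probability oracle", {
  # oracle: smallest/largest p whose binomial tail reaches alpha/2,
  # found by root finding on the exact tail sums
  oracle_ci <- function(x, n, level = 0.95) {
    a <- (1 - level) / 2
    lo <- if (x == 0) 0 else
      stats::uniroot(function(p) 1 - pbinom(x - 1, n, p) - a,
                     c(1e-12, 1 - 1e-12), tol = 1e-12)$root
    hi <- if (x == n) 1 else
      stats::uniroot(function(p) pbinom(x, n, p) - a,
                     c(1e-12, 1 - 1e-12), tol = 1e-12)$root
    c(lo, hi)
  }
  for (case in list(c(20, 40), c(1, 40), c(39, 40), c(7, 13), c(0, 25),
                    c(25, 25))) {
    got <- binomial_ci(case[1], case[2])
    expect_equal(unname(as.numeric(got)), oracle_ci(case[1], case[2]),
                 tolerance = 1e-6)
  }
})

test_that("the Monte-Carlo dispersion test behaves at its extremes", {
  # identical group proportions: observed variance 0, every resample ties
  # or exceeds it
  expect_equal(as.numeric(mc_proportion_test(c(0.8, 0.8, 0.8), 40,
                                             n_resamples = 2000, seed = 60)),
               1)
  # extreme separation: tiny p-value
  p <- mc_proportion_test(c(1, 0.95, 0.5), 40, n_resamples = 1e5, seed = 61)
  expect_lt(p, 0.001)
  expect_gt(p, 0)  # the +1/+1 correction keeps p positive
  expect_warning(mc_proportion_test(c(0.5, 0.6), 40, n_resamples = 500,
                                    seed = 62), "resamples")
})

test_that("fractional area hits the caption anchors exactly", {
  x <- seq(-1, 1, 0.2)
  # odd-symmetric curve about (0, 0.5)
  fa1 <- fractional_area(x, 0.5 + 0.4 * x)
  expect_equal(as.numeric(fa1), 1)
  expect_equal(attr(fa1, "raw"), 1)
  # chance for all negative correlations, above chance for positive
  y <- ifelse(x <= 0, 0.5, 0.5 + 0.5 * x)
  fa0 <- fractional_area(x, y)
  expect_equal(as.numeric(fa0), 0)
})

test_that("fractional area agrees with a high-resolution quadrature oracle", {
  x <- seq(-1, 1, 0.25)
  set.seed(63)
  y <- pmin(pmax(0.45 + 0.35 * (x + 0.2 * x^3) + 0.02, 0), 1)
  fit <- stats::splinefun(x, y, method = "monoH.FC")
  grid <- seq(-1, 1, length.out = 40001)
  yy <- abs(pmin(pmax(fit(grid), 0), 1) - 0.5)
  trap <- function(i) {
    g <- grid[i]; v <- yy[i]
    sum(diff(g) * (v[-1] + v[-length(v)]) / 2)
  }
  oracle <- trap(which(grid <= 0)) / trap(which(grid >= 0))
  expect_equal(as.numeric(fractional_area(x, y)), oracle, tolerance = 1e-4)
})

test_that("curves must span the correlation axis", {
  expect_error(fractional_area(seq(-0.5, 1, 0.5), rep(0.6, 4)), "cover")
})
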