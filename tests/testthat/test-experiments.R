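test_that("response-normalization sweeps return well-formed grids", {
  s <- sweep_density_rf(densities = c(0.12, 0.48), sigmas = c(0.04, 0.1),
                        n_patterns = 150, params = small_params(),
                        dx = 0.08, seed = 70)
  expect_identical(nrow(s), 4L)
  expect_true(all(is.finite(s$R_norm)))
  expect_true(all(s$se > 0))
  expect_equal(s$sigma_over_r, s$sigma / 0.09)
  # half-matched response rises when the RF shrinks relative to the dots
  lo <- s$R_norm[s$sigma == 0.04 & s$density == 0.12]
  hi <- s$R_norm[s$sigma == 0.1 & s$density == 0.48]
  expect_gt(lo, hi)
})

test_that("psychometric runs report exact binomial intervals per condition", {
  pop <- small_population(params = stim_params(duration_s = 0.25),
                          seed = 71)
  pop <- estimate_norm_constants(pop, n_patterns = 80, seed = 72)
  cond <- data.frame(correlation = c(1, 1), disparity_deg = c(0.48, 0.48),
                     duration_s = 0.25)
  res <- run_psychometric(pop, cond, n_trials = 60, kappa = c(0, 50),
                          seed = 73)
  expect_s3_class(res, "psychometric")
  expect_true(all(res$ci_lo <= res$proportion_correct &
                    res$proportion_correct <= res$ci_hi))
  expect_identical(res$n_trials, c(60L, 60L))
  # heavy noise drags accuracy toward chance
  expect_gt(res$proportion_correct[1], res$proportion_correct[2])
})

test_that("alternating-correlation conditions run through the harness", {
  p <- stim_params(refresh_rate_hz = 120, duration_s = 0.1, density = 1,
                   surround_mode = "same_as_center")
  pop <- small_population(params = p, kernel = temporal_kernel(), seed = 74)
  pop <- estimate_norm_constants(pop, n_patterns = 40, seed = 75)
  cond <- data.frame(alternation_rate_hz = c(15, 60), disparity_deg = 0.03)
  res <- run_psychometric(pop, cond, n_trials = 40, kappa = 1, seed = 76)
  expect_identical(nrow(res), 2L)
  expect_true(all(res$proportion_correct >= 0 & res$proportion_correct <= 1))
})

test_that("summary and fractional area integrate with psychometric output", {
  res <- structure(
    data.frame(correlation = seq(-1, 1, 0.25),
               proportion_correct = c(0.3, 0.35, 0.4, 0.45, 0.5, 0.62,
                                      0.75, 0.87, 0.97),
               ci_lo = 0, ci_hi = 1, n_trials = 100L, kappa = 1),
    class = c("psychometric", "data.frame"))
  fa <- fractional_area(res)
  expect_true(fa > 0 && fa < 1)
  expect_output(summary(res), "fractional area")
})
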