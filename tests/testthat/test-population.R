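test_that("size-disparity and frequency rules evaluate exactly", {
  spec <- population_spec()
  expect_equal(sigma_rule(spec, 0.03), 0.023 + 0.41 * 0.03)  # 0.0353
  expect_equal(sigma_rule(spec, -0.48), 0.023 + 0.41 * 0.48)
  expect_equal(sigma_rule(spec, 0), 0.023)
  expect_equal(spec$freq_c / sigma_rule(spec, 0), 0.3125 / 0.023)
  expect_error(population_spec(preferred_disparities = c(-0.1, 0.2, 0.3)),
               "sign-symmetric")
})

test_that("the population pairs every neuron with its antineuron", {
  pop <- small_population(seed = 31)
  u <- pop$units
  expect_identical(nrow(u), 32L)           # 4 disparities x 8
  expect_identical(max(u$pair), 16L)
  for (pr in unique(u$pair)) {
    pair <- u[u$pair == pr, ]
    expect_identical(nrow(pair), 2L)
    expect_equal(pair$dx[1], -pair$dx[2])
    expect_equal(pair$x0[1], pair$x0[2])   # same retinal location
    expect_equal(pair$y0[1], pair$y0[2])
  }
  # centres inside the disparity-defined disk
  expect_true(all(sqrt(u$x0^2 + u$y0^2) <=
                    pop$params$disk_diameter_deg / 2 + 1e-9))
})

test_that("within-group centre spacing respects the realized spacing", {
  pop <- small_population(seed = 32)
  u <- pop$units[pop$units$sign > 0, ]
  for (m in unique(abs(u$dx))) {
    g <- u[abs(u$dx) == m, ]
    dmat <- as.matrix(stats::dist(g[, c("x0", "y0")]))
    mind <- min(dmat[upper.tri(dmat)])
    expect_gte(mind, pop$realized_spacing[[as.character(m)]] - 1e-9)
  }
})

test_that("normalization constants are positive and normalize to 1", {
  pop <- small_population(seed = 33)
  pop <- estimate_norm_constants(pop, n_patterns = 120, seed = 34)
  expect_true(all(pop$norm_const > 0))
  # fresh correlated ensemble at one preferred disparity: normalized mean
  # response within 3 SE of 1
  p <- pop$params
  p$match_level <- 1; p$disparity_deg <- 0.03
  p$refresh_rate_hz <- 21.25; p$duration_s <- 1
  set.seed(35)
  sums <- stereobem:::population_trial_sums(pop, p, 30)
  sel <- pop$units$dx == 0.03
  resp <- sweep(sums$sumC2 / sums$n_t, 2, pop$norm_const, "/")[, sel]
  m <- colMeans(resp); se <- apply(resp, 2, sd) / sqrt(nrow(resp))
  expect_lt(stats::median(abs(m - 1) / se), 3)
})

test_that("smaller receptive fields respond less to uncorrelated patterns", {
  pop <- small_population(seed = 36)
  pop <- estimate_norm_constants(pop, n_patterns = 150, seed = 37)
  p <- pop$params
  p$refresh_rate_hz <- 21.25; p$duration_s <- 1
  set.seed(38)
  sums <- stereobem:::population_trial_sums(pop, p, 40, uncorrelated = TRUE)
  resp <- sweep(sums$sumC2 / sums$n_t, 2, pop$norm_const, "/")
  fine <- abs(pop$units$dx) < 0.1
  expect_lt(mean(resp[, fine]), mean(resp[, !fine]))
})

test_that("the noise model obeys its first two moments", {
  c2 <- c(0.2, 1, 3.7)
  expect_error(noisy_response(c2, 1, -0.1), "kappa")
  expect_equal(noisy_response(c2, 2, 0), c2 / 2)
  set.seed(39)
  n <- 1e5
  kappa <- 0.8; const <- 2.5; c2k <- 1.9
  draws <- replicate(3, {
    P <- noisy_response(rep(c2k, n), const, kappa)
    c(mean(P), var(P))
  })
  cn <- c2k / const
  # mean = normalized response, within 4 SE
  se_mean <- kappa * sqrt(cn / n)
  expect_lt(max(abs(draws[1, ] - cn)), 4 * se_mean)
  # variance = kappa^2 * normalized response, within 4 SE
  se_var <- sqrt(2 / (n - 1)) * kappa^2 * cn
  expect_lt(max(abs(draws[2, ] - kappa^2 * cn)), 4 * se_var)
})

test_that("the opponent decision follows the strict sign rule", {
  pop <- small_population(seed = 40)
  pop <- estimate_norm_constants(pop, n_patterns = 100, seed = 41)
  # all-gray stimulus: every response 0, tied sum decides near (0)
  p <- pop$params; p$density <- 1e-6; p$duration_s <- 3 / p$refresh_rate_hz
  s <- make_dot_pattern(p, seed = 42)
  out <- decide_trial(pop, s, kappa = 0)
  expect_equal(out$D, 0)
  expect_identical(out$decision, 0L)
  expect_equal(unname(out$R_per_pair), rep(0, 16))
})

test_that("noise-free decisions are nearly perfect for coarse correlated stimuli", {
  pop <- small_population(seed = 43)
  pop <- estimate_norm_constants(pop, n_patterns = 120, seed = 44)
  p <- pop$params
  p$match_level <- 1; p$disparity_deg <- 0.48; p$duration_s <- 0.5
  sim <- simulate(pop, nsim = 150, seed = 45, params = p, kappa = 0)
  expect_gt(mean(sim$correct), 0.95)
  # mirrored disparity: accuracy invariant to sign within MC error
  p$disparity_deg <- -0.48
  sim2 <- simulate(pop, nsim = 150, seed = 46, params = p, kappa = 0)
  expect_lt(abs(mean(sim$correct) - mean(sim2$correct)), 0.1)
})

test_that("accuracy decreases with kappa and calibration hits its target", {
  pop <- small_population(seed = 47)
  pop <- estimate_norm_constants(pop, n_patterns = 120, seed = 48)
  p <- pop$params
  p$match_level <- 1; p$disparity_deg <- 0.03; p$duration_s <- 0.75
  cond <- data.frame(correlation = 1, disparity_deg = 0.03,
                     duration_s = 0.75)
  accs <- vapply(c(0, 3, 30), function(k) {
    run_psychometric(pop, cond, n_trials = 200, kappa = k,
                     seed = 49)$proportion_correct
  }, numeric(1))
  expect_true(all(diff(accs) <= 0))
  set.seed(50)
  kap <- calibrate_kappa(pop, target = 0.85, params = p, n_trials = 250)
  res <- run_psychometric(pop, cond, n_trials = 500, kappa = as.numeric(kap),
                          seed = 51)
  # re-simulation on a fresh seed reproduces the target within 2 binomial SE
  expect_lt(abs(res$proportion_correct - 0.85),
            2 * sqrt(0.85 * 0.15 / 500))
  # a target above the noise-free ceiling is rejected with diagnostics
  p$match_level <- 0.5
  expect_error(calibrate_kappa(pop, target = 0.995, params = p,
                               n_trials = 100), "unreachable|bracketed")
})
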