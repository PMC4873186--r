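test_that("an all-gray stimulus drives no response", {
  p <- small_params(density = 1e-6)
  s <- make_dot_pattern(p, seed = 20)
  u <- small_unit()
  expect_equal(monocular_response(u, s, "left")$V, 0)
  tr <- complex_response(u, s)
  expect_equal(tr$C, 0)
  expect_equal(tr$C2, 0)
})

test_that("monocular drive is linear in luminance", {
  p <- small_params(match_level = 0.5, disparity_deg = 0.06)
  s <- make_dot_pattern(p, seed = 21)
  u <- small_unit()
  v <- monocular_response(u, s, "left")$V
  s_inv <- s
  s_inv$left <- -s_inv$left
  expect_equal(monocular_response(u, s_inv, "left")$V, -v)
  # the untouched eye is unchanged
  expect_equal(monocular_response(u, s_inv, "right")$V,
               monocular_response(u, s, "right")$V)
})

test_that("simple cell response obeys the binocular square identity", {
  set.seed(22)
  vl <- rnorm(50); vr <- rnorm(50)
  S <- simple_response(vl, vr)
  expect_equal(S - (vl^2 + vr^2 + 2 * vl * vr), rep(0, 50))
  # negating one eye flips only the cross term
  expect_equal(simple_response(vl, -vr), vl^2 + vr^2 - 2 * vl * vr)
  expect_true(all(S >= 0))
})

test_that("complex response is invariant to grating phase", {
  # with few-cycle Gabors (f * sigma = 0.3125) the quadrature pair has
  # slightly unequal norms (the exp(-(2 pi f sigma)^2) term), so phase
  # invariance holds only to ~1e-3; a many-cycle unit is exact to
  # numerical precision
  p <- small_params()
  phases <- seq(0, 2 * pi, length.out = 17)[-17]
  u1 <- bem_unit(dx = 0, sigma = 0.1, f = 3.125)
  C1 <- vapply(phases, function(ph) {
    complex_response(u1, grating_frames(p, 3.125, ph))$C
  }, numeric(1))
  expect_lt(sd(C1) / mean(C1), 1e-3)
  u2 <- bem_unit(dx = 0, sigma = 0.1, f = 10)
  C2 <- vapply(phases, function(ph) {
    complex_response(u2, grating_frames(p, 10, ph))$C
  }, numeric(1))
  expect_lt(sd(C2) / mean(C2), 1e-6)
})

test_that("engine and reference response paths agree", {
  # the C++ separable-patch engine against the plain-R full-field path
  p <- small_params(match_level = 0.5, disparity_deg = 0.06)
  u <- small_unit(dx = 0.06)
  bank <- stereobem:::build_filter_bank(list(u), p)
  set.seed(23)
  dots <- stereobem:::gen_dots(p, 3L)
  M <- stereobem:::frame_responses(bank, p, dots)
  im <- stereobem:::render_frames(p, dots)
  for (f in 1:3) {
    s1 <- stereobem:::new_stereo_frames(im$left[, , f, drop = FALSE],
                                        im$right[, , f, drop = FALSE], 0, p)
    tr <- complex_response(u, s1)
    expect_equal(stereobem:::frames_to_C(M)[f, 1], tr$C, tolerance = 1e-4)
  }
})

test_that("zero-order-hold convolution matrix reproduces direct convolution", {
  tk <- temporal_kernel()
  k <- sample_kernel(tk)
  sch <- stereobem:::frame_schedule(21.25, 0.4)
  H <- stereobem:::build_hold_matrix(k, sch$onsets, 0.4)
  set.seed(24)
  v_frame <- rnorm(sch$n_frames)
  via_H <- as.numeric(H %*% v_frame)
  # direct path: expand to the 1 ms grid and convolve
  idx <- findInterval((1:400) * 1e-3 - 5e-4, sch$onsets)
  s <- v_frame[pmax(idx, 1)]
  direct <- utils::head(stats::convolve(s, rev(as.numeric(k)),
                                        type = "open"), 400)
  expect_equal(via_H, direct, tolerance = 1e-10)
})

test_that("temporal units respond causally", {
  p <- small_params(refresh_rate_hz = 20, duration_s = 0.3)
  u <- small_unit(kernel = temporal_kernel())
  set.seed(25)
  s <- make_dynamic_rds(p)
  tr1 <- complex_response(u, s)
  # appending frames after the response window leaves the response alone
  p2 <- p; p2$duration_s <- 0.5
  set.seed(25)
  s2 <- make_dynamic_rds(p2)
  expect_equal(dim(s2$left)[3] > dim(s$left)[3], TRUE)
  tr2 <- complex_response(u, s2)
  expect_equal(tr2$C[1:300], tr1$C)
})

test_that("sample moments obey E[X^2] = E[X]^2 + Var[X]", {
  p <- small_params(match_level = 0.5, disparity_deg = 0.06)
  u <- small_unit(dx = 0.06)
  set.seed(26)
  res <- stereobem:::engine_static(list(u), p, 300)
  C <- res$C[, 1]
  var_b <- mean(C^2) - mean(C)^2  # biased form
  expect_equal(mean(C^2), mean(C)^2 + var_b)
})

test_that("tuning curves show the squaring signature", {
  p <- small_params()
  u <- small_unit(dx = 0.1, sigma = 0.08)
  tc <- tuning_curve(u, p, disparities = seq(-0.2, 0.2, length.out = 9),
                     n_patterns = 600, seed = 27)
  # linear model: amplitude ratio ~ 1; squared model: < 1
  expect_equal(amplitude_ratio(tc, "linear"), 1, tolerance = 0.2)
  expect_lt(amplitude_ratio(tc, "squared"), 0.85)
  # squared model: half-matched curve peaks at the preferred disparity
  hm <- tc[tc$class == "half_matched", ]
  expect_equal(hm$disparity[which.max(hm$mean_C2)], 0.1)
  # uncorrelated stimuli: flat within Monte-Carlo error
  un <- tc[tc$class == "uncorrelated", ]
  dev <- abs(un$mean_C2 - mean(un$mean_C2)) / un$sem_C2
  expect_lt(max(dev), 4.5)
  # linear model blind to half-matching: flat C curve
  devl <- abs(hm$mean_C - mean(hm$mean_C)) / hm$sem_C
  expect_lt(max(devl), 4.5)
})

test_that("normalized response hits its anchor points", {
  expect_equal(normalized_response(5, uncorr = 5, corr = 9), 0)
  expect_equal(normalized_response(9, uncorr = 5, corr = 9), 1)
  expect_error(normalized_response(5, uncorr = 9, corr = 9), "degenerate")
  p <- small_params()
  u <- small_unit(dx = 0.1, sigma = 0.08)
  tc <- tuning_curve(u, p, disparities = 0.1,
                     classes = c("correlated", "half_matched", "uncorrelated"),
                     n_patterns = 300, seed = 28)
  r <- normalized_response(tc)
  expect_true(is.finite(r) && r > 0 && r < 1)
  expect_gt(attr(r, "se"), 0)
})

test_that("receptive fields must fit inside the image", {
  p <- small_params()
  u <- bem_unit(x0 = 1.5, sigma = 0.3)
  s <- make_dot_pattern(p, seed = 29)
  expect_error(monocular_response(u, s, "left"), "border")
  expect_error(stereobem:::build_filter_bank(list(u), p), "border")
})
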