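test_that("Gabor evaluates to 1 at its centre and is even-symmetric", {
  gp <- gabor_params(x0 = 0.1, y0 = -0.05, dx = 0, sigma_x = 0.1, phi = 0)
  expect_equal(gabor_rf(gp, 0.1, -0.05)[1, 1], 1)
  d <- c(0.02, 0.07, 0.13)
  left <- gabor_rf(gp, 0.1 - d, -0.05)
  right <- gabor_rf(gp, 0.1 + d, -0.05)
  expect_equal(left, right)
})

test_that("disparity offsets shift envelope and carrier together", {
  gpL <- gabor_params(dx = 0.06, eye_sign = 1, sigma_x = 0.1, phi = 0)
  gpR <- gabor_params(dx = 0.06, eye_sign = -1, sigma_x = 0.1, phi = 0)
  x <- seq(-0.5, 0.5, by = 0.01)
  wL <- gabor_rf(gpL, x, 0)
  wR <- gabor_rf(gpR, x - 0.06, 0)  # sampling dx leftward recovers the left RF
  expect_equal(wL, wR)
})

test_that("quadrature Gabors are numerically orthogonal", {
  # discrete inner product of the phase-0 and phase-pi/2 Gabors, at the
  # stimulus resolution and at 10x finer sampling
  for (step in c(0.03, 0.003)) {
    x <- seq(-0.6, 0.6, by = step)
    g0 <- gabor_rf(gabor_params(sigma_x = 0.1, f = 3.125, phi = 0), x, x)
    g90 <- gabor_rf(gabor_params(sigma_x = 0.1, f = 3.125, phi = pi / 2),
                    x, x)
    ip <- sum(g0 * g90)
    expect_lt(abs(ip), 1e-3 * sqrt(sum(g0^2) * sum(g90^2)))
  }
})

test_that("a too-coarse grid triggers the sampling warning", {
  gp <- gabor_params(sigma_x = 0.02, f = 20)
  expect_warning(gabor_rf(gp, seq(-0.2, 0.2, by = 0.03), 0, 0.03), "coarse")
})

test_that("temporal kernel is causal and validates its parameters", {
  tk <- temporal_kernel()
  expect_equal(kernel_value(tk, c(-0.01, -1)), c(0, 0))
  expect_error(temporal_kernel(alpha = 0), "alpha")
  expect_error(temporal_kernel(tau = -1), "tau")
  k <- sample_kernel(tk)
  # truncated where the gamma envelope is < 1e-6 of its peak
  t <- (seq_along(k) - 1) * 1e-3
  env <- t^1.5 * exp(-t / tk$tau)
  expect_gte(env[length(k)] / max(env), 0.5e-6)
  expect_lt(env[length(k)] / max(env), 2e-6)
})

test_that("the on-phase of the default biphasic kernel lasts 125 ms", {
  tk <- temporal_kernel()  # omega = 8 pi, phase = -pi
  lobe <- kernel_on_phase_ms(tk)
  expect_equal(as.numeric(lobe), 125)
  expect_equal(attr(lobe, "crossings_s"), c(0.0625, 0.1875))
  # the kernel is positive strictly inside the lobe
  expect_gt(kernel_value(tk, 0.125), 0)
  expect_lt(kernel_value(tk, 0.05), 0)
})

test_that("spectral peak matches an independent FFT oracle and rescales", {
  tk <- temporal_kernel()
  pk <- kernel_peak_frequency(tk)
  # oracle: direct spectrum of the closed-form kernel at a different
  # sampling and padding
  dt <- 5e-4
  t <- seq(0, 2, by = dt)
  kv <- t^1.5 * exp(-t / 0.035) * cos(8 * pi * t - pi)
  n <- 2^22
  amp <- Mod(stats::fft(c(kv, numeric(n - length(kv)))))
  freq <- (seq_len(n %/% 2) - 1) / (n * dt)
  expect_equal(pk, freq[which.max(amp[seq_len(n %/% 2)])], tolerance = 2e-3)
  # time rescaling by s scales the peak frequency by 1/s
  tk2 <- temporal_kernel(omega = 4 * pi, tau = 0.07)
  expect_equal(kernel_peak_frequency(tk2), pk / 2, tolerance = 2e-2)
  # low-pass kind peaks at 0 Hz
  expect_equal(kernel_peak_frequency(temporal_kernel(kind = "lowpass")), 0)
})
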