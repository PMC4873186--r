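#' Spatial Gabor receptive field parameters
#'
#' Vertically oriented 2-D Gabor: a Gaussian envelope times a cosine
#' carrier.  Disparity selectivity is positional: the whole Gabor (envelope
#' and carrier together) is offset by +dx/2 in the left eye and -dx/2 in
#' the right eye.  No phase disparity is used anywhere in the package.
#'
#' @param x0,y0 Receptive-field center, degrees.
#' @param dx Preferred disparity, degrees.
#' @param sigma_x,sigma_y Envelope standard deviations, degrees (equal in
#'   all standard configurations).
#' @param f Spatial frequency, cycles/degree.
#' @param phi Carrier phase, radians.
#' @param eye_sign +1 selects the left-eye (+dx/2) offset, -1 the right.
#' @return An object of class `gabor_params`.
#' @export
gabor_params <- function(x0 = 0, y0 = 0, dx = 0, sigma_x = 0.1,
                         sigma_y = sigma_x, f = 0.3125 / sigma_x,
                         phi = 0, eye_sign = 1) {
  stopifnot(sigma_x > 0, sigma_y > 0, f > 0, eye_sign %in% c(-1, 1))
  structure(list(x0 = x0, y0 = y0, dx = dx, sigma_x = sigma_x,
                 sigma_y = sigma_y, f = f, phi = phi, eye_sign = eye_sign),
            class = "gabor_params")
}

#' Evaluate a Gabor receptive field on a grid
#'
#' @param gp A [gabor_params()] object.
#' @param x,y Numeric vectors of x (horizontal) and y (vertical) sample
#'   positions in degrees; the weights are returned as a
#'   `length(y)` by `length(x)` matrix.
#' @param deg_per_px If the grid spacing undersamples the carrier (fewer
#'   than 2 samples per period) a warning is issued.
#' @return Matrix of RF weights.
#' @export
gabor_rf <- function(gp, x, y,
                     deg_per_px = if (length(x) > 1) abs(diff(x[1:2])) else NULL) {
  stopifnot(inherits(gp, "gabor_params"))
  xc <- gp$x0 + gp$eye_sign * gp$dx / 2
  if (!is.null(deg_per_px) && deg_per_px > 0 &&
      gp$f > 1 / (2 * deg_per_px))
    warning("grid too coarse to sample the carrier: f = ", signif(gp$f, 4),
            " c/deg needs spacing < ", signif(1 / (2 * gp$f), 4), " deg")
  gx <- exp(-(x - xc)^2 / (2 * gp$sigma_x^2)) *
    cos(2 * pi * gp$f * (x - xc) + gp$phi)
  gy <- exp(-(y - gp$y0)^2 / (2 * gp$sigma_y^2))
  outer(gy, gx)
}

#' Biphasic (or low-pass) temporal kernel parameters
#'
#' The band-pass kernel is a gamma-density envelope times a cosine:
#' `t^(alpha-1) exp(-t/tau) cos(omega t + phase) / (gamma(alpha) tau^alpha)`
#' for `t >= 0` and 0 otherwise.  With the defaults (alpha = 2.5,
#' omega = 4 * 2 * pi rad/s, phase = -pi, tau = 0.035 s) the kernel is
#' biphasic with an on-phase (positive lobe of the cosine factor) lasting
#' 125 ms.  `kind = "lowpass"` drops the cosine factor, giving a
#' non-oscillatory gamma envelope with the same time constants (a stand-in
#' for sustained, low-pass temporal integration; no equivalence with any
#' specific published kernel is claimed).
#'
#' @param alpha Gamma shape (> 0).
#' @param omega Carrier angular frequency, rad/s.
#' @param phase Carrier phase, radians.
#' @param tau Time constant, seconds (> 0).
#' @param kind `"biphasic"` or `"lowpass"`.
#' @return An object of class `temporal_kernel`.
#' @examples
#' k <- temporal_kernel()
#' kernel_peak_frequency(k)
#' @export
temporal_kernel <- function(alpha = 2.5, omega = 4 * 2 * pi, phase = -pi,
                            tau = 0.035, kind = c("biphasic", "lowpass")) {
  kind <- match.arg(kind)
  if (alpha <= 0) stop("'alpha' must be > 0")
  if (tau <= 0) stop("'tau' must be > 0")
  structure(list(alpha = alpha, omega = omega, phase = phase, tau = tau,
                 kind = kind),
            class = "temporal_kernel")
}

#' @export
print.temporal_kernel <- function(x, ...) {
  cat(sprintf("%s temporal kernel: alpha = %.3g, omega = %.4g rad/s, phase = %.4g, tau = %.3g s\n",
              x$kind, x$alpha, x$omega, x$phase, x$tau))
  if (x$kind == "biphasic")
    cat(sprintf("  on-phase %.4g ms, spectral peak %.3g Hz\n",
                kernel_on_phase_ms(x), kernel_peak_frequency(x)))
  invisible(x)
}

## Envelope-based truncation length in samples (envelope < tol * peak).
kernel_truncation_length <- function(tk, dt = 1e-3, tol = 1e-6) {
  t <- dt * (0:200000)
  env <- t^(tk$alpha - 1) * exp(-t / tk$tau)
  keep <- which(env >= tol * max(env))
  max(keep)
}

#' Sample a temporal kernel on the simulation grid
#'
#' The kernel is identically 0 for `t < 0` (causal); samples are taken at
#' `t = 0, dt, 2 dt, ...` and truncated where the gamma envelope falls
#' below `tol` of its peak.
#'
#' @param tk A [temporal_kernel()] object.
#' @param dt Grid step in seconds (default 1 ms).
#' @param tol Envelope truncation tolerance relative to the envelope peak.
#' @return Numeric vector of kernel weights; the truncation length is
#'   attached as attribute `"t_max_s"`.
#' @export
sample_kernel <- function(tk, dt = 1e-3, tol = 1e-6) {
  stopifnot(inherits(tk, "temporal_kernel"))
  L <- kernel_truncation_length(tk, dt, tol)
  t <- dt * (0:(L - 1))
  k <- kernel_value(tk, t)
  attr(k, "t_max_s") <- L * dt
  k
}

#' Evaluate a temporal kernel at arbitrary times
#'
#' @param tk A [temporal_kernel()] object.
#' @param t Times in seconds (negative times give 0).
#' @return Numeric vector of kernel values.
#' @export
kernel_value <- function(tk, t) {
  v <- numeric(length(t))
  pos <- t >= 0
  tp <- t[pos]
  env <- tp^(tk$alpha - 1) * exp(-tp / tk$tau) /
    (gamma(tk$alpha) * tk$tau^tk$alpha)
  v[pos] <- if (tk$kind == "biphasic")
    env * cos(tk$omega * tp + tk$phase) else env
  v
}

#' Frequency of maximal spectral amplitude of a temporal kernel
#'
#' Computes the discrete amplitude spectrum of the sampled kernel with fine
#' zero-padding and returns the argmax frequency in Hz.  The low-pass kind
#' peaks at 0 Hz.
#'
#' @inheritParams sample_kernel
#' @param pad_to FFT length after zero-padding (power of two).
#' @return Peak frequency in Hz.
#' @export
kernel_peak_frequency <- function(tk, dt = 1e-3, pad_to = 2^20) {
  k <- sample_kernel(tk, dt)
  n <- max(pad_to, 2^ceiling(log2(length(k))))
  amp <- Mod(stats::fft(c(k, numeric(n - length(k)))))
  half <- seq_len(n %/% 2)
  freq <- (half - 1) / (n * dt)
  freq[which.max(amp[half])]
}

#' Duration of the on-phase (positive lobe) of the biphasic kernel
#'
#' The cosine factor `cos(omega t + phase)` is positive on an interval
#' bracketed by two zero crossings; this returns that interval's length in
#' milliseconds (the first positive lobe after t = 0).  For the defaults
#' (omega = 8 pi, phase = -pi) the lobe runs from 62.5 ms to 187.5 ms,
#' i.e. 125 ms.
#'
#' @param tk A [temporal_kernel()] object (`kind = "biphasic"`).
#' @return On-phase duration in ms; the bracketing zero crossings (s) are
#'   attached as attribute `"crossings_s"`.
#' @export
kernel_on_phase_ms <- function(tk) {
  stopifnot(inherits(tk, "temporal_kernel"))
  if (tk$kind != "biphasic") stop("on-phase is defined for biphasic kernels")
  ## zero crossings: omega t + phase = pi/2 + k pi  =>  t_k
  k <- -10:10
  tz <- sort((pi / 2 + k * pi - tk$phase) / tk$omega)
  tz <- tz[tz > 1e-12]
  ## find the first crossing pair bracketing a positive cosine interval
  for (i in seq_len(length(tz) - 1)) {
    mid <- (tz[i] + tz[i + 1]) / 2
    if (cos(tk$omega * mid + tk$phase) > 0) {
      out <- (tz[i + 1] - tz[i]) * 1000
      attr(out, "crossings_s") <- c(tz[i], tz[i + 1])
      return(out)
    }
  }
  stop("no positive lobe found")
}

#' Inter-frame interval of a dot-pattern refresh rate
#'
#' @param refresh_rate_hz Refresh rate in Hz.
#' @return Interval in milliseconds (e.g. 47.06 ms at 21.25 Hz, 8.33 ms at
#'   120 Hz).
#' @export
frame_interval_ms <- function(refresh_rate_hz) {
  stopifnot(refresh_rate_hz > 0)
  1000 / refresh_rate_hz
}
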