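#' Binocular energy model unit
#'
#' A model complex cell: two binocular simple cells built from quadrature
#' Gabor subunits (carrier phases `phi` and `phi + pi/2`), each simple cell
#' summing a left- and a right-eye monocular drive and squaring.  The
#' complex response is `C = S1 + S2`; with `exponent = 2` the final output
#' is `C^2` (the squaring output nonlinearity), with `exponent = 1` the
#' binocularly linear energy response `C` itself.
#'
#' Disparity selectivity is purely positional: the left-eye receptive
#' fields are centred at `x0 + dx/2`, the right-eye fields at `x0 - dx/2`,
#' with identical phases in the two eyes.
#'
#' @param x0,y0 Receptive-field centre, degrees.
#' @param dx Preferred disparity, degrees.
#' @param sigma Envelope SD, degrees (isotropic).
#' @param f Carrier spatial frequency, cycles/degree; defaults to the
#'   physiological scaling `0.3125 / sigma`.
#' @param phi Carrier phase of the first subunit, radians.
#' @param exponent Output exponent: 2 (squared) or 1 (linear).
#' @param kernel A [temporal_kernel()] or `NULL` for a static
#'   (space-only) unit.
#' @return An object of class `bem_unit`.
#' @examples
#' u <- bem_unit(dx = 0.1, sigma = 0.1)
#' u
#' @export
bem_unit <- function(x0 = 0, y0 = 0, dx = 0, sigma = 0.1,
                     f = 0.3125 / sigma, phi = 0, exponent = 2,
                     kernel = NULL) {
  stopifnot(sigma > 0, f > 0, exponent %in% c(1, 2))
  if (!is.null(kernel)) stopifnot(inherits(kernel, "temporal_kernel"))
  sub <- function(p, eye) gabor_params(x0, y0, dx, sigma, sigma, f, p, eye)
  structure(list(x0 = x0, y0 = y0, dx = dx, sigma = sigma, f = f,
                 phi = phi, exponent = exponent, kernel = kernel,
                 subunits = list(s1L = sub(phi, 1), s1R = sub(phi, -1),
                                 s2L = sub(phi + pi / 2, 1),
                                 s2R = sub(phi + pi / 2, -1))),
            class = "bem_unit")
}

#' @export
print.bem_unit <- function(x, ...) {
  cat(sprintf("BEM unit: dx = %+.3f deg, sigma = %.4f deg, f = %.3f c/deg, phi = %.2f, exponent = %d, %s\n",
              x$dx, x$sigma, x$f, x$phi, x$exponent,
              if (is.null(x$kernel)) "static" else x$kernel$kind))
  invisible(x)
}

## Degree coordinates of the pixel grid (centres), centred on fixation.
pixel_axis <- function(params) {
  (seq_len(params$field_size_px) - (params$field_size_px + 1) / 2) *
    params$deg_per_px
}

#' Monocular drive of one subunit
#'
#' Reference (pure R) response path on materialized frame stacks.  The
#' spatial response is the inner product of the sampled Gabor with each
#' frame; with a temporal kernel the frame responses are expanded to the
#' 1 ms grid by zero-order hold and convolved causally with the kernel.
#'
#' @param unit A [bem_unit()].
#' @param seq A `stereo_frames` object.
#' @param eye `"left"` or `"right"`.
#' @param subunit 1 or 2 (quadrature pair).
#' @param dt Simulation step for temporal units, seconds.
#' @return List with `times` (s) and `V` (drive); for static units one
#'   value per frame, for temporal units one per `dt`.
#' @export
monocular_response <- function(unit, seq, eye = c("left", "right"),
                               subunit = 1, dt = 1e-3) {
  eye <- match.arg(eye)
  stopifnot(inherits(unit, "bem_unit"), inherits(seq, "stereo_frames"))
  gp <- unit$subunits[[paste0("s", subunit, if (eye == "left") "L" else "R")]]
  params <- seq$params
  ax <- pixel_axis(params)
  xc <- gp$x0 + gp$eye_sign * gp$dx / 2
  half <- max(abs(ax))
  if (abs(xc) + 4 * gp$sigma_x > half || abs(gp$y0) + 4 * gp$sigma_y > half)
    stop("receptive field extends beyond the image border (needs +-4 sigma inside)")
  rf <- gabor_rf(gp, ax, ax, params$deg_per_px)
  nf <- dim(seq$left)[3]
  img <- seq[[eye]]
  v_frame <- vapply(seq_len(nf), function(f) sum(rf * img[, , f]), numeric(1))
  if (is.null(unit$kernel))
    return(list(times = seq$frame_times, V = v_frame))
  n_t <- round(params$duration_s / dt)
  t_grid <- (seq_len(n_t)) * dt
  idx <- findInterval(t_grid - dt / 2, seq$frame_times)
  s <- v_frame[pmax(idx, 1L)]
  k <- sample_kernel(unit$kernel, dt)
  V <- utils::head(stats::convolve(s, rev(as.numeric(k)), type = "open"), n_t)
  list(times = t_grid, V = V)
}

#' Binocular simple-cell response
#'
#' `S = (V_L + V_R)^2 = V_L^2 + V_R^2 + 2 V_L V_R`; the cross term carries
#' the disparity selectivity.
#'
#' @param V_L,V_R Aligned monocular drive traces.
#' @return Pointwise squared sum.
#' @export
simple_response <- function(V_L, V_R) {
  stopifnot(length(V_L) == length(V_R))
  (V_L + V_R)^2
}

#' Complex-cell response trace
#'
#' Combines the two quadrature simple cells: `C = S1 + S2`, plus the
#' squared output `C2 = C^2`.
#'
#' @param unit A [bem_unit()].
#' @param seq A `stereo_frames` object.
#' @param dt Simulation step for temporal units, seconds.
#' @return An object of class `bem_trace` with `times`, the four monocular
#'   drives, `S1`, `S2`, `C` and `C2`.
#' @export
complex_response <- function(unit, seq, dt = 1e-3) {
  v1L <- monocular_response(unit, seq, "left", 1, dt)
  v1R <- monocular_response(unit, seq, "right", 1, dt)
  v2L <- monocular_response(unit, seq, "left", 2, dt)
  v2R <- monocular_response(unit, seq, "right", 2, dt)
  S1 <- simple_response(v1L$V, v1R$V)
  S2 <- simple_response(v2L$V, v2R$V)
  C <- S1 + S2
  structure(list(times = v1L$times, V1L = v1L$V, V1R = v1R$V,
                 V2L = v2L$V, V2R = v2R$V, S1 = S1, S2 = S2,
                 C = C, C2 = C^2, unit = unit),
            class = "bem_trace")
}

#' @export
print.bem_trace <- function(x, ...) {
  cat(sprintf("BEM response trace: %d time point(s); mean C = %.4g, mean C^2 = %.4g\n",
              length(x$times), mean(x$C), mean(x$C2)))
  invisible(x)
}

#' @export
plot.bem_trace <- function(x, ...) {
  graphics::plot(x$times, x$C, type = "l", xlab = "time (s)",
                 ylab = "C", main = "complex response", ...)
  invisible(x)
}

#' @rdname complex_response
#' @param object A [bem_unit()].
#' @param stimulus A `stereo_frames` object.
#' @param ... Passed on (e.g. `dt`).
#' @export
predict.bem_unit <- function(object, stimulus, ...) {
  complex_response(object, stimulus, ...)
}

stimulus_classes <- c("correlated", "half_matched", "anticorrelated",
                      "uncorrelated")

class_match_level <- function(class) {
  switch(class, correlated = 1, half_matched = 0.5, anticorrelated = 0,
         uncorrelated = NA_real_,
         stop("unknown stimulus class: ", class))
}

#' Monte-Carlo disparity tuning of a BEM unit
#'
#' Mean response (both `C` and `C^2`) per disparity per stimulus class,
#' over independently drawn random-dot patterns.  Static units see one
#' fresh pattern per draw; temporal units see a dynamic stereogram of the
#' stimulus duration and the response is the time-averaged trace.
#'
#' @param unit A [bem_unit()].
#' @param params Stimulus parameters ([stim_params()]); disparity and match
#'   level are overridden per curve point.
#' @param disparities Disparities to probe, degrees.
#' @param classes Subset of `correlated`, `half_matched`, `anticorrelated`,
#'   `uncorrelated`.
#' @param n_patterns Patterns (or trials, for temporal units) per point.
#' @param seed Optional integer seed.
#' @return A `bem_tuning` data frame with columns `disparity`, `class`,
#'   `mean_C`, `sem_C`, `mean_C2`, `sem_C2`, `n`.
#' @export
tuning_curve <- function(unit, params = stim_params(),
                         disparities = seq(-0.4, 0.4, length.out = 21),
                         classes = stimulus_classes,
                         n_patterns = 1000, seed = NULL) {
  stopifnot(inherits(unit, "bem_unit"), n_patterns >= 1)
  classes <- match.arg(classes, stimulus_classes, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (c_i in classes) {
    for (d in disparities) {
      p <- params
      p$disparity_deg <- d
      unc <- identical(c_i, "uncorrelated")
      if (!unc) p$match_level <- class_match_level(c_i)
      if (is.null(unit$kernel)) {
        res <- engine_static(list(unit), p, n_patterns, uncorrelated = unc)
        Cv <- res$C[, 1]; C2v <- Cv^2
      } else {
        res <- engine_temporal(list(unit), p, unit$kernel, n_patterns,
                               uncorrelated = unc)
        Cv <- res$sumC[, 1] / res$n_t
        C2v <- res$sumC2[, 1] / res$n_t
      }
      rows[[length(rows) + 1L]] <-
        data.frame(disparity = d, class = c_i,
                   mean_C = mean(Cv), sem_C = stats::sd(Cv) / sqrt(n_patterns),
                   mean_C2 = mean(C2v),
                   sem_C2 = stats::sd(C2v) / sqrt(n_patterns),
                   n = n_patterns)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "unit") <- unit
  class(out) <- c("bem_tuning", "data.frame")
  out
}

#' @export
print.bem_tuning <- function(x, ...) {
  u <- attr(x, "unit")
  cat(sprintf("BEM disparity tuning: %d disparities x %d class(es), n = %d per point\n",
              length(unique(x$disparity)), length(unique(x$class)), x$n[1]))
  if (!is.null(u)) print(u)
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("  ...", nrow(x) - 8, "more rows\n")
  invisible(x)
}

#' @export
plot.bem_tuning <- function(x, response = c("C2", "C"), ...) {
  response <- match.arg(response)
  col_mean <- paste0("mean_", response)
  cls <- unique(x$class)
  cols <- stats::setNames(seq_along(cls) + 1, cls)
  graphics::plot(range(x$disparity), range(x[[col_mean]]), type = "n",
                 xlab = "disparity (deg)",
                 ylab = sprintf("mean %s", response), ...)
  for (c_i in cls) {
    s <- x[x$class == c_i, ]
    graphics::lines(s$disparity, s[[col_mean]], col = cols[[c_i]], lwd = 2)
  }
  graphics::legend("topright", legend = cls, col = cols, lwd = 2, bty = "n")
  invisible(x)
}

#' Normalized half-matched response
#'
#' `R_norm = (<R_hm> - <R_uncorr>) / (<R_corr> - <R_uncorr>)` computed at
#' the unit's preferred disparity: 1 means the half-matched response equals
#' the correlated response, 0 means it equals the uncorrelated response.
#'
#' @param x A `bem_tuning` object containing the three classes, or the mean
#'   half-matched response directly (then give `uncorr` and `corr`).
#' @param ... Method arguments.
#' @return The scalar `R_norm`; for tuning input, attribute `"se"` carries
#'   a delta-method standard error.
#' @export
normalized_response <- function(x, ...) UseMethod("normalized_response")

#' @rdname normalized_response
#' @param uncorr,corr Mean uncorrelated / correlated responses.
#' @export
normalized_response.default <- function(x, uncorr, corr, ...) {
  den <- corr - uncorr
  if (!is.finite(den) || den <= 0)
    stop("degenerate denominator: correlated response must exceed uncorrelated")
  (x - uncorr) / den
}

#' @rdname normalized_response
#' @param model `"squared"` (uses `C^2`) or `"linear"` (uses `C`).
#' @param preferred Preferred disparity; defaults to the unit's `dx`.
#' @export
normalized_response.bem_tuning <- function(x, model = c("squared", "linear"),
                                           preferred = NULL, ...) {
  model <- match.arg(model)
  col_m <- if (model == "squared") "mean_C2" else "mean_C"
  col_s <- if (model == "squared") "sem_C2" else "sem_C"
  u <- attr(x, "unit")
  if (is.null(preferred)) preferred <- if (!is.null(u)) u$dx else 0
  d0 <- unique(x$disparity)[which.min(abs(unique(x$disparity) - preferred))]
  pick <- function(cl) x[x$class == cl & x$disparity == d0, , drop = FALSE]
  hm <- pick("half_matched"); un <- pick("uncorrelated"); co <- pick("correlated")
  if (nrow(hm) != 1 || nrow(un) != 1 || nrow(co) != 1)
    stop("tuning must contain half_matched, uncorrelated and correlated at the preferred disparity")
  den <- co[[col_m]] - un[[col_m]]
  if (den <= 0)
    stop("degenerate denominator: correlated response must exceed uncorrelated")
  r <- (hm[[col_m]] - un[[col_m]]) / den
  ## delta method on the three independent means
  se <- sqrt(hm[[col_s]]^2 / den^2 +
             co[[col_s]]^2 * ((hm[[col_m]] - un[[col_m]]) / den^2)^2 +
             un[[col_s]]^2 * ((1 / den) - (hm[[col_m]] - un[[col_m]]) / den^2)^2)
  attr(r, "se") <- se
  r
}

#' Anticorrelated / correlated amplitude ratio
#'
#' Disparity-modulation amplitude (max minus min of the mean tuning curve)
#' for anticorrelated stimuli divided by that for correlated stimuli.  The
#' binocularly linear model has ratio 1; the squared model has ratio < 1.
#'
#' @param x A `bem_tuning` object with `correlated` and `anticorrelated`.
#' @param model `"squared"` or `"linear"`.
#' @return The amplitude ratio.
#' @export
amplitude_ratio <- function(x, model = c("squared", "linear")) {
  model <- match.arg(model)
  col_m <- if (model == "squared") "mean_C2" else "mean_C"
  amp <- function(cl) {
    v <- x[x$class == cl, col_m]
    if (length(v) < 2) stop("need a tuning curve for class ", cl)
    max(v) - min(v)
  }
  amp("anticorrelated") / amp("correlated")
}
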