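## Fast simulation paths: sparse Gabor filter banks evaluated in C++ on
## procedurally generated dot lists, plus the zero-order-hold / temporal
## convolution machinery.  The pure R reference path lives in bem.R and is
## cross-checked against this engine in the test suite.

## Build the separable filter bank for a list of bem_units on the pixel
## grid: one patch per (unit, eye), holding the shared vertical Gaussian
## profile gy and the two quadrature horizontal profiles gx1/gx2 (envelope
## times carrier at phases phi and phi + pi/2).  Patches extend
## +-patch_sigma envelope SDs around the offset centre (clipped to the
## image); an error is raised if the +-4 sigma core leaves the image.
build_filter_bank <- function(units, params, patch_sigma = 5) {
  n <- params$field_size_px
  ax <- pixel_axis(params)
  half <- (n / 2) * params$deg_per_px
  row0 <- integer(0); nrowv <- integer(0)
  col0 <- integer(0); ncolv <- integer(0); eye <- integer(0)
  gy <- list(); gx1 <- list(); gx2 <- list()
  for (u in units) {
    for (e in c(1, -1)) {
      gp <- u$subunits[[if (e > 0) "s1L" else "s1R"]]
      xc <- gp$x0 + gp$eye_sign * gp$dx / 2
      if (abs(xc) + 4 * gp$sigma_x > half || abs(gp$y0) + 4 * gp$sigma_y > half)
        stop("receptive field extends beyond the image border ",
             sprintf("(centre %.3f, sigma %.3f deg)", xc, gp$sigma_x))
      if (gp$f > 1 / (2 * params$deg_per_px))
        warning("pixel grid undersamples the carrier (f = ",
                signif(gp$f, 4), " c/deg at ", params$deg_per_px, " deg/px)")
      ext <- patch_sigma * gp$sigma_x
      cols <- which(ax >= xc - ext & ax <= xc + ext)
      rows <- which(ax >= gp$y0 - ext & ax <= gp$y0 + ext)
      env_x <- exp(-(ax[cols] - xc)^2 / (2 * gp$sigma_x^2))
      arg <- 2 * pi * gp$f * (ax[cols] - xc)
      row0 <- c(row0, rows[1] - 1L); nrowv <- c(nrowv, length(rows))
      col0 <- c(col0, cols[1] - 1L); ncolv <- c(ncolv, length(cols))
      eye <- c(eye, if (e > 0) 0L else 1L)
      gy[[length(gy) + 1L]] <-
        exp(-(ax[rows] - gp$y0)^2 / (2 * gp$sigma_y^2))
      gx1[[length(gx1) + 1L]] <- env_x * cos(arg + u$phi)
      gx2[[length(gx2) + 1L]] <- env_x * cos(arg + u$phi + pi / 2)
    }
  }
  list(row0 = row0, nrow = nrowv, col0 = col0, ncol = ncolv, eye = eye,
       gy = unlist(gy), gy_ptr = as.integer(c(0L, cumsum(nrowv))),
       gx1 = unlist(gx1), gx2 = unlist(gx2),
       gx_ptr = as.integer(c(0L, cumsum(ncolv))),
       n_units = length(units), n_filt = 4L * length(units))
}

## Per-frame inner products for a dot list; returns n_frames x 4 n_units,
## unit u in columns 4u+1..4u+4 ordered (s1L, s1R, s2L, s2R).
frame_responses <- function(bank, params, dots) {
  .cpp_frame_responses(params$field_size_px, params$field_size_px,
                       dots$lx, dots$ly, dots$lpol,
                       dots$rx, dots$ry, dots$rpol,
                       dots$frame_ptr, dots$r_px,
                       bank$row0, bank$nrow, bank$col0, bank$ncol,
                       bank$eye, bank$gy, bank$gy_ptr,
                       bank$gx1, bank$gx2, bank$gx_ptr)
}

## Evaluate the bank on one materialized left/right image pair (R path,
## used for single-trial inspection on stereo_frames objects).
bank_eval_images <- function(bank, imgL, imgR) {
  np <- length(bank$eye)
  out <- numeric(2L * np)
  for (g in seq_len(np)) {
    img <- if (bank$eye[g] == 0L) imgL else imgR
    rows <- bank$row0[g] + seq_len(bank$nrow[g])
    cols <- bank$col0[g] + seq_len(bank$ncol[g])
    z <- as.numeric(crossprod(bank$gy[bank$gy_ptr[g] + seq_len(bank$nrow[g])],
                              img[rows, cols, drop = FALSE]))
    u <- (g - 1L) %/% 2L; e <- (g - 1L) %% 2L
    gxi <- bank$gx_ptr[g] + seq_len(bank$ncol[g])
    out[4L * u + e + 1L] <- sum(z * bank$gx1[gxi])
    out[4L * u + e + 3L] <- sum(z * bank$gx2[gxi])
  }
  out
}

## Per-frame complex responses C (n_frames x n_units) from the 4-per-unit
## monocular inner products.
frames_to_C <- function(M) {
  nu <- ncol(M) %/% 4L
  i <- (seq_len(nu) - 1L) * 4L
  (M[, i + 1L, drop = FALSE] + M[, i + 2L, drop = FALSE])^2 +
    (M[, i + 3L, drop = FALSE] + M[, i + 4L, drop = FALSE])^2
}

## Static engine: n_patterns independent single frames; returns C
## (n_patterns x n_units).
engine_static <- function(units, params, n_patterns, match_level = NULL,
                          uncorrelated = FALSE, bank = NULL,
                          batch = 256L) {
  if (is.null(bank)) bank <- build_filter_bank(units, params)
  if (!is.null(match_level)) params$match_level <- match_level
  C <- matrix(NA_real_, n_patterns, bank$n_units)
  done <- 0L
  while (done < n_patterns) {
    nb <- min(batch, n_patterns - done)
    dots <- gen_dots(params, nb, uncorrelated = uncorrelated)
    M <- frame_responses(bank, params, dots)
    C[done + seq_len(nb), ] <- frames_to_C(M)
    done <- done + nb
  }
  list(C = C)
}

## Class-coupled static engine: per pattern, correlated / half-matched /
## uncorrelated variants share dot layouts (common random numbers), giving
## low-variance class contrasts.  Returns per-pattern C per class.
engine_static_classes <- function(units, params, n_patterns, bank = NULL,
                                  batch = 128L) {
  if (is.null(bank)) bank <- build_filter_bank(units, params)
  out <- lapply(1:3, function(i) matrix(NA_real_, n_patterns, bank$n_units))
  done <- 0L
  while (done < n_patterns) {
    nb <- min(batch, n_patterns - done)
    dots <- gen_dots_classes(params, nb)
    C <- frames_to_C(frame_responses(bank, params, dots))
    for (i in 1:3)
      out[[i]][done + seq_len(nb), ] <- C[seq(i, 3L * nb, by = 3L), ,
                                          drop = FALSE]
    done <- done + nb
  }
  names(out) <- c("corr", "hm", "unc")
  out
}

## Class-coupled temporal engine: per trial the three class variants share
## frame layouts.  Returns per-trial time-averaged C^2 (and C) per class.
engine_temporal_classes <- function(units, params, kernel, n_trials,
                                    bank = NULL, dt = 1e-3) {
  if (is.null(bank)) bank <- build_filter_bank(units, params)
  sch <- frame_schedule(params$refresh_rate_hz, params$duration_s)
  k <- sample_kernel(kernel, dt)
  H <- build_hold_matrix(k, sch$onsets, params$duration_s, dt)
  n_t <- nrow(H)
  nu <- bank$n_units
  i4 <- (seq_len(nu) - 1L) * 4L
  out <- lapply(1:3, function(i) matrix(NA_real_, n_trials, nu))
  for (tr in seq_len(n_trials)) {
    dots <- gen_dots_classes(params, sch$n_frames)
    M <- frame_responses(bank, params, dots)
    for (i in 1:3) {
      Mi <- M[seq(i, 3L * sch$n_frames, by = 3L), , drop = FALSE]
      U1 <- H %*% (Mi[, i4 + 1L, drop = FALSE] + Mi[, i4 + 2L, drop = FALSE])
      U2 <- H %*% (Mi[, i4 + 3L, drop = FALSE] + Mi[, i4 + 4L, drop = FALSE])
      C <- U1 * U1 + U2 * U2
      out[[i]][tr, ] <- colSums(C * C) / n_t
    }
  }
  names(out) <- c("corr", "hm", "unc")
  out
}

## Zero-order-hold convolution matrix H (n_t x n_frames): H[i, f] is the
## summed kernel weight applied to frame f at output time i (ms grid).
build_hold_matrix <- function(k, onsets_s, duration_s, dt = 1e-3) {
  n_t <- round(duration_s / dt)
  L <- length(k)
  kc <- c(0, cumsum(as.numeric(k)))     # kc[m + 1] = sum(k[1:m])
  nf <- length(onsets_s)
  ## frame f occupies ms samples a_f .. b_f (1-based, grid t_i = i * dt)
  a <- floor(onsets_s / dt) + 1L
  b <- c(a[-1L] - 1L, n_t)
  H <- matrix(0, n_t, nf)
  i <- seq_len(n_t)
  for (f in seq_len(nf)) {
    hi <- pmin(pmax(i - a[f] + 1L, 0L), L)
    lo <- pmin(pmax(i - b[f], 0L), L)
    H[, f] <- kc[hi + 1L] - kc[lo + 1L]
  }
  H
}

## Temporal engine: n_trials dynamic stereograms; per-trial, per-unit
## time-summed C and C^2 on the 1 ms grid (summed over the stimulus
## duration).  match_fun(n_frames), if given, returns the per-frame match
## levels of one trial (alternating stimuli, randomized start phase).
engine_temporal <- function(units, params, kernel, n_trials,
                            match_fun = NULL, uncorrelated = FALSE,
                            bank = NULL, dt = 1e-3) {
  if (is.null(bank)) bank <- build_filter_bank(units, params)
  sch <- frame_schedule(params$refresh_rate_hz, params$duration_s)
  k <- sample_kernel(kernel, dt)
  H <- build_hold_matrix(k, sch$onsets, params$duration_s, dt)
  n_t <- nrow(H)
  nu <- bank$n_units
  i4 <- (seq_len(nu) - 1L) * 4L
  sumC <- matrix(NA_real_, n_trials, nu)
  sumC2 <- matrix(NA_real_, n_trials, nu)
  for (tr in seq_len(n_trials)) {
    ml <- if (is.null(match_fun)) params$match_level else match_fun(sch$n_frames)
    dots <- gen_dots(params, sch$n_frames, match_level = ml,
                     uncorrelated = uncorrelated)
    M <- frame_responses(bank, params, dots)
    U1 <- H %*% (M[, i4 + 1L, drop = FALSE] + M[, i4 + 2L, drop = FALSE])
    U2 <- H %*% (M[, i4 + 3L, drop = FALSE] + M[, i4 + 4L, drop = FALSE])
    C <- U1 * U1 + U2 * U2
    sumC[tr, ] <- colSums(C)
    sumC2[tr, ] <- colSums(C * C)
  }
  list(sumC = sumC, sumC2 = sumC2, n_t = n_t, n_frames = sch$n_frames)
}
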