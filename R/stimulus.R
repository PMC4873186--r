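#' Stimulus parameters for mixed-correlation random-dot stereograms
#'
#' Bundles the full parameterization of a (dynamic) random-dot stereogram:
#' a disparity-defined central disk surrounded by a zero-disparity annulus,
#' drawn with anti-aliased black and white dots on a mid-gray background.
#' Luminance is coded gray = 0, white = +1, black = -1, so that
#' anticorrelation is sign inversion.
#'
#' Dot density is the proportion of region area the dots would cover if they
#' never occluded one another (they are allowed to occlude), so it may exceed
#' 1.  The number of dots per region is
#' `round(density * region_area / (pi * dot_radius_deg^2))`.
#'
#' @param field_size_px Square stimulus size in pixels (default 292).
#' @param deg_per_px Degrees of visual angle per pixel (default 0.03).
#' @param dot_radius_deg Dot radius in degrees (default 0.09).
#' @param density Coverage proportion (default 0.24; may exceed 1).
#' @param disparity_deg Signed horizontal disparity of the central disk, in
#'   degrees.  Split symmetrically: +d/2 in the left eye, -d/2 in the right.
#' @param match_level Proportion of binocularly matched dots in the disk,
#'   in `[0, 1]`; 0.5 is half-matched.  Related to binocular correlation by
#'   `correlation = 2 * match_level - 1`.
#' @param binocular_correlation Alternative to `match_level`, in `[-1, 1]`.
#' @param disk_diameter_deg Diameter of the disparity-defined disk (2.5).
#' @param annulus_width_deg Width of the surrounding annulus (1.0).
#' @param surround_mode `"correlated"` (surround always 100% correlated) or
#'   `"same_as_center"` (surround shares the center's match level).
#' @param refresh_rate_hz Dot pattern refresh rate in Hz.
#' @param duration_s Stimulus duration in seconds.
#' @param avoid_overlap If `TRUE`, dot centres are rejection-sampled so that
#'   dots never occlude (only feasible at low density; used by validation
#'   utilities).
#' @return An object of class `stim_params`.
#' @examples
#' p <- stim_params(density = 0.24, match_level = 0.5)
#' n_dots(p)
#' @export
stim_params <- function(field_size_px = 292L, deg_per_px = 0.03,
                        dot_radius_deg = 0.09, density = 0.24,
                        disparity_deg = 0, match_level = NULL,
                        binocular_correlation = NULL,
                        disk_diameter_deg = 2.5, annulus_width_deg = 1.0,
                        surround_mode = c("correlated", "same_as_center"),
                        refresh_rate_hz = 21.25, duration_s = 1.5,
                        avoid_overlap = FALSE) {
  surround_mode <- match.arg(surround_mode)
  if (!is.null(match_level) && !is.null(binocular_correlation))
    stop("give either 'match_level' or 'binocular_correlation', not both")
  if (is.null(match_level))
    match_level <- if (is.null(binocular_correlation)) 1
      else (binocular_correlation + 1) / 2
  stopifnot(field_size_px >= 4, deg_per_px > 0)
  if (density < 0) stop("'density' must be >= 0")
  if (dot_radius_deg <= 0) stop("'dot_radius_deg' must be > 0")
  if (disk_diameter_deg <= 0) stop("'disk_diameter_deg' must be > 0")
  if (annulus_width_deg < 0) stop("'annulus_width_deg' must be >= 0")
  if (match_level < 0 || match_level > 1)
    stop("'match_level' must be in [0, 1]")
  if (refresh_rate_hz <= 0) stop("'refresh_rate_hz' must be > 0")
  if (duration_s <= 0) stop("'duration_s' must be > 0")
  p <- list(field_size_px = as.integer(field_size_px),
            deg_per_px = deg_per_px, dot_radius_deg = dot_radius_deg,
            density = density, disparity_deg = disparity_deg,
            match_level = match_level,
            disk_diameter_deg = disk_diameter_deg,
            annulus_width_deg = annulus_width_deg,
            surround_mode = surround_mode,
            refresh_rate_hz = refresh_rate_hz, duration_s = duration_s,
            avoid_overlap = isTRUE(avoid_overlap))
  class(p) <- "stim_params"
  p
}

#' @export
print.stim_params <- function(x, ...) {
  cat("Random-dot stereogram parameters\n")
  cat(sprintf("  field: %d x %d px at %.3f deg/px (%.2f deg)\n",
              x$field_size_px, x$field_size_px, x$deg_per_px,
              x$field_size_px * x$deg_per_px))
  cat(sprintf("  dots: radius %.3f deg, density %.3g, match level %.2f (correlation %+.2f)\n",
              x$dot_radius_deg, x$density, x$match_level,
              2 * x$match_level - 1))
  cat(sprintf("  disk %.2f deg, annulus %.2f deg, surround %s, disparity %+.4f deg\n",
              x$disk_diameter_deg, x$annulus_width_deg, x$surround_mode,
              x$disparity_deg))
  cat(sprintf("  refresh %.4g Hz, duration %.4g s\n",
              x$refresh_rate_hz, x$duration_s))
  invisible(x)
}

#' Expected dot counts per stimulus region
#'
#' @param params A [stim_params()] object.
#' @return Named integer vector with elements `center` and `surround`.
#' @export
n_dots <- function(params) {
  r <- params$dot_radius_deg
  R1 <- params$disk_diameter_deg / 2
  R2 <- R1 + params$annulus_width_deg
  a_center <- pi * R1^2
  a_surround <- pi * (R2^2 - R1^2)
  c(center = as.integer(round(params$density * a_center / (pi * r^2))),
    surround = as.integer(round(params$density * a_surround / (pi * r^2))))
}

## Frame schedule: frame k (k = 0, 1, ...) has onset k / refresh; frames
## whose onset falls before the trial end are shown, the last one possibly
## truncated (shown for the remaining time).
frame_schedule <- function(refresh_rate_hz, duration_s) {
  interval <- 1 / refresh_rate_hz
  if (duration_s < interval - 1e-12)
    stop("duration_s (", duration_s, " s) is shorter than one frame (",
         signif(interval, 6), " s)")
  nf <- ceiling(duration_s / interval - 1e-9)
  onsets <- (seq_len(nf) - 1) * interval
  list(interval = interval, onsets = onsets, n_frames = as.integer(nf),
       n_complete_frames = as.integer(floor(duration_s / interval + 1e-9)))
}

## Uniform sample in a disk / annulus (degrees, centred on fixation).
runif_disk <- function(n, r_outer, r_inner = 0) {
  r <- sqrt(stats::runif(n, r_inner^2, r_outer^2))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(x = r * cos(th), y = r * sin(th))
}

## Rejection-sample non-overlapping dot centres (oracle utility).
sample_nonoverlap <- function(n, r_outer, r_inner, min_dist) {
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n) {
    p <- runif_disk(1L, r_outer, r_inner)
    if (length(xs) == 0 ||
        min((xs - p[1])^2 + (ys - p[2])^2) >= min_dist^2) {
      xs <- c(xs, p[1]); ys <- c(ys, p[2])
    }
    tries <- tries + 1L
    if (tries > 2000L * n)
      stop("cannot place ", n, " non-overlapping dots at this density")
  }
  cbind(x = xs, y = ys)
}

## Generate the dots of one or more frames, in paint order.
## match_level may be a vector of length n_frames (alternating stimuli).
## Returns pixel-space coordinates ready for the rendering engine.
##
## uncorrelated = TRUE draws independent dot patterns for the two eyes
## (no binocular correspondence at all).
gen_dots <- function(params, n_frames = 1L, match_level = params$match_level,
                     uncorrelated = FALSE) {
  match_level <- rep_len(match_level, n_frames)
  r <- params$dot_radius_deg
  R1 <- params$disk_diameter_deg / 2
  R2 <- R1 + params$annulus_width_deg
  nd <- n_dots(params)
  half <- params$disparity_deg / 2

  one_eye_set <- function(nc, ns) {
    if (params$avoid_overlap) {
      pc <- sample_nonoverlap(nc, R1, 0, 2 * r + 2 * params$deg_per_px)
      ps <- if (ns > 0)
        sample_nonoverlap(ns, R2, R1, 2 * r + 2 * params$deg_per_px)
      else cbind(x = numeric(0), y = numeric(0))
    } else {
      pc <- runif_disk(nc, R1)
      ps <- runif_disk(ns, R2, R1)
    }
    list(pc = pc, ps = ps)
  }

  lx <- ly <- lpol <- rx <- ry <- rpol <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    m <- match_level[f]
    s <- one_eye_set(nd[["center"]], nd[["surround"]])
    nc <- nrow(s$pc); ns <- nrow(s$ps)
    pol <- sample(c(-1, 1), nc + ns, replace = TRUE)
    matched <- logical(nc + ns)
    ## fractional dots are assigned at random so that counts are unbiased
    ## (an odd dot count would otherwise skew the realized match level)
    n_frac <- function(m, n) floor(m * n) + (stats::runif(1) < (m * n) %% 1)
    matched[seq_len(nc)][sample.int(nc, n_frac(m, nc))] <- TRUE
    m_s <- if (params$surround_mode == "correlated") 1 else m
    if (ns > 0)
      matched[nc + sample.int(ns, n_frac(m_s, ns))] <- TRUE

    x <- c(s$pc[, "x"], s$ps[, "x"])
    y <- c(s$pc[, "y"], s$ps[, "y"])
    dsh <- c(rep(half, nc), rep(0, ns))  # surround: zero disparity
    if (uncorrelated) {
      s2 <- one_eye_set(nc, ns)
      x2 <- c(s2$pc[, "x"], s2$ps[, "x"])
      y2 <- c(s2$pc[, "y"], s2$ps[, "y"])
      pol2 <- sample(c(-1, 1), nc + ns, replace = TRUE)
      xl <- x + dsh; yl <- y; pl <- pol
      xr <- x2 - dsh; yr <- y2; pr <- pol2
    } else {
      xl <- x + dsh; yl <- y; pl <- pol
      xr <- x - dsh; yr <- y
      pr <- pol * ifelse(matched, 1, -1)
    }
    ## single random paint permutation, identical in both eyes
    ord <- sample.int(nc + ns)
    lx[[f]] <- xl[ord]; ly[[f]] <- yl[ord]; lpol[[f]] <- pl[ord]
    rx[[f]] <- xr[ord]; ry[[f]] <- yr[ord]; rpol[[f]] <- pr[ord]
  }
  n_per <- vapply(lx, length, 1L)
  to_px_x <- function(v) v / params$deg_per_px + (params$field_size_px + 1) / 2
  list(lx = to_px_x(unlist(lx)), ly = to_px_x(unlist(ly)),
       lpol = unlist(lpol),
       rx = to_px_x(unlist(rx)), ry = to_px_x(unlist(ry)),
       rpol = unlist(rpol),
       frame_ptr = as.integer(c(0L, cumsum(n_per))),
       r_px = r / params$deg_per_px)
}

## Generate matched stimulus triplets (correlated / half-matched /
## uncorrelated) sharing dot layout, polarities and paint order — common
## random numbers for low-variance class contrasts (Rnorm estimation).
## Returns dots for 3 * n_frames frames ordered (corr, hm, unc) per
## pattern.
gen_dots_classes <- function(params, n_frames = 1L) {
  r <- params$dot_radius_deg
  R1 <- params$disk_diameter_deg / 2
  R2 <- R1 + params$annulus_width_deg
  nd <- n_dots(params)
  half <- params$disparity_deg / 2
  nc <- nd[["center"]]; ns <- nd[["surround"]]
  lx <- ly <- lpol <- rx <- ry <- rpol <- vector("list", 3L * n_frames)
  for (f in seq_len(n_frames)) {
    pc <- runif_disk(nc, R1); ps <- runif_disk(ns, R2, R1)
    x <- c(pc[, "x"], ps[, "x"]); y <- c(pc[, "y"], ps[, "y"])
    pol <- sample(c(-1, 1), nc + ns, replace = TRUE)
    dsh <- c(rep(half, nc), rep(0, ns))
    ord <- sample.int(nc + ns)
    ## anticorrelated flags for the half-matched variant (center only;
    ## surround per surround_mode); fractional dots assigned at random
    anti <- logical(nc + ns)
    n_anti <- function(n) floor(0.5 * n) + (stats::runif(1) < (0.5 * n) %% 1)
    anti[sample.int(nc, n_anti(nc))] <- TRUE
    if (params$surround_mode == "same_as_center" && ns > 0)
      anti[nc + sample.int(ns, n_anti(ns))] <- TRUE
    ## independent right-eye pattern for the uncorrelated variant
    pc2 <- runif_disk(nc, R1); ps2 <- runif_disk(ns, R2, R1)
    x2 <- c(pc2[, "x"], ps2[, "x"]); y2 <- c(pc2[, "y"], ps2[, "y"])
    pol2 <- sample(c(-1, 1), nc + ns, replace = TRUE)
    k <- 3L * (f - 1L)
    ## correlated
    lx[[k + 1L]] <- (x + dsh)[ord]; ly[[k + 1L]] <- y[ord]
    lpol[[k + 1L]] <- pol[ord]
    rx[[k + 1L]] <- (x - dsh)[ord]; ry[[k + 1L]] <- y[ord]
    rpol[[k + 1L]] <- pol[ord]
    ## half-matched
    lx[[k + 2L]] <- lx[[k + 1L]]; ly[[k + 2L]] <- ly[[k + 1L]]
    lpol[[k + 2L]] <- pol[ord]
    rx[[k + 2L]] <- rx[[k + 1L]]; ry[[k + 2L]] <- ry[[k + 1L]]
    rpol[[k + 2L]] <- (pol * ifelse(anti, -1, 1))[ord]
    ## uncorrelated
    lx[[k + 3L]] <- lx[[k + 1L]]; ly[[k + 3L]] <- ly[[k + 1L]]
    lpol[[k + 3L]] <- pol[ord]
    rx[[k + 3L]] <- (x2 - dsh)[ord]; ry[[k + 3L]] <- y2[ord]
    rpol[[k + 3L]] <- pol2[ord]
  }
  n_per <- vapply(lx, length, 1L)
  to_px <- function(v) v / params$deg_per_px + (params$field_size_px + 1) / 2
  list(lx = to_px(unlist(lx)), ly = to_px(unlist(ly)), lpol = unlist(lpol),
       rx = to_px(unlist(rx)), ry = to_px(unlist(ry)), rpol = unlist(rpol),
       frame_ptr = as.integer(c(0L, cumsum(n_per))),
       r_px = r / params$deg_per_px)
}

render_frames <- function(params, dots) {
  n <- params$field_size_px
  nf <- length(dots$frame_ptr) - 1L
  left <- array(0, c(n, n, nf)); right <- array(0, c(n, n, nf))
  for (f in seq_len(nf)) {
    i <- (dots$frame_ptr[f] + 1L):dots$frame_ptr[f + 1L]
    if (dots$frame_ptr[f + 1L] > dots$frame_ptr[f]) {
      left[, , f] <- .cpp_paint_dots(n, n, dots$lx[i], dots$ly[i],
                                     dots$lpol[i], dots$r_px)
      right[, , f] <- .cpp_paint_dots(n, n, dots$rx[i], dots$ry[i],
                                      dots$rpol[i], dots$r_px)
    }
  }
  list(left = left, right = right)
}

new_stereo_frames <- function(left, right, frame_times, params,
                              n_complete = dim(left)[3],
                              match_per_frame = NULL) {
  structure(list(left = left, right = right, frame_times = frame_times,
                 params = params,
                 n_complete_frames = as.integer(n_complete),
                 match_per_frame = match_per_frame),
            class = "stereo_frames")
}

#' Generate a single random-dot stereogram pair
#'
#' Draws one left/right image pair.  Center-disk dots carry the disparity
#' split symmetrically (+d/2 left eye, -d/2 right eye); each dot is black or
#' white with probability 0.5; a matched dot has the same sign in both eyes,
#' an unmatched dot the opposite sign.  Dots are painted in a single random
#' order (center and surround interleaved) so occlusion carries no cue.
#'
#' @param params A [stim_params()] object.
#' @param uncorrelated If `TRUE` the two eyes receive completely independent
#'   dot patterns (no binocular correspondence); `match_level` is ignored.
#' @param seed Optional integer seed.
#' @return A `stereo_frames` object with one frame.
#' @examples
#' p <- stim_params(field_size_px = 64, match_level = 1, disparity_deg = 0)
#' s <- make_dot_pattern(p, seed = 1)
#' identical(s$left, s$right)
#' @export
make_dot_pattern <- function(params, uncorrelated = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dots <- gen_dots(params, 1L, uncorrelated = uncorrelated)
  im <- render_frames(params, dots)
  new_stereo_frames(im$left, im$right, 0, params)
}

#' Generate a dynamic random-dot stereogram
#'
#' Independent fresh dot patterns at each refresh interval, identical
#' disparity and match level throughout.  Frame onsets are at multiples of
#' the refresh interval; the last frame is truncated if the duration is not
#' a whole number of intervals (`n_complete_frames` counts the whole ones).
#'
#' @inheritParams make_dot_pattern
#' @return A `stereo_frames` object (`left`/`right` are y-by-x-by-frame
#'   arrays, `frame_times` the onset of each frame in seconds).
#' @export
make_dynamic_rds <- function(params, uncorrelated = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sch <- frame_schedule(params$refresh_rate_hz, params$duration_s)
  dots <- gen_dots(params, sch$n_frames, uncorrelated = uncorrelated)
  im <- render_frames(params, dots)
  new_stereo_frames(im$left, im$right, sch$onsets, params,
                    n_complete = sch$n_complete_frames)
}

#' Parameters for alternating-correlation stereograms
#'
#' Every monitor frame is a fresh dot pattern; the binocular correlation of
#' the pattern flips between +1 (all dots matched) and -1 (all dots
#' anticorrelated) following a square wave at `alternation_rate_hz`.  The
#' refresh rate must be an integer multiple of twice the alternation rate so
#' each half-cycle is a whole number of frames.
#'
#' @param base A [stim_params()] object (refresh rate conventionally 120 Hz;
#'   surround is forced to `same_as_center` as in the alternating stimulus).
#' @param alternation_rate_hz Correlation alternation rate in Hz.
#' @param start_phase `"correlated_first"`, `"anticorrelated_first"` or
#'   `"random"`.
#' @return An object of class `alternation_params`.
#' @export
alternation_params <- function(base = stim_params(refresh_rate_hz = 120,
                                                  duration_s = 0.5,
                                                  density = 2,
                                                  surround_mode = "same_as_center"),
                               alternation_rate_hz = 15,
                               start_phase = c("correlated_first",
                                               "anticorrelated_first",
                                               "random")) {
  start_phase <- match.arg(start_phase)
  fph <- base$refresh_rate_hz / (2 * alternation_rate_hz)
  if (abs(fph - round(fph)) > 1e-9)
    stop("refresh_rate_hz must be an integer multiple of ",
         "2 * alternation_rate_hz (got ",
         base$refresh_rate_hz, " / (2 * ", alternation_rate_hz, ") = ",
         signif(fph, 6), " frames per half-cycle)")
  base$surround_mode <- "same_as_center"
  structure(list(base = base, alternation_rate_hz = alternation_rate_hz,
                 start_phase = start_phase,
                 frames_per_half_cycle = as.integer(round(fph))),
            class = "alternation_params")
}

## The per-frame match levels (1 or 0) of an alternating trial.
alternation_match_levels <- function(ap, n_frames,
                                     first_correlated = TRUE) {
  half <- ap$frames_per_half_cycle
  sq <- rep(rep(c(1, 0), each = half), length.out = n_frames)
  if (!first_correlated) sq <- 1 - sq
  sq
}

#' Generate an alternating-correlation stereogram
#'
#' @param ap An [alternation_params()] object.
#' @param seed Optional integer seed.
#' @return A `stereo_frames` object; `match_per_frame` records the realized
#'   square wave (1 = correlated frame, 0 = anticorrelated frame).
#' @export
make_alternating_rds <- function(ap, seed = NULL) {
  stopifnot(inherits(ap, "alternation_params"))
  if (!is.null(seed)) set.seed(seed)
  sch <- frame_schedule(ap$base$refresh_rate_hz, ap$base$duration_s)
  first <- switch(ap$start_phase,
                  correlated_first = TRUE,
                  anticorrelated_first = FALSE,
                  random = stats::runif(1) < 0.5)
  ml <- alternation_match_levels(ap, sch$n_frames, first)
  dots <- gen_dots(ap$base, sch$n_frames, match_level = ml)
  im <- render_frames(ap$base, dots)
  new_stereo_frames(im$left, im$right, sch$onsets, ap$base,
                    n_complete = sch$n_complete_frames,
                    match_per_frame = ml)
}

#' @export
print.stereo_frames <- function(x, ...) {
  d <- dim(x$left)
  cat(sprintf("Stereo frame sequence: %d frame(s) of %d x %d px\n",
              d[3], d[1], d[2]))
  cat(sprintf("  disparity %+.4f deg, match level %.2f, refresh %.4g Hz\n",
              x$params$disparity_deg, x$params$match_level,
              x$params$refresh_rate_hz))
  invisible(x)
}

#' @export
plot.stereo_frames <- function(x, frame = 1L, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  for (eye in c("left", "right")) {
    img <- x[[eye]][, , frame]
    graphics::image(t(img[nrow(img):1, ]), col = gray.colors(256),
                    zlim = c(-1, 1), axes = FALSE, main = eye, asp = 1)
  }
  invisible(x)
}

#' Pixel mask of the disparity-defined central disk
#'
#' @param params A [stim_params()] object.
#' @param shrink_deg Radial margin subtracted from the disk radius.
#' @return Logical matrix (y by x).
#' @export
center_disk_mask <- function(params, shrink_deg = 0) {
  n <- params$field_size_px
  ctr <- (n + 1) / 2
  xy <- ((seq_len(n) - ctr) * params$deg_per_px)
  d2 <- outer(xy^2, xy^2, "+")  # rows = y, cols = x
  d2 <= (params$disk_diameter_deg / 2 - shrink_deg)^2
}

#' Per-frame binocular pixel correlation
#'
#' Pearson correlation of left vs right pixel luminance within a mask, one
#' value per frame.  Validates, for example, that a half-matched stereogram
#' has mean binocular correlation 0.  Frames with no luminance variance
#' (all gray) give `NA`.
#'
#' @param seq A `stereo_frames` object.
#' @param mask Logical matrix; defaults to the central disk eroded by one
#'   dot footprint (radius plus the anti-alias ramp) so that surround dots
#'   spilling over the boundary do not leak into the estimate.
#' @return Numeric vector, one correlation per frame.
#' @export
binocular_pixel_correlation <- function(seq, mask = NULL) {
  stopifnot(inherits(seq, "stereo_frames"))
  if (is.null(mask))
    mask <- center_disk_mask(seq$params,
                             shrink_deg = seq$params$dot_radius_deg +
                               2 * seq$params$deg_per_px)
  if (!any(mask)) stop("empty mask")
  nf <- dim(seq$left)[3]
  vapply(seq_len(nf), function(f) {
    l <- seq$left[, , f][mask]; r <- seq$right[, , f][mask]
    if (stats::sd(l) == 0 || stats::sd(r) == 0) return(NA_real_)
    stats::cor(l, r)
  }, numeric(1))
}

#' Export a stereogram as PNG image stacks plus a JSON sidecar
#'
#' Writes `<prefix>_L_<frame>.png` / `<prefix>_R_<frame>.png` (luminance
#' mapped from `[-1, 1]` to `[0, 1]`) and `<prefix>_params.json` recording
#' the full stimulus parameterization.  An `.rds` copy of the sequence can
#' be written for exact round-trips.
#'
#' @param seq A `stereo_frames` object.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix.
#' @param rds Also write `<prefix>.rds` with the exact arrays.
#' @return Invisibly, the paths written.
#' @export
write_stimulus <- function(seq, dir, prefix = "stim", rds = FALSE) {
  stopifnot(inherits(seq, "stereo_frames"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nf <- dim(seq$left)[3]
  paths <- character(0)
  for (f in seq_len(nf)) {
    for (eye in c("L", "R")) {
      img <- (seq[[if (eye == "L") "left" else "right"]][, , f] + 1) / 2
      p <- file.path(dir, sprintf("%s_%s_%03d.png", prefix, eye, f))
      png::writePNG(img, p)
      paths <- c(paths, p)
    }
  }
  side <- file.path(dir, paste0(prefix, "_params.json"))
  jsonlite::write_json(unclass(seq$params), side, auto_unbox = TRUE,
                       digits = NA)
  paths <- c(paths, side)
  if (rds) {
    rp <- file.path(dir, paste0(prefix, ".rds"))
    saveRDS(seq, rp)
    paths <- c(paths, rp)
  }
  invisible(paths)
}
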