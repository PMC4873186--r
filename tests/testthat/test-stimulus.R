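test_that("stimulus parameters validate and map correlation to match level", {
  expect_error(stim_params(density = -1), "density")
  expect_error(stim_params(match_level = 1.2), "match_level")
  expect_error(stim_params(dot_radius_deg = 0), "dot_radius_deg")
  expect_error(stim_params(match_level = 1, binocular_correlation = 0),
               "not both")
  expect_equal(stim_params(binocular_correlation = -1)$match_level, 0)
  expect_equal(stim_params(binocular_correlation = 0)$match_level, 0.5)
  expect_equal(stim_params(binocular_correlation = 1)$match_level, 1)
})

test_that("dot counts follow density * area / dot area per region", {
  p <- stim_params(density = 0.24, dot_radius_deg = 0.09)
  nd <- n_dots(p)
  # independent arithmetic: disk 2.5 deg diameter, annulus 1 deg wide
  expect_identical(nd[["center"]],
                   as.integer(round(0.24 * pi * 1.25^2 / (pi * 0.09^2))))
  expect_identical(nd[["surround"]],
                   as.integer(round(0.24 * pi * (2.25^2 - 1.25^2) /
                                      (pi * 0.09^2))))
  # density may exceed 1 and scales dot count linearly
  expect_equal(n_dots(stim_params(density = 2.4))[["center"]],
               as.integer(round(10 * 0.24 * pi * 1.25^2 / (pi * 0.09^2))))
})

test_that("degenerate and fully matched patterns are exact", {
  s0 <- make_dot_pattern(small_params(density = 1e-6), seed = 3)
  expect_true(all(s0$left == 0) && all(s0$right == 0))
  s1 <- make_dot_pattern(small_params(match_level = 1, disparity_deg = 0),
                         seed = 4)
  expect_identical(s1$left, s1$right)
  expect_true(all(abs(s1$left) <= 1))
})

test_that("anticorrelated patterns are sign-inverted between the eyes", {
  # occlusion disabled (non-overlapping dots) and zero disparity: the
  # center region is exactly sign-inverted; the correlated surround is
  # excluded via an eroded disk mask
  p <- small_params(match_level = 0, disparity_deg = 0, density = 0.08,
                    avoid_overlap = TRUE)
  s <- make_dot_pattern(p, seed = 5)
  mask <- center_disk_mask(p, shrink_deg = p$dot_radius_deg + 2 * p$deg_per_px)
  expect_equal(s$left[mask], -s$right[mask])
  expect_equal(binocular_pixel_correlation(s), -1, tolerance = 1e-6)
})

test_that("binocular pixel correlation matches the match level", {
  p <- small_params(match_level = 1, disparity_deg = 0,
                    refresh_rate_hz = 40, duration_s = 0.5)
  s <- make_dynamic_rds(p, seed = 6)
  expect_equal(unname(binocular_pixel_correlation(s)), rep(1, 20))
  # half-matched: mean correlation within 3 SE of 0 over many frames
  p$match_level <- 0.5; p$duration_s <- 5
  s <- make_dynamic_rds(p, seed = 7)
  r <- binocular_pixel_correlation(s)
  expect_lt(abs(mean(r)) / (sd(r) / sqrt(length(r))), 3.5)
  # all-gray frame: correlation undefined, reported as NA
  sg <- make_dot_pattern(small_params(density = 1e-6), seed = 8)
  expect_true(is.na(binocular_pixel_correlation(sg)))
  expect_error(binocular_pixel_correlation(s, mask = matrix(FALSE, 2, 2)),
               "empty mask")
})

test_that("frame schedule gives the printed intervals and truncation rule", {
  expect_equal(frame_interval_ms(21.25), 47.06, tolerance = 1e-4)
  expect_equal(frame_interval_ms(120), 8.33, tolerance = 1e-3)
  sch <- stereobem:::frame_schedule(21.25, 1.5)
  expect_identical(sch$n_complete_frames, 31L)  # floor(1.5 * 21.25)
  expect_identical(sch$n_frames, 32L)           # last partial frame shown
  expect_true(all(sch$onsets < 1.5))
  expect_error(stereobem:::frame_schedule(2, 0.4), "shorter than one frame")
})

test_that("dynamic sequences refresh the pattern every frame", {
  p <- small_params(refresh_rate_hz = 30, duration_s = 0.2)
  s <- make_dynamic_rds(p, seed = 9)
  expect_identical(dim(s$left)[3], 6L)
  expect_false(identical(s$left[, , 1], s$left[, , 2]))
  expect_identical(dim(s$left), dim(s$right))
})

test_that("alternating sequences follow the square wave", {
  base <- small_params(refresh_rate_hz = 120, duration_s = 0.1, density = 1)
  ap60 <- alternation_params(base, 60, start_phase = "correlated_first")
  expect_identical(ap60$frames_per_half_cycle, 1L)
  s <- make_alternating_rds(ap60, seed = 10)
  expect_equal(s$match_per_frame, rep(c(1, 0), 6))
  # per-frame binocular correlation flips sign every frame
  r <- binocular_pixel_correlation(s)
  expect_true(all(sign(r) == rep(c(1, -1), 6)))
  ap30 <- alternation_params(base, 30)
  s30 <- make_alternating_rds(ap30, seed = 11)
  expect_equal(s30$match_per_frame, rep(c(1, 1, 0, 0), 3))
  expect_error(alternation_params(base, 50), "integer multiple")
})

test_that("random start phase is balanced", {
  base <- small_params(refresh_rate_hz = 120, duration_s = 0.025,
                       density = 0.05)
  ap <- alternation_params(base, 60, start_phase = "random")
  set.seed(12)
  firsts <- replicate(400, make_alternating_rds(ap)$match_per_frame[1])
  # binomial 3 sigma band around 0.5
  expect_lt(abs(mean(firsts) - 0.5), 3 * sqrt(0.25 / 400) + 1e-9)
})

test_that("coverage and polarity statistics match the generator contract", {
  # expected non-gray fraction at low density ~ density (occlusion rare)
  p <- small_params(density = 0.04, match_level = 1)
  set.seed(13)
  fr <- replicate(40, {
    s <- make_dot_pattern(p)
    mask <- center_disk_mask(p)
    mean(abs(s$left[mask]) > 0.5)
  })
  expect_lt(abs(mean(fr) - 0.04), 0.008)
  # black and white dots balanced over many patterns
  pol <- replicate(40, {
    s <- make_dot_pattern(p)
    v <- s$left[abs(s$left) > 0.9]
    mean(v > 0)
  })
  expect_lt(abs(mean(pol) - 0.5), 3 * sd(pol) / sqrt(length(pol)))
})

test_that("disparity moves the eyes' center regions by +-d/2", {
  d <- 0.12  # 4 px at 0.03 deg/px
  p <- small_params(match_level = 1, disparity_deg = d)
  s <- make_dot_pattern(p, seed = 14)
  mask <- center_disk_mask(p, shrink_deg = 0.25)
  rows <- which(apply(mask, 1, any))
  lag_corr <- sapply(-6:6, function(k) {
    l <- s$left[, , 1][rows, , drop = FALSE]
    r <- s$right[, , 1][rows, , drop = FALSE]
    nc <- ncol(l)
    sel <- (6 + 1):(nc - 6)
    stats::cor(as.numeric(l[, sel + k]), as.numeric(r[, sel]))
  })
  # left eye content is shifted +d/2 and right -d/2: the cross-correlation
  # peaks at the full pixel disparity
  expect_identical((-6:6)[which.max(lag_corr)], 4L)
})

test_that("stimulus export writes PNG stacks with a JSON sidecar", {
  dir <- withr::local_tempdir()
  p <- small_params(refresh_rate_hz = 40, duration_s = 0.05)
  s <- make_dynamic_rds(p, seed = 15)
  paths <- write_stimulus(s, dir, "t")
  expect_true(all(file.exists(paths)))
  expect_length(grep("\\.png$", paths), 2 * dim(s$left)[3])
  side <- jsonlite::read_json(file.path(dir, "t_params.json"))
  expect_equal(side$density, p$density)
  img <- png::readPNG(paths[1])
  expect_equal(img, (s$left[, , 1] + 1) / 2, tolerance = 1 / 255)
})
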