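# Small-geometry fixtures: full-scale stimuli are 292 px; unit tests use a
# reduced field so rendering and inner products stay cheap.

small_params <- function(...) {
  stim_params(field_size_px = 120L, disk_diameter_deg = 1.6,
              annulus_width_deg = 0.6, ...)
}

# a small BEM probe centred on the fixture disk
small_unit <- function(dx = 0.1, sigma = 0.08, ...) {
  bem_unit(dx = dx, sigma = sigma, ...)
}

# a reduced opponent population (8 cells per disparity) for plumbing tests
small_population <- function(params = stim_params(), kernel = NULL,
                             exponent = 2, seed = 99) {
  spec <- population_spec(n_per_disparity = 8L)
  build_population(spec, params, exponent = exponent, kernel = kernel,
                   seed = seed)
}

# grating stereogram: identical sinusoidal luminance in both eyes
grating_frames <- function(params, f, phase = 0) {
  ax <- (seq_len(params$field_size_px) -
           (params$field_size_px + 1) / 2) * params$deg_per_px
  img <- matrix(rep(cos(2 * pi * f * ax + phase),
                    each = params$field_size_px),
                params$field_size_px, params$field_size_px)
  arr <- array(img, c(dim(img), 1L))
  stereobem:::new_stereo_frames(arr, arr, 0, params)
}
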