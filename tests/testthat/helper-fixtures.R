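# shared fixtures: tips, stacks, small scenes; everything built in code

default_tip <- function(...) tip_model(...)          # a=80, r=60, L=300, g=0.7e^{i0.06}
real_g_tip <- function() tip_model(g_factor = 0.7) # for lossless-phase checks

si_stack <- function() layer_stack(layer(1), layer(11.7))
uniform_stack <- function(eps = 1)
  suppressWarnings(layer_stack(layer(eps), layer(eps, 10), layer(eps)))
sin_d2o_stack <- function(eps_film = 4, d = 10, eps_sub = 1.69 + 0.35i)
  layer_stack(layer(1), layer(eps_film, d), layer(eps_sub))

# single-vesicle scene in the style of the imaging experiments:
# flat interior amplitude/phase, ~100 nm fringe, 10 nm pixels
disc_scene <- function(radius = 330, noise_sigma = 0, seed = 1L,
                       interior_amplitude = 7.8 * exp(1),
                       fringe_width = 100, n = 128) {
  scene_spec(image_size = c(n, n), pixel_size = 10,
             vesicles = data.frame(x = n * 5, y = n * 5, radius = radius,
                                   interior_phase = 28,
                                   interior_amplitude = interior_amplitude,
                                   fringe_width = fringe_width),
             background_amplitude = 0, background_phase = 10,
             noise_sigma = noise_sigma, seed = seed)
}

# rasterized binary disc / square masks (pixel units)
disc_mask <- function(R = 50.3, n = 128, cx = n / 2, cy = n / 2) {
  xs <- seq_len(n) - 0.5
  outer(xs, xs, function(x, y) (x - cx)^2 + (y - cy)^2 <= R^2)
}
square_mask <- function(s = 40, n = 128, i0 = 40) {
  m <- matrix(FALSE, n, n)
  m[i0:(i0 + s - 1), i0:(i0 + s - 1)] <- TRUE
  m
}

expect_rel <- function(x, y, tol) expect_lt(abs(x / y - 1), tol)
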