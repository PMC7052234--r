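# Small shared fixtures. Tiny configurations keep FFT convolutions and EM
# loops cheap; the default configuration is exercised where the test is
# about the instrument geometry itself.

tiny_config <- function(n_tcspc = 64L, n_spectral = 4L) {
  sflim_config(n_spectral = n_spectral, n_tcspc = n_tcspc)
}

tiny_irf <- function(config = tiny_config()) gaussian_irf(config)

tiny_donor <- function(brightness = 1) {
  fluorophore("donor", 519, 14, decay = 3.84, excitation = c(1, 0.02),
              brightness = brightness)
}

tiny_acceptor <- function(brightness = 1) {
  fluorophore("acceptor", 573, 16, decay = 4.0, excitation = c(0.1, 0.9),
              brightness = brightness)
}

tiny_pair <- function(E = 0.171875, sf = 0.5) {
  fret_pair(tiny_donor(), tiny_acceptor(), efficiency = E,
            sensitized_fraction = sf)
}

# one-structure scene on a small grid
tiny_scene <- function(label = tiny_donor(), shape = c(16L, 16L),
                       seed = 7L, background = 0) {
  scene_spec(shape = shape,
             structures = list(list(kind = "blobs",
                                    params = list(count = 4L, ax = 2, ay = 3),
                                    label = label)),
             background = background, seed = seed)
}

expect_prob_vector <- function(p, tol = 1e-8) {
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = tol)
}
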