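# Shared fixtures: all test data is generated programmatically.

# A small ball-mask volume with controllable intensities.
toy_volume <- function(size = 12L, fill = 100, radius = 4) {
  ctr <- (size + 1) / 2
  ax <- seq_len(size) - ctr
  r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  mask <- array(as.numeric(r2 <= radius^2), dim = rep(size, 3L))
  volume(array(fill, dim = rep(size, 3L)) * mask, mask = mask)
}

# Hard-label two-tissue volume: inner WM box, outer GM rim, within a mask.
toy_two_tissue <- function(size = 10L, mu_gm = 300, mu_wm = 600,
                           sd_gm = 0, sd_wm = 0, seed = 1L) {
  set.seed(seed)
  mask <- array(1, dim = rep(size, 3L))
  wm <- array(0, dim = rep(size, 3L))
  inner <- (size %/% 4 + 1):(size - size %/% 4)
  wm[inner, inner, inner] <- 1
  gm <- mask - wm
  v <- array(0, dim = rep(size, 3L))
  v[wm == 1] <- rnorm(sum(wm), mu_wm, sd_wm)
  v[gm == 1] <- rnorm(sum(gm), mu_gm, sd_gm)
  list(vol = volume(v, mask = mask),
       seg = structure(list(csf = array(0, dim = rep(size, 3L)),
                            gm = gm, wm = wm),
                       class = "tissue_segmentation"))
}

# Median-normalize a cohort in place (phantom grids already fit 48^3).
normalize_cohort <- function(co, target = 48L) {
  co$phantoms <- lapply(co$phantoms, function(ph) {
    ph$volume <- pad_crop(normalize_median(ph$volume), target)
    ph
  })
  co
}

site_hist <- function(co) {
  average_histograms(lapply(co$phantoms,
                            function(p) brain_histogram(p$volume)))
}

# Small network specs used throughout the training tests.
test_gen_spec <- function() generator_spec(depth = 2L, base_channels = 8L)
test_disc_spec <- function()
  discriminator_spec(layers = list(c(4, 2, 4), c(4, 2, 8), c(4, 2, 16),
                                   c(3, 1, 1)))

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-12), tol)
}
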