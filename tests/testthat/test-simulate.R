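test_that("make_axis builds the documented uniform grids", {
  ax <- make_axis(602, 4, 308L)
  expect_equal(ax$values[1], 602)
  expect_equal(ax$values[308], 602 + 4 * 307)   # = 1830
  expect_true(all(c(1006, 1010, 1614) %in% ax$values))
  ax2 <- make_axis(1543, 4, 50L)
  expect_true(all(c(1603, 1607, 1611) %in% ax2$values))
  expect_error(make_axis(602, 4, 1L), "at least 2")
  expect_error(make_axis(602, 0, 10L), "positive")
})

test_that("signature_spectrum reproduces peak maximum and FWHM by construction", {
  ax <- wavenumber_axis(seq(960, 1040, by = 10))
  sig <- gas_signature("x", data.frame(center = 1000, fwhm = 20, amplitude = 1))
  s <- signature_spectrum(sig, ax)
  expect_equal(s[ax$values == 1000], 1.0)
  expect_equal(s[ax$values == 990], 0.5)        # half maximum at c - fwhm/2
  expect_equal(s[ax$values == 1010], 0.5)
  # Gaussian lineshape has the same FWHM parameterization
  sg <- signature_spectrum(sig, ax, lineshape = "gaussian")
  expect_equal(sg[ax$values == 1000], 1.0)
  expect_equal(sg[ax$values == 990], 0.5, tolerance = 1e-12)
  expect_error(gas_signature("bad", data.frame(center = numeric(0),
                                               fwhm = numeric(0),
                                               amplitude = numeric(0))),
               "at least one peak")
})

test_that("1603 + 1614 bands merge into a single 1607 grid peak at 4 cm^-1 sampling", {
  ax <- short_axis()
  sig <- gas_signature("mix", data.frame(center = c(1603, 1614),
                                         fwhm = c(20, 20),
                                         amplitude = c(1, 1)))
  s <- signature_spectrum(sig, ax)
  win <- which(ax$values >= 1595 & ax$values <= 1620)
  expect_equal(ax$values[win][which.max(s[win])], 1607)
})

test_that("plume_field matches the Gaussian closed form", {
  g <- grid_geometry()
  # source exactly at the center of pixel (17, 17)
  ctr <- pixel_center_mm(17L, 17L, g)
  src <- source_spec("BZD", c(ctr$x_mm, ctr$y_mm), sigma = 2, strength = 3)
  f <- plume_field(src, g)
  expect_equal(f[18, 18], 3)                      # strength at the source pixel
  expect_equal(f[18, 18 - 5], f[18, 18 + 5])      # mirror symmetry in x
  expect_equal(f[18 - 7, 18], f[18 + 7, 18])      # and in y
  # grid sum approximates the analytic integral 2*pi*sx*sy / pitch^2
  src_c <- source_spec("BZD", c(7.5, 7.5), sigma = 2, strength = 1)
  expect_equal(sum(plume_field(src_c, g)), 2 * pi * 4 / g$pitch^2,
               tolerance = 0.01)
  expect_error(source_spec("BZD", c(7.5, 7.5), sigma = 0), "positive")
})

test_that("gap_mask marks the internal sensor boundaries", {
  g <- grid_geometry()
  mask <- gap_mask(g)
  expect_equal(sum(mask), 140L)                   # 2*36 + 2*36 - 4 overlaps
  expect_true(all(mask[13, ]) && all(mask[25, ])) # rows 12, 24 (0-based)
  expect_true(all(mask[, 13]) && all(mask[, 25]))
  expect_equal(sum(gap_mask(g, band_width = 0L)), 0L)
  expect_identical(mask, t(mask))                 # symmetric construction
  expect_error(gap_mask(g, sensors_per_side = 5L), "divisible")
})

test_that("simulate_scan follows its generative formula", {
  sc <- simulate_scan(list(center_bzd_source()))
  expect_equal(dim(sc$V), c(1296L, 308L))

  # zero sources, zero noise: every non-gap spectrum is exactly b * B
  g <- grid_geometry(6L, 6L)
  ax <- short_axis()
  sc0 <- simulate_scan(list(), noise = noise_model(0, 0, 1L, seed = 1L),
                       geometry = g, axis = ax,
                       baseline_strength = 0.3, baseline_continuum = 0.6)
  expected <- 0.3 * (signature_spectrum(baseline_signature(), ax) + 0.6)
  gap <- as.vector(t(gap_mask(g, band_width = 1L)))
  for (p in which(!gap)[1:5])
    expect_equal(sc0$V[p, ], expected, tolerance = 1e-12)
  expect_true(all(sc0$V[gap, ] == 0))

  # noise-free center source: 1006 cm^-1 argmax is one of the 4 center pixels
  sc1 <- simulate_scan(list(center_bzd_source()),
                       noise = noise_model(0, 0, 1L, seed = 1L))
  ch <- which(sc1$axis$values == 1006)
  k <- which.max(sc1$V[, ch]) - 1L
  pos <- grid_position(k, sc1$geometry)
  expect_true(pos$row %in% 17:18 && pos$col %in% 17:18)
})

test_that("simulated scans are non-negative, reproducible, and rarely clipped", {
  sc_a <- simulate_scan(list(center_bzd_source()),
                        noise = noise_model(seed = 11L))
  sc_b <- simulate_scan(list(center_bzd_source()),
                        noise = noise_model(seed = 11L))
  expect_identical(sc_a$V, sc_b$V)
  expect_true(all(sc_a$V >= 0))
  expect_lt(sc_a$metadata$clipped_fraction, 0.01)
})

test_that("simulate_feature_dataset honors class counts and its seed", {
  ds <- simulate_feature_dataset(c(68L, 21L, 13L), seed = 5L)
  expect_equal(nrow(ds$spectra), 102L)
  expect_equal(as.vector(table(factor(ds$labels, levels = 0:2))),
               c(68L, 21L, 13L))
  te <- simulate_feature_dataset(c(28L, 14L, 14L), seed = 6L)
  expect_equal(nrow(te$spectra), 56L)
  expect_equal(as.vector(table(factor(te$labels, levels = 0:2))),
               c(28L, 14L, 14L))
  ds2 <- simulate_feature_dataset(c(68L, 21L, 13L), seed = 5L)
  expect_identical(ds$spectra, ds2$spectra)
  expect_identical(ds$labels, ds2$labels)
  expect_true(all(ds$spectra >= 0))
  expect_error(simulate_feature_dataset(c(0L, 0L, 0L)), "positive")
})
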