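test_that("smooth_map is identity at sigma 0 and conserves mass before renormalization", {
  g <- grid_geometry()
  mp <- reshape_map(plume_field(center_bzd_source(), g), g)
  expect_identical(smooth_map(mp, 0), mp)
  x <- mp$values
  blurred <- sersmap:::gaussian_blur(x, 1.5)
  expect_equal(sum(blurred), sum(x), tolerance = 1e-6)
  # single-pixel spike: center reduced, 8-neighborhood raised
  sp <- matrix(0, 9, 9); sp[5, 5] <- 1
  b <- sersmap:::gaussian_blur(sp, 1)
  expect_lt(b[5, 5], 1)
  expect_true(all(b[4:6, 4:6][-5] > 0))
  expect_error(smooth_map(mp, -1), ">= 0")
})

test_that("find_peaks seeds at local maxima with separation control", {
  g <- grid_geometry()
  mp1 <- reshape_map(plume_field(center_bzd_source(), g), g)
  pk1 <- find_peaks(mp1, 3L)
  expect_equal(nrow(pk1), 1L)                      # suppression leaves one
  expect_true(pk1[1, "row"] %in% 17:18 && pk1[1, "col"] %in% 17:18)
  two <- plume_field(source_spec("BZD", c(3.3, 11.7), 1.3), g) +
         plume_field(source_spec("BZD", c(11.7, 3.3), 1.3), g)
  pk2 <- find_peaks(reshape_map(two, g), 2L)
  expect_equal(nrow(pk2), 2L)
  got <- pk2[order(pk2[, "row"]), ]
  expect_lte(max(abs(got[1, c("row", "col")] - c(7, 27))), 1)  # within 1 px
  expect_lte(max(abs(got[2, c("row", "col")] - c(27, 7))), 1)
  flat <- concentration_map(matrix(0, 36, 36), g, normalize = FALSE)
  expect_warning(pk0 <- find_peaks(flat, 1L), "no strict local maxima")
  expect_equal(nrow(pk0), 0L)
})

test_that("fitting the Gaussian model to its own noiseless output recovers the parameters", {
  g <- grid_geometry()
  mp <- concentration_map(plume_field(source_spec("BZD", c(7.5, 7.5), 2), g),
                          g)
  f <- fit_gaussians(mp, 1L)[[1]]
  expect_lt(abs(f$sigma_x_mm - 2) / 2, 0.01)
  expect_lt(abs(f$sigma_y_mm - 2) / 2, 0.01)
  expect_lt(abs(f$x0_mm - 7.5), g$pitch / 2)
  expect_lt(abs(f$y0_mm - 7.5), g$pitch / 2)
  expect_lt(abs(f$offset), 0.01)
  expect_error(fit_gaussians(concentration_map(matrix(1, 36, 36), g,
                                               normalize = FALSE), 1L),
               "constant")
})

test_that("parameter recovery survives 5% additive noise", {
  g <- grid_geometry()
  set.seed(42)
  clean <- plume_field(source_spec("BZD", c(7.5, 7.5), 2), g)
  noisy <- clean + matrix(rnorm(length(clean), 0, 0.05 * max(clean)), 36)
  mp <- reshape_map(as.vector(t(noisy)), g)
  f <- fit_gaussians(mp, 1L)[[1]]
  expect_lt(abs(f$x0_mm - 7.5), g$pitch)           # within one pixel
  expect_lt(abs(f$y0_mm - 7.5), g$pitch)
  expect_lt(abs(f$sigma_x_mm - 2) / 2, 0.10)
  expect_lt(abs(f$sigma_y_mm - 2) / 2, 0.10)
})

test_that("two well-separated sources are localized jointly", {
  g <- grid_geometry()
  two <- plume_field(source_spec("BZD", c(3.3, 11.7), 1.6), g) +
         plume_field(source_spec("BZD", c(11.7, 3.3), 1.6), g)
  fits <- fit_gaussians(concentration_map(two, g), 2L)
  expect_length(fits, 2L)
  ctrs <- t(sapply(fits, function(f) c(f$x0_mm, f$y0_mm)))
  ctrs <- ctrs[order(ctrs[, 1]), ]
  expect_lt(max(abs(ctrs[1, ] - c(3.3, 11.7))), g$pitch)
  expect_lt(max(abs(ctrs[2, ] - c(11.7, 3.3))), g$pitch)
  # requesting more Gaussians than found peaks degrades gracefully
  one <- concentration_map(plume_field(center_bzd_source(), g), g)
  expect_warning(f1 <- fit_gaussians(one, 2L), "only 1 peak")
  expect_length(f1, 1L)
})

test_that("fitted_diameter is the sigma average, symmetric and recovered by fits", {
  mk <- function(sx, sy) structure(list(amplitude = 1, x0_mm = 0, y0_mm = 0,
                                        sigma_x_mm = sx, sigma_y_mm = sy,
                                        offset = 0, residual_norm = 0,
                                        converged = TRUE), class = "plume_fit")
  expect_equal(fitted_diameter(mk(2, 2)), 2)
  expect_equal(fitted_diameter(mk(1, 3)), 2)
  expect_equal(fitted_diameter(mk(3, 1)), fitted_diameter(mk(1, 3)))
  g <- grid_geometry()
  mp <- concentration_map(plume_field(source_spec("BZD", c(7.5, 7.5), 1.5),
                                      g), g)
  f <- fit_gaussians(mp, 1L)[[1]]
  expect_lt(abs(fitted_diameter(f) - 1.5), 0.015)
})

test_that("calibrate_size performs ordinary least squares with R^2", {
  d <- c(1, 2, 3, 4)
  cal <- calibrate_size(data.frame(actual = d, fitted = 0.5 * d))
  expect_equal(cal$slope, 0.5, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1)
  cal2 <- calibrate_size(data.frame(actual = c(1, 2, 3),
                                    fitted = c(1, 3, 2)))
  expect_equal(cal2$r_squared, 0.25, tolerance = 1e-12)  # hand OLS
  # R^2 invariant under affine rescaling of the actual axis
  cal3 <- calibrate_size(data.frame(actual = 10 + 2 * c(1, 2, 3),
                                    fitted = c(1, 3, 2)))
  expect_equal(cal3$r_squared, cal2$r_squared, tolerance = 1e-12)
  expect_error(calibrate_size(data.frame(actual = c(2, 2),
                                         fitted = c(1, 2))), "degenerate")
  expect_error(calibrate_size(data.frame(actual = 1, fitted = 1)),
               "at least 2")
})
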