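test_that("axis and geometry constructors enforce their invariants", {
  expect_error(wavenumber_axis(1000), "at least 2")
  expect_error(wavenumber_axis(c(1000, 1000)), "strictly increasing")
  expect_error(wavenumber_axis(c(1000, NA)), "finite")
  ax <- wavenumber_axis(c(600, 604, 608))
  expect_equal(length(ax), 3L)
  expect_equal(ax$resolution_hint, 4)

  expect_error(grid_geometry(0, 36), "at least one")
  expect_error(grid_geometry(36, 36, array_size = -1), "positive")
  g <- grid_geometry()
  expect_equal(g$n_points, 1296L)
  expect_equal(g$pitch, 15 / 36)
})

test_that("flat_index and grid_position are mutually inverse on the full 36x36 grid", {
  g <- grid_geometry()
  expect_identical(flat_index(0L, 0L, g), 0L)
  expect_identical(flat_index(1L, 0L, g), 36L)
  k <- 0:(g$n_points - 1L)
  pos <- grid_position(k, g)
  expect_identical(flat_index(pos$row, pos$col, g), k)
  # and the other direction on every (row, col)
  rc <- expand.grid(row = 0:35, col = 0:35)
  kk <- flat_index(rc$row, rc$col, g)
  pos2 <- grid_position(kk, g)
  expect_identical(pos2$row, rc$row)
  expect_identical(pos2$col, rc$col)
  expect_error(flat_index(36L, 0L, g), "out of range")
  expect_error(grid_position(1296L, g), "out of range")
})

test_that("pixel centers tile (0, array_size) and average to the array center", {
  g <- grid_geometry()
  p00 <- pixel_center_mm(0L, 0L, g)
  expect_equal(p00$x_mm, 0.5 * 15 / 36, tolerance = 1e-12)
  expect_equal(p00$y_mm, p00$x_mm)
  p35 <- pixel_center_mm(35L, 35L, g)
  expect_equal(p35$x_mm, 35.5 * 15 / 36, tolerance = 1e-12)
  # the two central diagonal pixels straddle the array center
  a <- pixel_center_mm(17L, 17L, g); b <- pixel_center_mm(18L, 18L, g)
  expect_true(a$x_mm < 7.5 && b$x_mm > 7.5)
  expect_equal((a$x_mm + b$x_mm) / 2, 7.5)
  rc <- expand.grid(row = 0:35, col = 0:35)
  ctr <- pixel_center_mm(rc$row, rc$col, g)
  expect_equal(mean(ctr$x_mm), 7.5)
  expect_equal(mean(ctr$y_mm), 7.5)
  expect_true(all(ctr$x_mm > 0 & ctr$x_mm < 15))
})

test_that("scan construction validates shapes and finiteness", {
  g <- tiny_geometry()
  ax <- wavenumber_axis(c(1000, 1004, 1008))
  expect_s3_class(hyperspectral_scan(matrix(1, 4, 3), g, ax),
                  "hyperspectral_scan")
  expect_error(hyperspectral_scan(matrix(1, 5, 3), g, ax), "grid points")
  expect_error(hyperspectral_scan(matrix(1, 4, 2), g, ax), "channels")
  bad <- matrix(1, 4, 3); bad[2, 2] <- NaN
  expect_error(hyperspectral_scan(bad, g, ax), "finite")
})

test_that("scan CSV round-trip is lossless to numeric precision", {
  sc <- simulate_scan(list(center_bzd_source()), noise = quiet_noise(),
                      geometry = grid_geometry(6L, 6L), axis = short_axis())
  path <- withr::local_tempfile(fileext = ".csv")
  write_scan(sc, path)
  back <- read_scan(path)           # geometry/axis from the sidecar
  expect_lt(max(abs(back$V - sc$V)), 1e-9)
  expect_equal(back$geometry$n_points, sc$geometry$n_points)
  expect_equal(back$axis$values, sc$axis$values)
  # explicit geometry/axis also accepted
  back2 <- read_scan(path, sc$geometry, sc$axis)
  expect_lt(max(abs(back2$V - sc$V)), 1e-9)
})

test_that("read_scan rejects malformed files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,2,3", "4,5,6", "7,8,9", "1,2,3", "4,5,6"), path)
  g <- tiny_geometry()
  ax <- wavenumber_axis(c(1000, 1004, 1008))
  expect_error(read_scan(path, g, ax), "grid points")   # 5 rows for 4 points
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,2,x", "4,5,6", "7,8,9", "1,2,3"), path2)
  expect_error(read_scan(path2, g, ax))
  # NaN entries are refused before writing
  sc <- hyperspectral_scan(matrix(1, 4, 3), g, ax)
  sc$V[1, 1] <- NaN
  expect_error(write_scan(sc, path), "finite")
})

test_that("datasets round-trip through CSV and length-307 spectra are padded", {
  ds <- simulate_feature_dataset(c(6L, 4L, 4L), seed = 3L,
                                 axis = make_axis(m = 308L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(back$spectra, ds$spectra, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_identical(back$labels, ds$labels)
  # one channel short: right-padded with the final value
  short <- labeled_spectrum_dataset(ds$spectra[, 1:307], ds$labels,
                                    pad_to = 308L)
  expect_equal(ncol(short$spectra), 308L)
  expect_equal(short$spectra[, 308], short$spectra[, 307])
  expect_error(labeled_spectrum_dataset(ds$spectra, c(ds$labels, 0L)),
               "one label per spectrum")
  expect_error(labeled_spectrum_dataset(ds$spectra,
                                        rep(3L, nrow(ds$spectra))),
               "\\{0, 1, 2\\}")
})
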