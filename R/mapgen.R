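#' Reshape a concentration column into a normalized map
#'
#' Reorganizes one column of the NMF concentration matrix `W` into the
#' `n_rows x n_cols` grid (row-major scan order, top-left origin) and min-max
#' normalizes it to `[0, 1]`; this grid is the heatmap visualizing the spatial
#' distribution of that component. Constant columns normalize to all zeros.
#'
#' @param w Numeric vector of length `n_rows * n_cols` in scan order.
#' @param geometry A [grid_geometry()].
#' @return A [concentration_map()].
#' @export
reshape_map <- function(w, geometry) {
  w <- as.numeric(w)
  if (length(w) != geometry$n_points)
    stop(sprintf("concentration column has length %d, geometry expects %d",
                 length(w), geometry$n_points), call. = FALSE)
  grid <- matrix(w, nrow = geometry$n_rows, ncol = geometry$n_cols,
                 byrow = TRUE)
  concentration_map(grid, geometry, normalize = TRUE)
}

#' Spectra along the main diagonal of a square scan
#'
#' Returns the spectra at grid positions (0,0), (1,1), ..., ordered from the
#' top-left to the bottom-right corner — the transect used to show how band
#' intensity varies with distance from the odor source.
#'
#' @param scan A [hyperspectral_scan()] with a square grid.
#' @return Matrix with `n_rows` rows (one spectrum per diagonal position).
#' @export
extract_diagonal <- function(scan) {
  stopifnot(inherits(scan, "hyperspectral_scan"))
  g <- scan$geometry
  if (g$n_rows != g$n_cols)
    stop("diagonal extraction requires a square grid", call. = FALSE)
  idx <- flat_index(seq_len(g$n_rows) - 1L, seq_len(g$n_cols) - 1L, g)
  scan$V[idx + 1L, , drop = FALSE]
}

#' Relative standard deviation of spot intensities
#'
#' `100 * sd(x) / mean(x)` (sample standard deviation) — the spot-to-spot
#' uniformity statistic used to qualify a sensor batch.
#'
#' @param values Numeric vector of peak intensities, length >= 2, nonzero mean.
#' @return RSD in percent.
#' @export
spot_rsd <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("RSD needs at least 2 values", call. = FALSE)
  mu <- mean(values)
  if (mu == 0) stop("RSD undefined for zero mean", call. = FALSE)
  100 * stats::sd(values) / mu
}

#' Overlay several concentration maps in color
#'
#' Renders each map in its own color and blends additively per pixel (RGB
#' channels clipped to `[0, 1]`), so two gases detected on one array can be
#' shown in a single image — e.g. a blue benzaldehyde spot and a yellow
#' 4-ethylbenzaldehyde spot, mixing where the plumes overlap.
#'
#' @param maps List of [concentration_map()] sharing one geometry.
#' @param colors Character vector of R color names/hex, one per map.
#' @return An object of class `overlay_image`: `geometry`, `layers`, and
#'   `rendered`, an `n_rows x n_cols x 3` RGB array in `[0, 1]`.
#' @export
overlay_maps <- function(maps, colors) {
  if (inherits(maps, "concentration_map")) maps <- list(maps)
  if (length(maps) < 1L) stop("need at least one map", call. = FALSE)
  if (length(colors) != length(maps))
    stop("need exactly one color per map", call. = FALSE)
  g <- maps[[1]]$geometry
  for (mp in maps)
    if (mp$geometry$n_rows != g$n_rows || mp$geometry$n_cols != g$n_cols)
      stop("all maps must share one geometry", call. = FALSE)
  rgb <- array(0, dim = c(g$n_rows, g$n_cols, 3L))
  for (i in seq_along(maps)) {
    col <- grDevices::col2rgb(colors[i])[, 1] / 255
    for (ch in 1:3)
      rgb[, , ch] <- rgb[, , ch] + maps[[i]]$values * col[ch]
  }
  rgb[rgb > 1] <- 1
  structure(list(geometry = g,
                 layers = Map(function(m, c) list(map = m, color = c),
                              maps, colors),
                 rendered = rgb),
            class = "overlay_image")
}

#' Write a concentration map or overlay as files
#'
#' `write_map()` writes the grid as headerless CSV (row 0 first, i.e. the top
#' of the array) and, optionally, a PNG render using a single-hue ramp.
#' `write_overlay_png()` writes the blended RGB raster of an
#' [overlay_maps()] result.
#'
#' @param map A [concentration_map()].
#' @param path Output CSV path.
#' @param png_path Optional PNG path.
#' @param color Ramp color for the PNG render (default `"red"`).
#' @param scale Integer pixel-replication factor for the PNG (default 8).
#' @return The CSV path, invisibly.
#' @export
write_map <- function(map, path, png_path = NULL, color = "red", scale = 8L) {
  stopifnot(inherits(map, "concentration_map"))
  data.table::fwrite(data.table::as.data.table(map$values), path,
                     col.names = FALSE, showProgress = FALSE)
  if (!is.null(png_path)) {
    col <- grDevices::col2rgb(color)[, 1] / 255
    rgb <- array(0, dim = c(dim(map$values), 3L))
    for (ch in 1:3) rgb[, , ch] <- map$values * col[ch]
    png::writePNG(upscale_raster(rgb, scale), png_path)
  }
  invisible(path)
}

#' @rdname write_map
#' @param overlay An [overlay_maps()] result.
#' @export
write_overlay_png <- function(overlay, png_path, scale = 8L) {
  stopifnot(inherits(overlay, "overlay_image"))
  png::writePNG(upscale_raster(overlay$rendered, scale), png_path)
  invisible(png_path)
}

upscale_raster <- function(rgb, scale) {
  scale <- max(1L, as.integer(scale))
  if (scale == 1L) return(rgb)
  ri <- rep(seq_len(dim(rgb)[1]), each = scale)
  ci <- rep(seq_len(dim(rgb)[2]), each = scale)
  rgb[ri, ci, , drop = FALSE]
}
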