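#' Wavenumber axis of a Raman spectrometer
#'
#' Constructs the spectral coordinate of a scan: an ordered vector of Raman
#' shifts in reciprocal centimetres. The axis must be strictly increasing,
#' finite, and hold at least two channels.
#'
#' @param values Numeric vector of Raman shifts (cm^-1), strictly increasing.
#' @param resolution_hint Nominal channel spacing in cm^-1. Defaults to the
#'   median spacing of `values`.
#' @return An object of class `wavenumber_axis`.
#' @seealso [make_axis()] for building a uniform axis from start/step/length.
#' @export
wavenumber_axis <- function(values, resolution_hint = NULL) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a wavenumber axis needs at least 2 channels", call. = FALSE)
  if (!all(is.finite(values)))
    stop("wavenumber axis values must all be finite", call. = FALSE)
  if (any(diff(values) <= 0))
    stop("wavenumber axis values must be strictly increasing", call. = FALSE)
  if (is.null(resolution_hint)) resolution_hint <- stats::median(diff(values))
  structure(list(values = values, resolution_hint = resolution_hint),
            class = "wavenumber_axis")
}

#' @export
length.wavenumber_axis <- function(x) length(x$values)

#' @export
print.wavenumber_axis <- function(x, ...) {
  cat(sprintf("<wavenumber_axis> %d channels, %.6g .. %.6g cm^-1 (step ~%.3g)\n",
              length(x$values), x$values[1], x$values[length(x$values)],
              x$resolution_hint))
  invisible(x)
}

#' Grid geometry of a 2D sensor-array scan
#'
#' Describes the scanning raster over the sensor array: point counts, physical
#' edge length and the derived pixel pitch. Scan order is row-major from the
#' top-left corner (the direction the array is rastered); row/column indices
#' throughout the package are 0-based so that `flat_index(r, c) = r * n_cols + c`
#' matches the position of a spectrum in the scan matrix.
#'
#' @param n_rows,n_cols Number of scan points per side (default 36 x 36).
#' @param array_size Physical edge length of the (square) array in mm
#'   (default 15).
#' @return An object of class `grid_geometry` with fields `n_rows`, `n_cols`,
#'   `array_size`, `pitch` (mm per pixel) and `n_points`.
#' @export
grid_geometry <- function(n_rows = 36L, n_cols = 36L, array_size = 15) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L)
    stop("grid must have at least one row and one column", call. = FALSE)
  if (!is.finite(array_size) || array_size <= 0)
    stop("array_size must be a positive length in mm", call. = FALSE)
  structure(list(n_rows = n_rows, n_cols = n_cols, array_size = array_size,
                 pitch = array_size / n_cols, n_points = n_rows * n_cols),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %d x %d points over %g x %g mm (pitch %.4g mm)\n",
              x$n_rows, x$n_cols, x$array_size, x$array_size, x$pitch))
  invisible(x)
}

#' Hyperspectral scan of a sensor array
#'
#' Bundles the intensity matrix `V` (one row per scan point in scan order, one
#' column per wavenumber channel) with its grid geometry and wavenumber axis.
#' All entries must be finite; row and column counts must match the geometry
#' and axis.
#'
#' @param V Numeric matrix, `n_rows * n_cols` rows by `length(axis)` columns.
#' @param geometry A [grid_geometry()].
#' @param axis A [wavenumber_axis()].
#' @param metadata Optional named list of free-form provenance.
#' @return An object of class `hyperspectral_scan`.
#' @export
hyperspectral_scan <- function(V, geometry, axis, metadata = list()) {
  V <- as.matrix(V)
  storage.mode(V) <- "double"
  if (nrow(V) != geometry$n_points)
    stop(sprintf("scan has %d spectra but geometry declares %d grid points",
                 nrow(V), geometry$n_points), call. = FALSE)
  if (ncol(V) != length(axis))
    stop(sprintf("scan has %d channels but axis has %d", ncol(V), length(axis)),
         call. = FALSE)
  if (!all(is.finite(V)))
    stop("scan intensities must all be finite", call. = FALSE)
  structure(list(V = V, geometry = geometry, axis = axis, metadata = metadata),
            class = "hyperspectral_scan")
}

#' @export
print.hyperspectral_scan <- function(x, ...) {
  cat(sprintf("<hyperspectral_scan> V %d x %d (%d x %d grid, %d channels)\n",
              nrow(x$V), ncol(x$V), x$geometry$n_rows, x$geometry$n_cols,
              length(x$axis)))
  invisible(x)
}

#' Normalized per-component concentration map
#'
#' A `n_rows x n_cols` grid of component weights rescaled to `[0, 1]`
#' (min-max). Constant input normalizes to all zeros rather than NaN.
#'
#' @param values Numeric matrix matching the geometry, or values already in
#'   `[0, 1]`.
#' @param geometry A [grid_geometry()].
#' @param normalize Min-max rescale the values (default `TRUE`).
#' @return An object of class `concentration_map`.
#' @export
concentration_map <- function(values, geometry, normalize = TRUE) {
  values <- as.matrix(values)
  if (nrow(values) != geometry$n_rows || ncol(values) != geometry$n_cols)
    stop("map shape does not match geometry", call. = FALSE)
  if (!all(is.finite(values)))
    stop("map values must be finite", call. = FALSE)
  if (normalize) values <- minmax01(values)
  if (min(values) < 0 || max(values) > 1)
    stop("map values must lie in [0, 1]; use normalize = TRUE", call. = FALSE)
  structure(list(values = values, geometry = geometry),
            class = "concentration_map")
}

# min-max to [0,1]; zero-range input collapses to all zeros (degenerate but safe)
minmax01 <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) return(array(0, dim = dim(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Labeled feature-spectrum dataset
#'
#' Fixed-length feature spectra (rows) with integer class labels:
#' 0 = interference (baseline/noise), 1 = benzaldehyde (BZD),
#' 2 = 4-ethylbenzaldehyde (EBZD). Spectra one channel short of
#' `pad_to` are right-padded with their last value (a known off-by-one
#' between dataset exports and the scan matrix).
#'
#' @param spectra Numeric matrix, one spectrum per row.
#' @param labels Integer vector in `{0, 1, 2}`, one per spectrum.
#' @param split_tag Optional tag such as `"train"`, `"valid"` or `"test"`.
#' @param pad_to If spectra are exactly one channel shorter, right-pad with the
#'   last value to this length (default `NULL`: no padding).
#' @return An object of class `labeled_spectrum_dataset`.
#' @export
labeled_spectrum_dataset <- function(spectra, labels, split_tag = NULL,
                                     pad_to = NULL) {
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  labels <- as.integer(labels)
  if (!is.null(pad_to) && ncol(spectra) == pad_to - 1L)
    spectra <- cbind(spectra, spectra[, ncol(spectra)])
  if (nrow(spectra) != length(labels))
    stop("need exactly one label per spectrum", call. = FALSE)
  if (!all(labels %in% 0:2))
    stop("labels must be in {0, 1, 2}", call. = FALSE)
  if (!all(is.finite(spectra)))
    stop("spectra must be finite", call. = FALSE)
  structure(list(spectra = spectra, labels = labels, split_tag = split_tag),
            class = "labeled_spectrum_dataset")
}

#' @export
print.labeled_spectrum_dataset <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:2))
  cat(sprintf("<labeled_spectrum_dataset>%s %d spectra x %d channels (0:%d 1:%d 2:%d)\n",
              if (is.null(x$split_tag)) "" else paste0(" [", x$split_tag, "]"),
              nrow(x$spectra), ncol(x$spectra), tab[1], tab[2], tab[3]))
  invisible(x)
}

## ---- scan order / coordinates ------------------------------------------

#' Row-major flat index of a grid point
#'
#' Maps a 0-based (row, col) grid position to its 0-based position in the scan
#' matrix. The array is rastered row-major from the top-left corner, so
#' `flat_index(r, c) = r * n_cols + c`.
#'
#' @param row,col 0-based indices (vectors allowed).
#' @param geometry A [grid_geometry()].
#' @return Integer 0-based flat index.
#' @export
flat_index <- function(row, col, geometry) {
  if (any(row < 0L) || any(row >= geometry$n_rows) ||
      any(col < 0L) || any(col >= geometry$n_cols))
    stop("grid index out of range", call. = FALSE)
  as.integer(row) * geometry$n_cols + as.integer(col)
}

#' Inverse of [flat_index()]
#'
#' @param k 0-based flat index (vector allowed).
#' @param geometry A [grid_geometry()].
#' @return A list with integer vectors `row` and `col` (0-based).
#' @export
grid_position <- function(k, geometry) {
  k <- as.integer(k)
  if (any(k < 0L) || any(k >= geometry$n_points))
    stop("flat index out of range", call. = FALSE)
  list(row = k %/% geometry$n_cols, col = k %% geometry$n_cols)
}

#' Physical pixel-center coordinates in mm
#'
#' x increases rightward and y downward from the array's top-left corner;
#' positions are the centers of the square pixels, so
#' `x = (col + 0.5) * pitch`, `y = (row + 0.5) * pitch`.
#'
#' @param row,col 0-based indices (vectors allowed).
#' @param geometry A [grid_geometry()].
#' @return A list with numeric vectors `x_mm` and `y_mm`.
#' @export
pixel_center_mm <- function(row, col, geometry) {
  if (any(row < 0L) || any(row >= geometry$n_rows) ||
      any(col < 0L) || any(col >= geometry$n_cols))
    stop("grid index out of range", call. = FALSE)
  list(x_mm = (col + 0.5) * geometry$pitch, y_mm = (row + 0.5) * geometry$pitch)
}

## ---- file IO ------------------------------------------------------------

#' Read a hyperspectral scan from CSV
#'
#' The matrix body is headerless CSV: one row per grid point in scan order, one
#' column per wavenumber channel. Geometry and axis come either from the
#' arguments or from a `<path>.meta` key-value sidecar written by
#' [write_scan()].
#'
#' @param path CSV file.
#' @param geometry,axis Optional; read from the sidecar when omitted.
#' @return A validated [hyperspectral_scan()].
#' @export
read_scan <- function(path, geometry = NULL, axis = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = FALSE, data.table = FALSE,
                          showProgress = FALSE)
  if (!all(vapply(dt, is.numeric, logical(1))))
    stop("non-numeric cell in scan file: ", path, call. = FALSE)
  V <- as.matrix(dt)
  meta <- list()
  side <- paste0(path, ".meta")
  if ((is.null(geometry) || is.null(axis)) && file.exists(side)) {
    kv <- read_keyvalue(side)
    if (is.null(geometry))
      geometry <- grid_geometry(as.integer(kv$n_rows), as.integer(kv$n_cols),
                                as.numeric(kv$array_size))
    if (is.null(axis))
      axis <- wavenumber_axis(as.numeric(strsplit(kv$axis_values, ",")[[1]]))
    meta <- kv[grep("^meta\\.", names(kv))]
    names(meta) <- sub("^meta\\.", "", names(meta))
  }
  if (is.null(geometry) || is.null(axis))
    stop("geometry and axis must be supplied or present in a .meta sidecar",
         call. = FALSE)
  hyperspectral_scan(V, geometry, axis, metadata = meta)
}

#' Write a hyperspectral scan to CSV
#'
#' Writes the headerless matrix body to `path` and a `<path>.meta` key-value
#' sidecar holding the geometry, the axis and any scalar metadata, so that
#' `read_scan(path)` round-trips the scan.
#'
#' @param scan A [hyperspectral_scan()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "hyperspectral_scan"))
  if (!all(is.finite(scan$V)))
    stop("scan intensities must be finite before writing", call. = FALSE)
  data.table::fwrite(data.table::as.data.table(scan$V), path,
                     col.names = FALSE, showProgress = FALSE)
  kv <- list(n_rows = scan$geometry$n_rows, n_cols = scan$geometry$n_cols,
             array_size = scan$geometry$array_size,
             axis_values = paste(format(scan$axis$values, digits = 15,
                                        trim = TRUE, scientific = FALSE),
                                 collapse = ","))
  md <- scan$metadata
  md <- md[vapply(md, function(v) is.atomic(v) && length(v) == 1L, logical(1))]
  if (length(md)) {
    names(md) <- paste0("meta.", names(md))
    kv <- c(kv, md)
  }
  write_keyvalue(kv, paste0(path, ".meta"))
  invisible(path)
}

#' Read / write a labeled spectrum dataset as CSV
#'
#' Headerless CSV with one spectrum per row and the integer class label in the
#' final column.
#'
#' @param path CSV file.
#' @param split_tag Optional tag stored on the loaded dataset.
#' @param pad_to Passed to [labeled_spectrum_dataset()] (default 308).
#' @return A [labeled_spectrum_dataset()].
#' @export
read_dataset <- function(path, split_tag = NULL, pad_to = 308L) {
  dt <- data.table::fread(path, header = FALSE, data.table = FALSE,
                          showProgress = FALSE)
  m <- ncol(dt)
  labeled_spectrum_dataset(as.matrix(dt[, -m, drop = FALSE]), dt[[m]],
                           split_tag = split_tag, pad_to = pad_to)
}

#' @rdname read_dataset
#' @param dataset A [labeled_spectrum_dataset()].
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "labeled_spectrum_dataset"))
  data.table::fwrite(
    data.table::as.data.table(cbind(dataset$spectra, dataset$labels)),
    path, col.names = FALSE, showProgress = FALSE)
  invisible(path)
}

## simple `key=value` config files (one pair per line, '#' comments)
read_keyvalue <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0)) stop("malformed key=value line in ", path, call. = FALSE)
  out <- as.list(trimws(substring(lines, eq + 1L)))
  names(out) <- trimws(substring(lines, 1L, eq - 1L))
  out
}

write_keyvalue <- function(kv, path) {
  writeLines(paste0(names(kv), "=", vapply(kv, as.character, character(1))),
             path)
  invisible(path)
}
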