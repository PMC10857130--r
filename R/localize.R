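#' Gaussian smoothing of a concentration map
#'
#' Separable Gaussian blur with reflective (mirror) boundary handling, which
#' conserves total intensity exactly for the symmetric kernel; the result is
#' re-normalized to `[0, 1]`. `sigma_px = 0` returns the map unchanged. The
#' blur width is a visualization/seeding aid — the Gaussian plume fit itself
#' runs on the unsmoothed map.
#'
#' @param map A [concentration_map()].
#' @param sigma_px Blur standard deviation in pixels, >= 0.
#' @return A smoothed [concentration_map()].
#' @export
smooth_map <- function(map, sigma_px) {
  stopifnot(inherits(map, "concentration_map"))
  if (sigma_px < 0) stop("smoothing sigma must be >= 0", call. = FALSE)
  if (sigma_px == 0) return(map)
  concentration_map(gaussian_blur(map$values, sigma_px), map$geometry,
                    normalize = TRUE)
}

# separable Gaussian convolution with mirror padding; conserves sum(x)
gaussian_blur <- function(x, sigma) {
  rad <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-rad:rad, sd = sigma)
  k <- k / sum(k)
  blur1d <- function(v) {
    n <- length(v)
    pad <- c(v[rad:1], v, v[n:(n - rad + 1L)])   # mirror both ends
    out <- numeric(n)
    for (j in seq_along(k)) out <- out + k[j] * pad[(j - 1L) + seq_len(n)]
    out
  }
  x <- apply(x, 2L, blur1d)
  t(apply(x, 1L, blur1d))
}

#' Seed positions from local maxima of a map
#'
#' Finds pixels that are greater than or equal to all of their 8 neighbors and
#' strictly greater than at least one, sorts them by height and greedily
#' suppresses maxima closer than `min_separation_px` (Chebyshev distance) to
#' an already accepted seed. A constant map yields no seeds (with a warning).
#'
#' @param map A [concentration_map()].
#' @param k Maximum number of seeds to return, >= 1.
#' @param min_separation_px Minimum seed separation in pixels (default 6).
#' @return Integer matrix with columns `row`, `col` (0-based) and `value`;
#'   up to `k` rows.
#' @export
find_peaks <- function(map, k, min_separation_px = 6L) {
  stopifnot(inherits(map, "concentration_map"))
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  v <- map$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr * nc == 0L) stop("empty map", call. = FALSE)
  cand <- matrix(numeric(0), 0L, 3L,
                 dimnames = list(NULL, c("row", "col", "value")))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- max(1L, i - 1L):min(nr, i + 1L)
    cj <- max(1L, j - 1L):min(nc, j + 1L)
    nb <- v[ri, cj]
    nb <- nb[-(which(ri == i) + (which(cj == j) - 1L) * length(ri))]
    if (all(v[i, j] >= nb) && any(v[i, j] > nb))
      cand <- rbind(cand, c(i - 1L, j - 1L, v[i, j]))
  }
  if (nrow(cand) == 0L) {
    warning("no strict local maxima found (constant map?)")
    return(cand)
  }
  cand <- cand[order(-cand[, "value"], cand[, "row"], cand[, "col"]),
               , drop = FALSE]
  keep <- matrix(numeric(0), 0L, 3L, dimnames = dimnames(cand))
  for (i in seq_len(nrow(cand))) {
    if (nrow(keep) >= k) break
    if (nrow(keep) == 0L ||
        all(pmax(abs(keep[, "row"] - cand[i, "row"]),
                 abs(keep[, "col"] - cand[i, "col"])) >= min_separation_px))
      keep <- rbind(keep, cand[i, ])
  }
  keep
}

#' Fit a sum of elliptical 2D Gaussians to a concentration map
#'
#' Least-squares fit (Levenberg–Marquardt with box bounds) of
#' \deqn{F(x, y) = \mathrm{offset} + \sum_{i=1}^{k} A_i
#'   \exp\!\left(-\frac{(x - x_{0i})^2}{2\sigma_{xi}^2}
#'               -\frac{(y - y_{0i})^2}{2\sigma_{yi}^2}\right)}
#' in mm pixel-center coordinates. Initial centers come from [find_peaks()] on
#' a lightly smoothed copy of the map (or from `seeds`); initial widths from
#' local intensity-weighted second moments. Widths are bounded to
#' `[pitch/2, array_size]` and centers may overshoot the array edge by one
#' pitch. If the optimizer reports failure the fit restarts from jittered
#' initial values a bounded number of times, keeping the best attempt.
#'
#' @param map A [concentration_map()].
#' @param k Number of Gaussians, 1 to 3.
#' @param seeds Optional integer matrix of 0-based `(row, col)` seed
#'   positions (as returned by [find_peaks()]).
#' @param smooth_sigma_px Blur width used only for peak seeding (default 1).
#' @param max_restarts Jittered restarts after a failed fit (default 4).
#' @return List of `k` (or fewer, with a warning, if fewer peaks are found)
#'   `plume_fit` objects: `amplitude`, `x0_mm`, `y0_mm`, `sigma_x_mm`,
#'   `sigma_y_mm`, `offset`, `residual_norm`, `converged`.
#' @export
fit_gaussians <- function(map, k = 1L, seeds = NULL, smooth_sigma_px = 1,
                          max_restarts = 4L) {
  stopifnot(inherits(map, "concentration_map"))
  k <- as.integer(k)
  if (k < 1L || k > 3L) stop("k must be between 1 and 3", call. = FALSE)
  g <- map$geometry
  v <- map$values
  if (max(v) == min(v))
    stop("cannot fit a constant map", call. = FALSE)

  if (is.null(seeds)) {
    sm <- smooth_map(map, smooth_sigma_px)
    seeds <- find_peaks(sm, k)
  }
  seeds <- as.matrix(seeds)
  if (nrow(seeds) == 0L)
    stop("no peaks found to seed the fit", call. = FALSE)
  if (nrow(seeds) < k) {
    warning(sprintf("only %d peak(s) found; fitting %d Gaussian(s)",
                    nrow(seeds), nrow(seeds)))
    k <- nrow(seeds)
  }
  seeds <- seeds[seq_len(k), , drop = FALSE]

  xc <- (seq_len(g$n_cols) - 0.5) * g$pitch
  yc <- (seq_len(g$n_rows) - 0.5) * g$pitch
  X <- matrix(xc, g$n_rows, g$n_cols, byrow = TRUE)
  Y <- matrix(yc, g$n_rows, g$n_cols)

  offset0 <- stats::quantile(v, 0.1, names = FALSE)
  # intensity-weighted local moments around each seed (nearest-seed partition)
  seed_x <- (seeds[, "col"] + 0.5) * g$pitch
  seed_y <- (seeds[, "row"] + 0.5) * g$pitch
  d2 <- array(0, dim = c(g$n_rows, g$n_cols, k))
  for (i in seq_len(k))
    d2[, , i] <- (X - seed_x[i])^2 + (Y - seed_y[i])^2
  owner <- apply(d2, c(1, 2), which.min)
  p0 <- offset0
  lower <- -1; upper <- 2
  for (i in seq_len(k)) {
    wts <- pmax(v - offset0, 0) * (owner == i)
    sw <- sum(wts)
    sx <- if (sw > 0) sqrt(sum(wts * (X - seed_x[i])^2) / sw) else g$pitch * 3
    sy <- if (sw > 0) sqrt(sum(wts * (Y - seed_y[i])^2) / sw) else g$pitch * 3
    s_lo <- g$pitch / 2; s_hi <- g$array_size
    A0 <- max(v[seeds[i, "row"] + 1L, seeds[i, "col"] + 1L] - offset0, 0.05)
    p0 <- c(p0, A0, seed_x[i], seed_y[i],
            min(max(sx, s_lo), s_hi), min(max(sy, s_lo), s_hi))
    lower <- c(lower, 1e-6, -g$pitch, -g$pitch, s_lo, s_lo)
    upper <- c(upper, 2, g$array_size + g$pitch, g$array_size + g$pitch,
               s_hi, s_hi)
  }

  model <- function(p) {
    f <- matrix(p[1], g$n_rows, g$n_cols)
    for (i in seq_len(k)) {
      q <- p[2 + (i - 1) * 5 + 0:4]   # A, x0, y0, sx, sy
      f <- f + q[1] * exp(-((X - q[2])^2 / (2 * q[4]^2) +
                            (Y - q[3])^2 / (2 * q[5]^2)))
    }
    f
  }
  resid_fn <- function(p) as.vector(v - model(p))

  best <- NULL
  for (attempt in 0:max_restarts) {
    # deterministic multiplicative jitter on restarts; leaves the RNG untouched
    start <- if (attempt == 0) p0 else
      pmin(pmax(p0 * (1 + 0.1 * sin(2.3 * attempt * seq_along(p0))), lower),
           upper)
    fit <- try(minpack.lm::nls.lm(
      par = start, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 400)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    ok <- fit$info %in% 1:4
    rn <- sqrt(sum(fit$fvec^2))
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn, ok = ok)
    if (ok) break
  }
  if (is.null(best))
    stop("Gaussian fit failed on all attempts", call. = FALSE)
  if (!best$ok)
    warning("Gaussian fit did not fully converge; returning best attempt")

  p <- best$fit$par
  fits <- vector("list", k)
  for (i in seq_len(k)) {
    q <- p[2 + (i - 1) * 5 + 0:4]
    fits[[i]] <- structure(
      list(amplitude = q[1], x0_mm = q[2], y0_mm = q[3],
           sigma_x_mm = q[4], sigma_y_mm = q[5], offset = p[1],
           residual_norm = best$rn, converged = best$ok),
      class = "plume_fit")
  }
  fits
}

#' @export
print.plume_fit <- function(x, ...) {
  cat(sprintf(
    "<plume_fit> center (%.3f, %.3f) mm, sigma (%.3f, %.3f) mm, A %.3f, offset %.3f\n",
    x$x0_mm, x$y0_mm, x$sigma_x_mm, x$sigma_y_mm, x$amplitude, x$offset))
  invisible(x)
}

#' Fitted diameter of an odor source
#'
#' The source-size statistic `(sigma_x + sigma_y) / 2` in mm, calibrated
#' against the actual source diameter by [calibrate_size()].
#'
#' @param fit A `plume_fit` from [fit_gaussians()].
#' @return Fitted diameter in mm.
#' @export
fitted_diameter <- function(fit) {
  stopifnot(inherits(fit, "plume_fit"))
  (fit$sigma_x_mm + fit$sigma_y_mm) / 2
}

#' Linear calibration of fitted against actual source diameters
#'
#' Ordinary least squares of `fitted = slope * actual + intercept`, with the
#' coefficient of determination `R^2 = 1 - SS_res / SS_tot`.
#'
#' @param pairs Two-column data frame or matrix: `actual` (mm), `fitted` (mm);
#'   at least 2 pairs, actuals not all equal.
#' @return An object of class `size_calibration`: `pairs`, `slope`,
#'   `intercept`, `r_squared`, and the underlying `stats::lm` fit.
#' @export
calibrate_size <- function(pairs) {
  pairs <- as.data.frame(pairs)
  names(pairs)[1:2] <- c("actual", "fitted")
  if (nrow(pairs) < 2L)
    stop("calibration needs at least 2 diameter pairs", call. = FALSE)
  if (stats::var(pairs$actual) == 0)
    stop("actual diameters are all equal; regression is degenerate",
         call. = FALSE)
  fit <- stats::lm(fitted ~ actual, data = pairs)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((pairs$fitted - mean(pairs$fitted))^2)
  structure(list(pairs = pairs,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 lm = fit),
            class = "size_calibration")
}

#' @export
print.size_calibration <- function(x, ...) {
  cat(sprintf("<size_calibration> fitted = %.4f * actual + %.4f, R^2 = %.4f (%d pairs)\n",
              x$slope, x$intercept, x$r_squared, nrow(x$pairs)))
  invisible(x)
}
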