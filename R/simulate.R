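#' Gas signature: a Raman peak list
#'
#' A gas is described by its characteristic Raman bands: center (cm^-1), full
#' width at half maximum (cm^-1) and relative amplitude per peak. Band shapes
#' are rendered by [signature_spectrum()].
#'
#' @param name Gas identifier, e.g. `"BZD"`.
#' @param peaks Data frame (or matrix) with columns `center`, `fwhm`,
#'   `amplitude`; at least one peak, all `fwhm` and `amplitude` positive.
#' @return An object of class `gas_signature`.
#' @export
gas_signature <- function(name, peaks) {
  peaks <- as.data.frame(peaks)
  if (nrow(peaks) < 1L)
    stop("a gas signature needs at least one peak", call. = FALSE)
  if (!all(c("center", "fwhm", "amplitude") %in% names(peaks)))
    stop("peaks need columns center, fwhm, amplitude", call. = FALSE)
  if (any(peaks$fwhm <= 0) || any(peaks$amplitude <= 0))
    stop("peak fwhm and amplitude must be positive", call. = FALSE)
  structure(list(name = name, peaks = peaks), class = "gas_signature")
}

#' Built-in signatures for the benzaldehyde sensing problem
#'
#' Benzaldehyde (BZD) carries characteristic bands at 1006 and 1603 cm^-1;
#' 4-ethylbenzaldehyde (EBZD) a single distinct band at 1614 cm^-1. The sensor
#' baseline (residual synthesis agents on the silver nanoparticles) shows bands
#' near 900, 1050 and 1400 cm^-1.
#'
#' @return `default_signatures()`: a named list of [gas_signature()] objects
#'   for `"BZD"` and `"EBZD"`; `baseline_signature()`: the baseline signature.
#' @export
default_signatures <- function() {
  list(
    BZD = gas_signature("BZD", data.frame(
      center = c(1006, 1603), fwhm = c(20, 20), amplitude = c(1.0, 0.85))),
    EBZD = gas_signature("EBZD", data.frame(
      center = 1614, fwhm = 20, amplitude = 1.0)))
}

#' @rdname default_signatures
#' @export
baseline_signature <- function() {
  gas_signature("baseline", data.frame(
    center = c(900, 1050, 1400), fwhm = c(25, 25, 25),
    amplitude = c(1.0, 0.8, 0.9)))
}

#' Odor-source specification
#'
#' One odor source: which gas it emits, where it sits under the array (mm,
#' top-left origin), the widths of its Gaussian plume and its peak
#' concentration.
#'
#' @param gas Signature name (must exist in the signature set used downstream).
#' @param center Length-2 numeric `(x_mm, y_mm)`.
#' @param sigma Length-2 positive numeric `(sigma_x_mm, sigma_y_mm)` (a scalar
#'   is recycled).
#' @param strength Peak concentration in arbitrary units (>= 0, default 1).
#' @return An object of class `source_spec`.
#' @export
source_spec <- function(gas, center, sigma, strength = 1) {
  sigma <- rep(as.numeric(sigma), length.out = 2L)
  center <- as.numeric(center)
  if (length(center) != 2L) stop("center must be (x_mm, y_mm)", call. = FALSE)
  if (any(sigma <= 0)) stop("plume sigma must be positive", call. = FALSE)
  if (strength < 0) stop("strength must be >= 0", call. = FALSE)
  structure(list(gas = gas, center = center, sigma = sigma,
                 strength = strength), class = "source_spec")
}

#' Measurement-noise model for simulated scans
#'
#' @param additive_sd Additive white-noise standard deviation as a fraction of
#'   the maximum clean intensity (default 0.05).
#' @param multiplicative_sd Per-pixel lognormal spread of the adsorption
#'   efficiency (sdlog; default 0.05) — spot-to-spot enhancement randomness.
#' @param gap_band_width Width in pixels of the noise-only bands at internal
#'   sensor boundaries (default 1).
#' @param seed RNG seed making the simulated scan reproducible (default 42).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(additive_sd = 0.05, multiplicative_sd = 0.05,
                        gap_band_width = 1L, seed = 42L) {
  if (additive_sd < 0 || multiplicative_sd < 0)
    stop("noise standard deviations must be >= 0", call. = FALSE)
  if (gap_band_width < 0)
    stop("gap band width must be >= 0", call. = FALSE)
  structure(list(additive_sd = additive_sd,
                 multiplicative_sd = multiplicative_sd,
                 gap_band_width = as.integer(gap_band_width),
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Build a uniform wavenumber axis
#'
#' `values[k] = start + (k - 1) * step`. The default 308 channels at 4 cm^-1
#' from 602 cm^-1 span 602–1830 cm^-1, covering all bands used by the built-in
#' signatures.
#'
#' @param start First Raman shift (cm^-1).
#' @param step Channel spacing (cm^-1), > 0.
#' @param m Number of channels, >= 2.
#' @return A [wavenumber_axis()].
#' @export
make_axis <- function(start = 602, step = 4, m = 308L) {
  if (step <= 0) stop("axis step must be positive", call. = FALSE)
  if (m < 2L) stop("axis needs at least 2 channels", call. = FALSE)
  wavenumber_axis(start + step * (seq_len(m) - 1L), resolution_hint = step)
}

#' Render a gas signature on an axis
#'
#' Sums one line per peak evaluated at the axis channels. The default
#' Lorentzian lineshape is
#' `a / (1 + ((nu - c) / (fwhm/2))^2)`; a Gaussian lineshape with the same
#' FWHM parameterization is selectable.
#'
#' @param sig A [gas_signature()].
#' @param axis A [wavenumber_axis()].
#' @param lineshape `"lorentzian"` (default) or `"gaussian"`.
#' @return Non-negative numeric vector, one intensity per axis channel.
#' @export
signature_spectrum <- function(sig, axis,
                               lineshape = c("lorentzian", "gaussian")) {
  stopifnot(inherits(sig, "gas_signature"), inherits(axis, "wavenumber_axis"))
  lineshape <- match.arg(lineshape)
  nu <- axis$values
  s <- numeric(length(nu))
  for (i in seq_len(nrow(sig$peaks))) {
    p <- sig$peaks[i, ]
    hw <- p$fwhm / 2
    s <- s + if (lineshape == "lorentzian") {
      p$amplitude / (1 + ((nu - p$center) / hw)^2)
    } else {
      p$amplitude * exp(-4 * log(2) * ((nu - p$center) / p$fwhm)^2)
    }
  }
  s
}

#' Gaussian plume concentration field
#'
#' Concentration of gas evaporating from one source, evaluated at the pixel
#' centers of the array:
#' `G(x, y) = strength * exp(-((x - x0)^2 / (2 sigma_x^2) + (y - y0)^2 / (2 sigma_y^2)))`.
#'
#' @param source A [source_spec()].
#' @param geometry A [grid_geometry()].
#' @return `n_rows x n_cols` numeric matrix.
#' @export
plume_field <- function(source, geometry) {
  stopifnot(inherits(source, "source_spec"))
  xc <- (seq_len(geometry$n_cols) - 0.5) * geometry$pitch
  yc <- (seq_len(geometry$n_rows) - 0.5) * geometry$pitch
  gx <- exp(-(xc - source$center[1])^2 / (2 * source$sigma[1]^2))
  gy <- exp(-(yc - source$center[2])^2 / (2 * source$sigma[2]^2))
  source$strength * outer(gy, gx)
}

#' Mask of inter-sensor gap pixels
#'
#' The array is tiled from `sensors_per_side^2` individual sensor chips; scan
#' points falling on the slight gaps between chips see no enhancing surface
#' and record noise only. Bands of `band_width` pixels start at each internal
#' chip boundary (rows and columns 12 and 24 for the 36-point, 3-chip
#' defaults, 0-based).
#'
#' @param geometry A [grid_geometry()].
#' @param sensors_per_side Chips per side (default 3); must divide both point
#'   counts.
#' @param band_width Band width in pixels (default 1; 0 gives an empty mask).
#' @return `n_rows x n_cols` logical matrix, `TRUE` on gap pixels.
#' @export
gap_mask <- function(geometry, sensors_per_side = 3L, band_width = 1L) {
  if (geometry$n_cols %% sensors_per_side != 0L ||
      geometry$n_rows %% sensors_per_side != 0L)
    stop("grid size must be divisible by sensors_per_side", call. = FALSE)
  mask <- matrix(FALSE, geometry$n_rows, geometry$n_cols)
  if (band_width == 0L || sensors_per_side < 2L) return(mask)
  step_r <- geometry$n_rows %/% sensors_per_side
  step_c <- geometry$n_cols %/% sensors_per_side
  for (b in seq_len(sensors_per_side - 1L)) {
    rows <- b * step_r + seq_len(band_width)        # 1-based: boundary pixel first
    cols <- b * step_c + seq_len(band_width)
    mask[rows[rows <= geometry$n_rows], ] <- TRUE
    mask[, cols[cols <= geometry$n_cols]] <- TRUE
  }
  mask
}

#' Simulate a gas-adsorbed sensor-array scan
#'
#' Builds the scan matrix `V` from the generative model: for each non-gap
#' pixel `p`,
#' `V[p, ] = sum_g plume_g(p) * m_p * S_g + b * B + eps_p`,
#' where `S_g` is the gas signature spectrum, `m_p` a per-pixel lognormal
#' adsorption multiplier, `B` the baseline spectrum (Raman bands plus a flat
#' continuum, as on a real substrate) scaled by `baseline_strength`, and
#' `eps_p` additive white noise. Gap pixels carry noise-only (half-normal)
#' spectra. All intensities are clipped at zero; the clipped fraction is
#' recorded in the scan metadata, along with the ground-truth source
#' parameters for recovery tests.
#'
#' @param sources List of [source_spec()] (may be empty).
#' @param signatures Named list of [gas_signature()] covering every source gas.
#' @param baseline Baseline [gas_signature()].
#' @param noise A [noise_model()].
#' @param geometry A [grid_geometry()].
#' @param axis A [wavenumber_axis()].
#' @param baseline_strength Scale of the baseline contribution (default 0.3).
#' @param baseline_continuum Flat continuum amplitude added to the baseline
#'   band spectrum before scaling (default 0.6).
#' @param lineshape Passed to [signature_spectrum()].
#' @return A [hyperspectral_scan()]; `metadata$truth` holds the source
#'   parameters, `metadata$clipped_fraction` the fraction of entries clipped
#'   at zero.
#' @export
simulate_scan <- function(sources = list(),
                          signatures = default_signatures(),
                          baseline = baseline_signature(),
                          noise = noise_model(),
                          geometry = grid_geometry(),
                          axis = make_axis(),
                          baseline_strength = 0.3,
                          baseline_continuum = 0.6,
                          lineshape = "lorentzian") {
  if (inherits(sources, "source_spec")) sources <- list(sources)
  for (src in sources)
    if (is.null(signatures[[src$gas]]))
      stop("no signature defined for gas: ", src$gas, call. = FALSE)

  m <- length(axis)
  n <- geometry$n_points
  B <- signature_spectrum(baseline, axis, lineshape) + baseline_continuum
  base_term <- baseline_strength * B

  set.seed(noise$seed)
  clean <- matrix(rep(base_term, each = n), n, m)
  for (src in sources) {
    plume <- as.vector(t(plume_field(src, geometry)))   # row-major scan order
    S <- signature_spectrum(signatures[[src$gas]], axis, lineshape)
    mult <- stats::rlnorm(n, meanlog = 0, sdlog = noise$multiplicative_sd)
    clean <- clean + (plume * mult) %o% S
  }
  max_clean <- max(clean)
  V <- clean
  if (noise$additive_sd > 0)
    V <- V + matrix(stats::rnorm(n * m, 0, noise$additive_sd * max_clean), n, m)

  gap <- as.vector(t(gap_mask(geometry, band_width = noise$gap_band_width)))
  if (any(gap)) {
    sd_gap <- if (noise$additive_sd > 0) noise$additive_sd * max_clean else 0
    V[gap, ] <- abs(stats::rnorm(sum(gap) * m, 0, sd_gap))
  }
  clipped <- mean(V < 0)
  V[V < 0] <- 0

  truth <- lapply(sources, function(s)
    list(gas = s$gas, center = s$center, sigma = s$sigma,
         strength = s$strength))
  hyperspectral_scan(V, geometry, axis,
                     metadata = list(truth = truth, seed = noise$seed,
                                     clipped_fraction = clipped))
}

#' Simulate a labeled feature-spectrum dataset
#'
#' Emulates the feature spectra that the factorization stage extracts from
#' scans: class 1 spectra are jittered benzaldehyde signatures, class 2
#' jittered 4-ethylbenzaldehyde signatures, and class 0 (interference) spectra
#' are half baseline-like and half pure noise. Because factorization never
#' separates components perfectly, gas-class spectra additionally carry a
#' random fraction (up to `baseline_leak`) of the baseline spectrum, as the
#' components extracted from real scans do. Peak centers are jittered
#' uniformly within `peak_jitter` cm^-1 and amplitudes within a relative
#' `amp_jitter`; white noise of standard deviation `noise_sd` (relative to the
#' unit peak amplitude) is added throughout, and intensities are clipped at
#' zero.
#'
#' @param counts_per_class Integer triple `(n0, n1, n2)`; default the
#'   102-spectrum training composition `c(68, 21, 13)`.
#' @param peak_jitter Max absolute peak-center shift in cm^-1 (default 2).
#' @param amp_jitter Max relative amplitude jitter (default 0.15).
#' @param noise_sd Additive white-noise sd (default 0.02).
#' @param baseline_leak Max fraction of the baseline spectrum (bands plus
#'   continuum) leaking into gas-class spectra (default 0.3).
#' @param seed RNG seed (default 42).
#' @param axis A [wavenumber_axis()].
#' @param split_tag Stored on the result.
#' @param lineshape Passed to [signature_spectrum()].
#' @return A [labeled_spectrum_dataset()]; rows are shuffled (seeded).
#' @export
simulate_feature_dataset <- function(counts_per_class = c(68L, 21L, 13L),
                                     peak_jitter = 2, amp_jitter = 0.15,
                                     noise_sd = 0.02, baseline_leak = 0.3,
                                     seed = 42L,
                                     axis = make_axis(), split_tag = NULL,
                                     lineshape = "lorentzian") {
  counts_per_class <- as.integer(counts_per_class)
  if (length(counts_per_class) != 3L || any(counts_per_class < 0L))
    stop("counts_per_class must be three non-negative counts", call. = FALSE)
  if (sum(counts_per_class) == 0L)
    stop("at least one class count must be positive", call. = FALSE)

  set.seed(seed)
  m <- length(axis)
  sigs <- default_signatures()
  base <- baseline_signature()

  jittered <- function(sig) {
    pk <- sig$peaks
    pk$center <- pk$center + stats::runif(nrow(pk), -peak_jitter, peak_jitter)
    pk$amplitude <- pk$amplitude *
      (1 + stats::runif(nrow(pk), -amp_jitter, amp_jitter))
    signature_spectrum(gas_signature(sig$name, pk), axis, lineshape)
  }

  spectra <- list(); labels <- integer(0)
  n0 <- counts_per_class[1]
  n_base <- n0 %/% 2L                       # baseline-like half of class 0
  for (i in seq_len(n0)) {
    s <- if (i <= n_base) 0.8 * jittered(base) + 0.1
         else abs(stats::rnorm(m, 0, 0.15))  # pure-noise interference
    spectra[[length(spectra) + 1L]] <- s
    labels <- c(labels, 0L)
  }
  base_full <- signature_spectrum(base, axis, lineshape) + 0.6  # with continuum
  gas_example <- function(sig) {
    jittered(sig) + stats::runif(1, 0, baseline_leak) * base_full
  }
  for (i in seq_len(counts_per_class[2])) {
    spectra[[length(spectra) + 1L]] <- gas_example(sigs$BZD)
    labels <- c(labels, 1L)
  }
  for (i in seq_len(counts_per_class[3])) {
    spectra[[length(spectra) + 1L]] <- gas_example(sigs$EBZD)
    labels <- c(labels, 2L)
  }
  X <- do.call(rbind, spectra)
  X <- X + matrix(stats::rnorm(length(X), 0, noise_sd), nrow(X), ncol(X))
  X[X < 0] <- 0
  ord <- sample.int(nrow(X))
  labeled_spectrum_dataset(X[ord, , drop = FALSE], labels[ord],
                           split_tag = split_tag)
}
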