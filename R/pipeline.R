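#' Full scan-to-report pipeline
#'
#' Runs the complete analysis on one hyperspectral scan: clip negatives ->
#' factorize at rank `n_gases + 2` -> normalize and order components ->
#' identify each component (by reference-signature correlation, or with a
#' trained CNN) -> reshape gas components into concentration maps -> fit
#' elliptical Gaussians to localize the sources -> compose the color overlay.
#' Fully deterministic given `seed`.
#'
#' @param scan A [hyperspectral_scan()].
#' @param n_gases Number of distinct gas types expected, >= 1.
#' @param identifier Either `"signatures"` (correlation against
#'   `signatures`) or a trained `sers_cnn` model.
#' @param signatures Named list of [gas_signature()] used for matching and for
#'   naming CNN classes (class 1 -> `"BZD"`, class 2 -> `"EBZD"`).
#' @param seed Seed for the NMF initialization (default 42).
#' @param n_init Seeded NMF restarts, best objective kept (default 5).
#' @param sources_per_gas Gaussians to fit per gas map; `NULL` (default) uses
#'   the number of peaks surviving [find_peaks()] on the smoothed map (capped
#'   at 3).
#' @param smooth_sigma_px Peak-seeding blur width (default 1).
#' @param colors Overlay colors recycled over gas components
#'   (default blue, yellow, red).
#' @param ... Further arguments passed to [nmf()] (e.g. `max_iter`, `tol`).
#' @return An object of class `pipeline_report`: `unmixing` (normalized
#'   factors), `component_labels`, `maps` (named per gas), `fits` (list of
#'   [fit_gaussians()] results per gas), `overlay` (or `NULL` if no gas
#'   component was found), and `provenance`.
#' @export
run_pipeline <- function(scan, n_gases,
                         identifier = "signatures",
                         signatures = default_signatures(),
                         seed = 42L, n_init = 5L, sources_per_gas = NULL,
                         smooth_sigma_px = 1,
                         colors = c("blue", "yellow", "red"), ...) {
  stopifnot(inherits(scan, "hyperspectral_scan"))
  if (n_gases < 1L) stop("n_gases must be >= 1", call. = FALSE)
  V <- clip_nonnegative(scan$V)
  res <- nmf(V, choose_rank(n_gases), seed = seed, n_init = n_init, ...)
  res <- normalize_components(res)

  if (inherits(identifier, "sers_cnn")) {
    cls <- predict_component_labels(res$H, identifier)
    class_names <- c("interference", names(signatures)[1:2])
    labels <- class_names[cls + 1L]
  } else if (identical(identifier, "signatures")) {
    labels <- match_components(res$H, signatures, scan$axis)
  } else {
    stop("identifier must be \"signatures\" or a trained sers_cnn",
         call. = FALSE)
  }

  gas_idx <- which(labels != "interference")
  if (length(gas_idx) == 0L)
    stop("no component was identified as a gas; check signatures or rank",
         call. = FALSE)

  maps <- list(); fits <- list()
  for (i in gas_idx) {
    gas <- labels[i]
    mp <- reshape_map(res$W[, i], scan$geometry)
    k <- sources_per_gas
    if (is.null(k)) {
      pk <- find_peaks(smooth_map(mp, smooth_sigma_px), 3L)
      # keep only peaks at least half as high as the dominant one, so noise
      # bumps on the normalized map do not spawn extra sources
      if (nrow(pk) > 0L) pk <- pk[pk[, "value"] >= 0.5 * pk[1, "value"], ,
                                  drop = FALSE]
      k <- max(1L, nrow(pk))
    }
    maps[[gas]] <- mp
    fits[[gas]] <- fit_gaussians(mp, k = min(k, 3L),
                                 smooth_sigma_px = smooth_sigma_px)
  }
  overlay <- overlay_maps(unname(maps),
                          rep_len(colors, length(maps)))

  structure(list(unmixing = res, component_labels = labels, maps = maps,
                 fits = fits, overlay = overlay,
                 provenance = list(seed = seed, n_gases = n_gases,
                                   rank = res$r,
                                   identifier = if (inherits(identifier, "sers_cnn"))
                                     "cnn" else "signatures",
                                   scan_metadata = scan$metadata)),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> rank %d, components: %s\n",
              x$unmixing$r, paste(x$component_labels, collapse = ", ")))
  for (gas in names(x$fits)) {
    for (f in x$fits[[gas]])
      cat(sprintf("  %s: center (%.2f, %.2f) mm, fitted diameter %.2f mm\n",
                  gas, f$x0_mm, f$y0_mm, fitted_diameter(f)))
  }
  invisible(x)
}
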