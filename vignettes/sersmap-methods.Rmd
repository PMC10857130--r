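---
title: "Methods: unmixing, localization and identification for SERS gas-sensor arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unmixing, localization and identification for SERS gas-sensor arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sersmap)
```

## The measurement model

A 2D SERS sensor array is scanned point by point after gas from one or more
odor sources has adsorbed onto it. The scan is a matrix `V` with one row per
scan point (row-major from the top-left corner; 36 × 36 = 1296 points over a
15 mm × 15 mm array by default) and one column per Raman-shift channel (308
channels at a nominal 4 cm⁻¹ spacing). Each spectrum is modeled as a
non-negative mixture of three spectrum families:

* **gas signatures** — Lorentzian bands at the compound's characteristic
  shifts (benzaldehyde at 1006 and 1603 cm⁻¹; 4-ethylbenzaldehyde at
  1614 cm⁻¹), scaled by the local gas concentration;
* **sensor baseline** — bands near 900, 1050 and 1400 cm⁻¹ from residual
  synthesis agents on the silver nanoparticles, present at every non-gap
  pixel, plus a flat continuum;
* **gap noise** — spectra collected from the slight gaps between the 3 × 3
  sensor chips (rows/columns 12 and 24 in 0-based indexing), which see no
  enhancing surface.

The local gas concentration is modeled as a 2D Gaussian plume centered under
the source,
$$G(x, y) = A \exp\!\left(-\frac{(x - x_0)^2}{2\sigma_x^2}
                          -\frac{(y - y_0)^2}{2\sigma_y^2}\right),$$
evaluated at the pixel centers `((col + 0.5)·pitch, (row + 0.5)·pitch)` with
pitch 15/36 ≈ 0.417 mm. The Gaussian-plume assumption describes quiescent
evaporation from an open-topped source in an enclosed chamber; it does not
model airflow, advection or time dynamics.

## Unmixing by NMF

`nmf()` minimizes the Frobenius reconstruction error `‖V − WH‖_F` under
non-negativity with the classical multiplicative updates, a denominator
guard `δ = 1e-12`, and seeded uniform initialization in (0, 1] scaled by
`sqrt(mean(V)/r)`. Iteration stops when the relative objective decrease
falls below `tol = 1e-6` or at `max_iter = 2000`; the per-iteration
objective trace is retained and is non-increasing by construction. The rank
is `choose_rank(n_gases) = n_gases + 2` — one component per gas plus
baseline and gap noise.

Two numerical points matter in practice:

* **Restarts.** Multiplicative updates converge to initialization-dependent
  local solutions. `nmf(..., n_init = k)` runs `k` consecutive seeds and
  keeps the lowest final objective; `run_pipeline()` defaults to five
  restarts, which in our experiments reliably discards the occasional
  poorly mixed two-gas solution (those solutions also score a visibly worse
  objective).
* **Identifiability.** Because the baseline is present at *every* pixel,
  `H_gas = S + α·b·B` (gas signature plus a fraction of the baseline
  spectrum) gives an exactly equivalent factorization for a range of α —
  the classic rotational ambiguity of NMF; no algorithm minimizing
  reconstruction error alone can pin α to zero. Gas components recovered
  from simulated scans therefore correlate with the true signature at about
  0.93–0.97 rather than 1.0, while the *row space* of `H` contains the true
  signature essentially exactly (projection correlation > 0.99). The
  component-matching threshold (Pearson r ≥ 0.8 in `match_components()`)
  and the CNN classifier are both comfortably robust to this level of
  leakage; the training-data generator reproduces it on purpose (see
  below).

`normalize_components()` rescales each `H` row to unit maximum (with the
inverse scale on the matching `W` column, leaving `WH` unchanged) and orders
components by total concentration, so the dominant gas is component 1.
All-zero components are left untouched and flagged. Constant `W` columns
min-max normalize to all-zero maps rather than NaN.

## Localization and size estimation

`fit_gaussians()` fits `offset + Σᵢ Aᵢ·Gᵢ(x, y)` (axis-aligned elliptical
Gaussians, no rotation term) to a concentration map by Levenberg–Marquardt
with box constraints: σ ∈ [pitch/2, array_size] and centers allowed to
overshoot the array edge by one pitch. The offset absorbs the uniform
baseline leakage that the NMF concentration column can carry. Seeding uses
local maxima of a 1-pixel-blurred copy of the map (strictly above at least
one 8-neighbor, greedy suppression within a Chebyshev radius of 6 px); the
fit itself runs on the unsmoothed map. Initial widths come from
intensity-weighted second moments over a nearest-seed partition. On failure
the fit restarts up to four times from deterministically jittered starts and
keeps the best attempt. Joint fitting of up to three Gaussians (rather than
sequential masking) keeps overlapping plumes resolvable.

Fitting the model to its own noiseless output recovers σ within far less
than 1% and centers within numerical precision — the strongest available
oracle — and recovery degrades gracefully to about one pixel / 10% under 5%
additive noise.

The source-size statistic is `fitted_diameter() = (σx + σy)/2` (mm).
`calibrate_size()` regresses fitted on actual diameters by OLS and reports
`R² = 1 − SS_res/SS_tot` computed directly from the residuals. The slope is
substantially below 1 on simulated data (the plume is wider than the
aperture, and min-max normalization plus offset absorb scale), which is why
the *linear calibration*, not the raw statistic, is the size estimate.

In `smooth_map()` the Gaussian blur uses a separable kernel with mirror
padding, which conserves total intensity exactly for the symmetric kernel;
the map is re-normalized to [0, 1] afterwards.

## Identification with a small 1D CNN

The classifier is deliberately minimal: conv(8 filters, kernel 7, stride 1)
→ ReLU → FC(64) → ReLU → FC(3) → softmax, cross-entropy loss, Adam
(β₁ = 0.9, β₂ = 0.999), initial learning rate 1e-4 cosine-annealed to
1e-5 with a 10-epoch period and warm restarts
(`η(t) = η_min + (η_0 − η_min)(1 + cos(π (t mod T)/T))/2`; a
non-restarting variant is selectable), batch size 8, 100 epochs, stratified
7:3 train/validation split (`round(0.7·n)` per label). Every spectrum is
divided by its own maximum on entry, so only band *positions and shape*
carry class information — amplitude cannot leak. Forward pass,
backpropagation and Adam are implemented directly in base R; at this scale
(≈155k parameters, ≈100 training spectra) a full 100-epoch run takes a few
seconds. Weight initialization (He-normal), shuffling and therefore the
final model are deterministic given the config seed. Spectra with no signal
at all (maximum ≤ 0) are labeled interference without a forward pass.

The hidden hyperparameters (8 filters, kernel 7, 64 hidden units, batch 8,
100 epochs) are the smallest configuration that cleanly separates the
synthetic classes; all are exposed in `classifier_config()`.

## What the simulator emulates — and what it does not

`simulate_scan()` draws, per non-gap pixel,
`V[p,] = Σ_g plume_g(p)·m_p·S_g + b·B + ε_p`, with

| parameter | default | meaning |
|---|---|---|
| lineshape | Lorentzian | standard Raman line model (Gaussian selectable) |
| axis | 602 + 4k cm⁻¹, 308 channels | covers all built-in bands; note no uniform 4 cm⁻¹ grid contains 1006, 1603 *and* 1614 simultaneously, so exact peak readings depend on the anchor |
| `baseline_strength` b | 0.3 | baseline amplitude relative to unit gas strength |
| `baseline_continuum` | 0.6 | flat continuum added to the baseline bands, as on real substrates; keeps simulated intensities well above zero so that clipping at 0 affects < 1% of entries at default noise |
| `multiplicative_sd` | 0.05 | per-pixel lognormal adsorption jitter (spot-to-spot enhancement randomness) |
| `additive_sd` | 0.05 | white noise, as a fraction of the maximum clean intensity |
| `gap_band_width` | 1 px | noise-only bands at internal chip boundaries (half-normal draws, so gap spectra are non-negative without clipping) |

Clean (noise-free) scans equal the generative formula exactly, so the
simulator is its own oracle; fixed seeds give bit-identical scans.

`simulate_feature_dataset()` emulates the *output of the unmixing stage*,
which is what the classifier consumes in practice: class 1/2 spectra are
gas signatures with peak centers jittered within ±2 cm⁻¹ and amplitudes
within ±15%, **plus up to 30% baseline leakage** (`baseline_leak = 0.3`) —
matching the α·b·B contamination measured on components unmixed from
simulated scans; class 0 is half baseline-like, half pure-noise spectra.
Default class counts are 68/21/13 for the 102-spectrum training pool and
28/14/14 for the 56-spectrum test set.

What passing tests on these data do **not** show: robustness to real
instrument artifacts (cosmic rays, detector baseline drift, wavenumber
miscalibration), to non-Gaussian plumes under airflow, to chemically
interacting mixtures, or to gas classes outside {BZD, EBZD}. The synthetic
classes are well separated by construction; accuracies near 100% on them
are a correctness check of the training stack, not a claim about field
performance.

## Problem sizes and determinism

The test suite and the acceptance script run everything at the native scan
size (1296 × 308; NMF at rank 3–4 converges in a few seconds per restart)
and train the CNN for the full 100 epochs per seed; the whole suite
completes in a few minutes on one core. Every stochastic step — scan noise,
dataset generation, NMF initialization, weight initialization, minibatch
shuffling — is governed by an explicit integer seed, and fixed seeds
reproduce results bit-identically.

## Known limitations

* NMF component spectra carry baseline leakage for the identifiability
  reason above; downstream stages are designed around it rather than
  pretending it away.
* The Gaussian plume model has no rotation term; strongly sheared plumes
  would need it.
* The 307-vs-308 channel ambiguity in dataset exports is resolved in favor
  of 308; 307-channel spectra are right-padded with their last value on
  load.
* `fitted_diameter` is a relative size statistic; only its linear
  calibration against known apertures yields physical diameters.
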