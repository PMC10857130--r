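# sersmap

Spectral unmixing and odor-source localization for two-dimensional
surface-enhanced Raman scattering (SERS) gas-sensor arrays.

## The problem

A SERS sensor array is a tiled plasmonic surface placed above an evaporating
odor source. Gas molecules adsorb onto the silver-nanoparticle surface in
proportion to the local gas concentration, and rastering a Raman probe over
the array (36 × 36 points over 15 mm × 15 mm) yields a hyperspectral scan:
1296 spectra of 308 wavenumber channels, collected row-major from the
top-left corner. Each spectrum mixes up to three ingredients — the
characteristic bands of the adsorbed gas (benzaldehyde, BZD, at 1006 and
1603 cm⁻¹; 4-ethylbenzaldehyde, EBZD, at 1614 cm⁻¹), the sensor's own
baseline bands (near 900, 1050 and 1400 cm⁻¹), and noise from the gaps
between sensor chips.

`sersmap` implements the full computational stack for such scans, for anyone
building or analyzing spatially resolved chemical sensing experiments:

1. **Unmixing.** The scan matrix `V (n × m)` is factorized by non-negative
   matrix factorization, `V ≈ W H`, with Frobenius-objective multiplicative
   updates written from scratch:

   `H ← H ⊙ (WᵀV) / (WᵀW H + δ)`, `W ← W ⊙ (V Hᵀ) / (W H Hᵀ + δ)`.

   Each row of `H` is a component's feature spectrum; each column of `W` its
   concentration at every scan point. The rank is the number of gas types
   plus two (baseline and gap noise): `choose_rank(1) = 3`,
   `choose_rank(2) = 4`.
2. **Visualization.** A gas component's `W` column is min-max normalized and
   reshaped to the 36 × 36 grid (`reshape_map()`); maps for several gases
   are blended into one color overlay (`overlay_maps()`).
3. **Localization and size.** An elliptical 2D Gaussian (plus offset) is
   fitted to the map in mm coordinates (`fit_gaussians()`, Levenberg–
   Marquardt); the source-size statistic `(σx + σy)/2`
   (`fitted_diameter()`) is calibrated against true source diameters by
   ordinary least squares (`calibrate_size()`).
4. **Identification.** Component spectra are assigned to
   {interference, BZD, EBZD} either by Pearson correlation against reference
   signatures (`match_components()`) or with a five-layer 1D convolutional
   network — conv → ReLU → FC → ReLU → FC → softmax — trained with Adam and
   a cosine-annealed learning rate (1e-4 → 1e-5, period 10 epochs)
   implemented entirely in base R (`train_classifier()`).
5. **Simulation.** Because no public scans exist, `simulate_scan()`
   generates fully specified synthetic scans — Lorentzian gas/baseline
   signatures, Gaussian plume concentration fields, per-pixel adsorption
   jitter, gap-pixel noise — with the ground truth attached, and
   `simulate_feature_dataset()` builds labeled spectrum datasets for the
   classifier.

## Worked example

```r
library(sersmap)

## one benzaldehyde source at the array center, sigma 2 mm, default noise
scan <- simulate_scan(list(source_spec("BZD", center = c(7.5, 7.5), sigma = 2)))
scan
#> <hyperspectral_scan> V 1296 x 308 (36 x 36 grid, 308 channels)

report <- run_pipeline(scan, n_gases = 1)
report
#> <pipeline_report> rank 3, components: BZD, interference, interference
#>   BZD: center (7.54, 7.55) mm, fitted diameter 1.61 mm
```

The NMF at rank 3 isolates one component whose spectrum correlates with the
BZD signature (the other two carry baseline and gap noise); the Gaussian fit
localizes the plume within a tenth of a pixel of the true center (7.5, 7.5)
mm, and `(σx + σy)/2` estimates the source extent.

Sweeping five source sizes and calibrating fitted against actual diameters:

```r
d <- c(2.24, 3.25, 3.96, 4.43, 4.8)   # source diameters, mm
fitted <- sapply(seq_along(d), function(i) {
  sc <- simulate_scan(list(source_spec("BZD", c(7.5, 7.5), d[i] / 2)),
                      noise = noise_model(seed = 42L + i))
  rp <- run_pipeline(sc, 1, n_init = 1, sources_per_gas = 1)
  fitted_diameter(rp$fits$BZD[[1]])
})
calibrate_size(data.frame(actual = d, fitted = fitted))
#> <size_calibration> fitted = 0.3526 * actual + 0.2472, R^2 = 0.9960 (5 pairs)
```

The strong linear relation (R² = 0.996) is what makes the fitted diameter a
usable proxy for the physical source size.

A command-line front end over the same functions lives at
`inst/cli/sersmap.R` (subcommands `simulate`, `unmix`, `map`, `localize`,
`calibrate`, `train`, `evaluate`, `predict`, `run-all`).

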