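# small shared fixtures, built in code

tiny_geometry <- function() grid_geometry(2L, 2L, array_size = 1)

# short axis holding the two high-wavenumber bands
short_axis <- function() make_axis(1543, 4, 50L)

# a quiet noise model for near-deterministic scans
quiet_noise <- function(seed = 7L)
  noise_model(additive_sd = 0.02, multiplicative_sd = 0, gap_band_width = 1L,
              seed = seed)

center_bzd_source <- function(sigma = 2)
  source_spec("BZD", center = c(7.5, 7.5), sigma = sigma, strength = 1)
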