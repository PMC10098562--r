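# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the default run stays fast.

# A tiny deterministic spectra tibble (no package RNG involved).
tiny_spectra <- function(n = 6, wavelengths = 400:439) {
  m <- length(wavelengths)
  mat <- t(vapply(seq_len(n), function(i) {
    0.2 + 0.05 * i / n + 0.1 * sin(seq(0, 3, length.out = m) + i / 2)
  }, numeric(m)))
  as_spectra_tbl(mat, wavelengths)
}

# Small simulated dataset on a reduced wavelength grid.
small_sim <- function(n = 12, nutrient = "TK2O", seed = 101,
                      wavelengths = seq(400, 478, by = 2), ...) {
  simulate_dataset(synthetic_config(nutrient = nutrient, n_samples = n,
                                    wavelengths = wavelengths, seed = seed, ...))
}

# Small preprocessed joint table (window must fit the reduced grid).
small_joint <- function(n = 12, seed = 101, nutrient = "TK2O", ...) {
  sim <- small_sim(n = n, seed = seed, nutrient = nutrient, ...)
  preprocess_joint(sim$spectra, sim$labels$value_g_per_kg, nutrient,
                   window = 7, low_nm = -Inf, high_nm = Inf)
}

# Fast GAN configuration for structural tests.
fast_gan_config <- function(seed = 99, ...) {
  gan_config(epochs = 30, checkpoint_interval = 10, samples_per_checkpoint = 5,
             noise_dim = 5, hidden_g = c(8, 8), hidden_d = c(8, 8), seed = seed, ...)
}

# Fast CNN configuration for structural tests.
fast_cnn_config <- function(epochs = 5, seed = 7, ...) {
  cnn_config(epochs = epochs, conv_layers = list(c(4, 5, 1), c(3, 3, 1)),
             dense_units = 8, seed = seed, ...)
}

# Hand-rolled gan_archive stub holding given label sets as checkpoints
# (spectral block is constant), for epoch-selection tests.
stub_archive <- function(label_sets, divisor = 1, n_bands = 3) {
  checkpoints <- lapply(label_sets, function(labs) {
    cbind(matrix(0.5, length(labs), n_bands), labs / divisor)
  })
  structure(list(checkpoints = checkpoints, divisor = divisor,
                 width = n_bands + 1L, wavelengths = seq_len(n_bands),
                 nutrient = NULL, norm_params = NULL),
            class = "gan_archive")
}
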