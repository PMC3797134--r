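# Shared fixtures, built lazily and cached for the session so expensive
# simulations run once.

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_sat <- function() saturation_params()
fx_scanner <- function() scanner_params()

# two-pool default system and its noise-free spectrum at b0 = 0
fx_z0 <- function() fx("z0", function()
  simulate_zspectrum(default_pools(), fx_sat(), fx_scanner()))

# tumor-like and reference-like three-pool systems
fx_tumor_pools <- function() c(default_pools(3e-3), list(mt_pool()))
fx_cord_pools <- function() c(default_pools(1e-3), list(mt_pool()))

# small noise-free phantom with default anatomy and B0 field
fx_phantom_free <- function() fx("phantom_free", function()
  generate_phantom_stack(phantom_spec(image_size = 32, noise_sigma = 0,
                                      seed = 11)))

# same anatomy with default noise
fx_phantom_noisy <- function() fx("phantom_noisy", function()
  generate_phantom_stack(phantom_spec(image_size = 32, seed = 11)))

# uniform-muscle phantom, no B0, no noise: every pixel shares one spectrum
fx_phantom_uniform <- function() fx("phantom_uniform", function() {
  n <- 32L
  generate_phantom_stack(
    phantom_spec(image_size = n, noise_sigma = 0, b0_amplitude = 0,
                 tissue_map = matrix("muscle", n, n), seed = 2))
})

# minimal animal_result carrying given corrected values at one offset
fx_animal <- function(values, offset = 3.5, group = "g", ids = NULL) {
  lapply(seq_along(values), function(i)
    structure(list(table = data.frame(offset_ppm = offset,
                                      tumor = values[i], cord = 0,
                                      corrected = values[i]),
                   animal = if (is.null(ids)) sprintf("%s%02d", group, i)
                            else ids[i],
                   group = group, n_tumors = 1L),
              class = "animal_result"))
}
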