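# Shared small fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

tiny_profile <- function(noise = 0.02, psf = 1.6, n_clean = 2, seed = 1) {
  make_centre_profiles(1, seed = seed, matrix_size = 64, n_clean = n_clean,
                       n_artefact = 0, psf_fwhm = psf, noise_scale = noise)[[1]]
}

tiny_pair <- function() {
  memo("tiny_pair", function() generate_patient(tiny_profile(), seed = 5))
}

noiseless_pair <- function() {
  memo("noiseless_pair", function() {
    generate_patient(tiny_profile(noise = 0, psf = 0.01), seed = 5,
                     lesion_max = 0)
  })
}

# small config used across network/federated tests
tiny_net_config <- function(seed = 3, ...) {
  network_config(n_stages = 2, base_channels = 3, rsu_inner_depth = 1,
                 batch_size = 4, epochs = 2, seed = seed, ...)
}

# deterministic toy regression task: y is a clipped linear map of a smooth
# random field (smooth like real normalized PET slices, so the
# half-resolution side outputs can also fit it)
toy_dataset <- function(n = 4, size = 16, seed = 11) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      x <- fedasc:::gaussian_blur(matrix(runif(size * size, 0, 1), size), 1.5)
      list(x = x, y = pmin(x * 1.8, 1))
    })
  })
}
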