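# Small shared phantom fixtures, generated once per test run.
# Unit tests use compact 64-pixel phantoms; the pipeline-closure checks in
# test-acceptance.R build their own full-size phantoms.

small_spec <- function(plane = "sagittal", seed = 11, ...) {
  phantom_spec(plane, image_size = 64L, rng_seed = seed, ...)
}

fix_sag <- generate_volume(small_spec())
fix_trans <- generate_volume(small_spec("transverse", seed = 12))

# deterministic test raster with structure
ramp_noise_slice <- function(n = 32, seed = 1, modality = "MR",
                             plane = "sagittal") {
  set.seed(seed)
  m <- outer(seq_len(n), seq_len(n), function(r, c) r + 2 * c) +
    matrix(rnorm(n * n, 0, 0.5), n, n)
  knee_slice(m - min(m), modality = modality, plane = plane)
}
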