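# Shared small fixtures, built in code. Heavier artifacts (trained models,
# the desk-scale ground-truth dataset) are created lazily and cached for
# the duration of the test run in `.fixture_cache`.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_optics <- function() optics_config()

small_acq <- function(shape = c(128, 128), dwell = 200) {
  acquisition_config(sigma_wd = 5, image_shape = shape, dwell_time = dwell)
}

small_scene <- function(seed = 1, shape = c(192, 192), blank_frac = 0) {
  scene_raster(shape, seed = seed, blank_frac = blank_frac)
}

# Tiny dataset for smoke tests: 6 locations x 4 aberrations at 96x96.
tiny_dataset <- function() {
  cache_get("tiny_dataset", function() {
    plan <- sampling_plan(6, 4, wd_range = 20, stig_range = 5,
                          image_shape = c(96, 96))
    generate_ground_truth(plan, default_optics(), seed = 321)
  })
}

# Defocus-dominated dataset for training smoke tests (strong wd signal,
# near-zero stigmators) at 96x96 images.
smoke_dataset <- function() {
  cache_get("smoke_dataset", function() {
    plan <- sampling_plan(48, 4, wd_range = 20, stig_range = 0.5,
                          image_shape = c(96, 96))
    generate_ground_truth(plan, default_optics(), seed = 654)
  })
}

# A small encoder for fast training smoke tests on 32 px patches.
smoke_spec <- function() {
  encoder_spec(out_ch = c(6L, 12L), kernel = c(5L, 3L), pool = c(2L, 2L),
               fc_hidden = c(16L, 8L))
}

# Noise-free render of a scene under a state (simulator ground truth).
noisefree_render <- function(scene, state, optics = default_optics()) {
  semfocus:::fft_convolve(scene, beam_spot_kernel(state, optics))
}
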