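# small phantom used across unit tests: coarse grid, short litter,
# chosen for speed; analyses asserting quantitative recovery at the
# study's default conditions live in test-acceptance.R
small_spec <- function(gestational_age = "E14.5", n_placentas = 4,
                       grid_shape = c(48, 48, 8), seed = 1L, ...) {
  phantom_spec(n_placentas = n_placentas, grid_shape = grid_shape,
               gestational_age = gestational_age, seed = seed, ...)
}

# default time grid of the acquisition
default_time_grid <- function(n_frames = 50, dt = 18) (seq_len(n_frames) - 1) * dt

default_aif_params <- function() {
  phantom_spec()$aif_params
}
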