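# Shared fixtures. Cohorts are generated once per test run and memoised here;
# everything is built in code (no stored fixtures).

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, expr, .fixture_env)
  get(key, .fixture_env)
}

# small, fast phantom configs
cfg64 <- function(noise = 10, seed = 11, n_slices = 1, ...) {
  phantom_config(image_size = 64, n_slices = n_slices, noise_sigma = noise,
                 seed = seed, ...)
}

clean_sample64 <- function() {
  memo("clean64", generate_phantom(cfg64(noise = 0, seed = 5), "clean64"))
}

noisy_sample64 <- function() {
  memo("noisy64", generate_phantom(cfg64(noise = 10, seed = 6), "noisy64"))
}

clean_stack64 <- function() {
  memo("stack64",
       generate_phantom(cfg64(noise = 0, seed = 8, n_slices = 5), "stack64"))
}
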