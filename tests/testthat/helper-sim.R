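# small simulation setups shared across test files

tiny_config <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(n_sensors = 24, n_localizer_trials = 48,
                   n_rsvp_trials = 16, n_subjects = 1, noise_sd = 1,
                   rng_seed = seed)
  do.call(sim_config, utils::modifyList(defaults, args))
}

tiny_primitives <- function(n_sensors = 24, seed = 1) {
  list(patterns = make_category_patterns(n_sensors, rng_seed = seed),
       kernels = make_response_kernels())
}

# four-class toy data with one informative direction per class
toy_multiclass <- function(n_per = 30, p = 12, sep = 2.5, seed = 1) {
  X <- with_seed(seed, do.call(rbind, lapply(1:4, function(k) {
    M <- matrix(rnorm(n_per * p), n_per, p)
    M[, k] <- M[, k] + sep
    M
  })))
  list(X = X, y = rep(letters[1:4], each = n_per))
}
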