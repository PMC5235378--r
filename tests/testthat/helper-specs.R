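# shared fixtures: small configurations and degenerate specs built in code

tiny_config <- function(n = 1000L, seed = 1L, ...) {
  simulation_config(n_trials = n, seed = seed, ...)
}

# a model whose facilitation never reaches the threshold
subthreshold_atm_spec <- function() {
  model_spec("atm",
             facilitation = gaussian_process_spec(amplitude = c(1.0, 0),
                                                  peak_time = c(0.006, 0),
                                                  width = c(0.064, 0)),
             threshold = threshold_spec("tonic-sampled", tonic = c(1.8, 0)))
}

# zero-variability version of the reference ATM go model
deterministic_atm_go_spec <- function() {
  model_spec("atm",
             facilitation = gaussian_process_spec(amplitude = c(2.576, 0),
                                                  peak_time = c(0.006, 0),
                                                  width = c(0.064, 0)),
             threshold = threshold_spec("tonic-sampled", tonic = c(1.798, 0)))
}

# closed-form upward crossing of a Gaussian through a constant level
gauss_cross_closed_form <- function(a, b, c, thr) {
  w <- sqrt(-2 * c^2 * log(thr / a))
  c(onset = b - w, offset = b + w)
}

random_gaussian_params <- function() {
  gaussian_params(amplitude = runif(1, 1.5, 4),
                  peak_time = runif(1, -0.05, 0.06),
                  width = runif(1, 0.03, 0.12))
}
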