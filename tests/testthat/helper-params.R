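# Compact parameter factory for tests: small population, everything
# overridable.
tpar <- function(...) {
  defaults <- list(n_total = 10L, max_age = 3L, n_attacks = 2L,
                   n_disturbances = 1L, beta = 0.5,
                   p_capture_f = 0.2, p_capture_b = 0.6,
                   energy_gain = 10, energy_cost_escape = 0.5,
                   init_freq_f = 0.5, base_seed = 99L)
  do.call(model_params, utils::modifyList(defaults, list(...)))
}

# Random valid configuration for property-style sweeps.
random_params <- function() {
  has_comp <- runif(1) < 0.3
  tpar(
    n_total = sample(2:30, 1),
    max_age = sample(1:6, 1),
    n_attacks = sample(0:8, 1),
    n_disturbances = sample(0:5, 1),
    beta = runif(1),
    p_capture_f = runif(1),
    p_capture_b = runif(1),
    energy_gain = runif(1, 0, 20),
    energy_cost_escape = runif(1, 0, 2),
    risk_mode = sample(c("frequency_dependent", "frequency_independent"), 1),
    init_freq_f = runif(1),
    init_age_distribution = sample(c("uniform", "all_youngest"), 1),
    competition = if (has_comp)
      competition_params(r_f = runif(1, 0.5, 3), r_b = runif(1, 0.5, 3),
                         a_ff = runif(1, 0, 0.01), a_fb = runif(1, 0, 0.01),
                         a_bf = runif(1, 0, 0.01), a_bb = runif(1, 0, 0.01))
      else NULL,
    base_seed = sample.int(100000L, 1)
  )
}
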