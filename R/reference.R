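#' Reference study scenarios
#'
#' The package's canonical parameter sets for the two families of
#' experiments, used by the shipped experiment drivers, the acceptance
#' script and the examples.  The values are the package's reference study
#' conditions: chosen once, documented in the methods vignette, and fixed.
#' They exhibit the model's characteristic regimes — fearfulness
#' favored in small populations and boldness in large ones, an
#' intermediate-attack-intensity optimum for fearfulness at moderate
#' population size, fearfulness advantage decaying with the escape cost,
#' and stable coexistence once competitive background fitness is enabled.
#'
#' `scenario = "predation"` is the base scenario of the population-size,
#' attack-intensity and escape-cost experiments: `max_age = 5`, 20 attacks
#' and 20 disturbances per season, `beta = 0.1`, capture probabilities
#' 0.5 (F) / 0.8 (B), seasonal energy gain 8, escape cost 0.1, 50% initial
#' fearful proportion, 1000 replicates.  The population-size levels used
#' with it are 50 (small), 200 (moderate) and 350 (large).
#'
#' `scenario = "coexistence"` is the background-fitness scenario: a
#' sharper survival contrast (`p_capture_f = 0.2`, `p_capture_b = 0.9`),
#' smaller escape cost 0.05, and Lotka-Volterra coefficients
#' `r_f = r_b = 2`, `a_ff = 0.005`, `a_fb = 0.006`, `a_bf = 0.0005`,
#' `a_bb = 0.008` — the bold phenotype's competitive effects (`a_fb`,
#' `a_bb`) exceed the fearful phenotype's (`a_ff`, `a_bf`): individuals
#' that risk more when confronting predators compete more aggressively.
#' Its population-size levels are 240-320; the default `n_total` is the
#' middle of the band, 285.
#'
#' @param scenario Which reference scenario to return.
#' @param ... Overrides for any [model_params()] argument.
#' @return A validated `model_params` object.
#' @examples
#' reference_params("predation", n_total = 50)
#' @export
reference_params <- function(scenario = c("predation", "coexistence"), ...) {
  scenario <- match.arg(scenario)
  base <- switch(scenario,
    predation = list(
      n_total = 200L, max_age = 5L, n_attacks = 20L, n_disturbances = 20L,
      beta = 0.1, p_capture_f = 0.5, p_capture_b = 0.8,
      energy_gain = 8, energy_cost_escape = 0.1,
      init_freq_f = 0.5, n_replicates = 1000L, base_seed = 1L),
    coexistence = list(
      n_total = 285L, max_age = 5L, n_attacks = 20L, n_disturbances = 20L,
      beta = 0.1, p_capture_f = 0.2, p_capture_b = 0.9,
      energy_gain = 8, energy_cost_escape = 0.05,
      init_freq_f = 0.5, n_replicates = 1000L, base_seed = 1L,
      competition = competition_params(r_f = 2, r_b = 2,
                                       a_ff = 0.005, a_fb = 0.006,
                                       a_bf = 0.0005, a_bb = 0.008))
  )
  args <- utils::modifyList(base, list(...))
  do.call(model_params, args)
}
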