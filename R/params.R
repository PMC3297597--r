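#' Model parameters for the fearfulness-boldness simulation
#'
#' Collects every biological and protocol constant of one simulation
#' scenario into a validated `model_params` object.  The population holds
#' `n_total` asexual pure strategists, fearful (F) or bold (B), living at
#' most `max_age` breeding seasons.  Each season brings `n_attacks` real
#' predatory attacks and `n_disturbances` non-lethal disturbing events;
#' fearful individuals flee at every threat, bold ones only at real attacks,
#' so the two phenotypes pay different energy costs and face different
#' capture risks.
#'
#' @param n_total Total population size N, held constant at each season
#'   start.  Must be at least 2 for a two-phenotype contest.
#' @param max_age Maximum natural life A in years; individuals reaching age
#'   `max_age` are removed at the end of that season even if never captured.
#' @param n_attacks Number of real predatory attacks per breeding season (a).
#' @param n_disturbances Number of non-lethal disturbing events per season
#'   (d).  Disturbances cause no mortality; they only drain the energy of
#'   fearful individuals, who flee at every threat.
#' @param beta Relative probability, in `[0, 1]`, that a fearful individual
#'   is selected by a predator, compared with a bold individual.  Near 0 the
#'   fearful are almost never attacked; at 1 the risk is shared equally.
#' @param p_capture_f,p_capture_b Probability that a selected fearful (bold)
#'   individual is actually captured.  Bold individuals delay flight, so
#'   typically `p_capture_b > p_capture_f`.
#' @param energy_gain Total energy e0 gained over a breeding season.
#' @param energy_cost_escape Energy c lost per escape flight.
#' @param repro_scale Proportionality constant of the reproductive-success
#'   function; it cancels in all offspring shares and is exposed only for
#'   completeness.
#' @param repro_exponent Exponent of the reproductive-success function
#'   `f(x) = repro_scale * x^repro_exponent`.  The default 1 is the linear
#'   form ("reproductive success proportional to energy reserves"); other
#'   positive exponents are available as a sensitivity switch.
#' @param risk_mode `"frequency_dependent"` (group selection probability
#'   proportional to phenotype abundance) or `"frequency_independent"`
#'   (selection split `beta : 1` regardless of population structure).
#' @param competition Optional [competition_params()] object enabling
#'   Lotka-Volterra-style background fitness; `NULL` disables it
#'   (background fitness identically 1).
#' @param init_freq_f Initial proportion of fearful individuals in `[0, 1]`.
#'   The initial count is `round_half_up(init_freq_f * n_total)`.
#' @param init_age_distribution `"uniform"` (each individual's age drawn
#'   uniformly on `1..max_age`) or `"all_youngest"` (everyone starts at age
#'   1, useful for deterministic tests).
#' @param max_seasons Cap on seasons per run-to-fixation replicate; runs
#'   hitting the cap are reported as timeouts, never as fixations.
#' @param n_replicates Default number of replicates for fixation-frequency
#'   estimation.
#' @param base_seed Integer root of the reproducible random stream; each
#'   replicate derives its own seed from `(base_seed, replicate_index)`.
#' @param empty_group_renormalize Only relevant in frequency-independent
#'   mode: if the predator selects a phenotype group that is empty, the
#'   attack fails (`FALSE`, default, keeping selection literally independent
#'   of population structure) or is redirected to the non-empty group
#'   (`TRUE`).
#'
#' @return A validated object of class `model_params` (a named list).
#' @seealso [competition_params()], [validate_params()], [read_params_json()]
#' @examples
#' p <- model_params(n_total = 50, max_age = 5, n_attacks = 10,
#'                   n_disturbances = 10, beta = 0.1,
#'                   p_capture_f = 0.5, p_capture_b = 0.8,
#'                   energy_gain = 10, energy_cost_escape = 0.1)
#' p
#' @export
model_params <- function(n_total,
                         max_age,
                         n_attacks,
                         n_disturbances = 0L,
                         beta = 1,
                         p_capture_f = 0.5,
                         p_capture_b = 0.8,
                         energy_gain = 10,
                         energy_cost_escape = 0.1,
                         repro_scale = 1,
                         repro_exponent = 1,
                         risk_mode = c("frequency_dependent",
                                       "frequency_independent"),
                         competition = NULL,
                         init_freq_f = 0.5,
                         init_age_distribution = c("uniform", "all_youngest"),
                         max_seasons = 100000L,
                         n_replicates = 1000L,
                         base_seed = 1L,
                         empty_group_renormalize = FALSE) {
  risk_mode <- match.arg(risk_mode)
  init_age_distribution <- match.arg(init_age_distribution)
  p <- structure(
    list(
      n_total = as.integer(n_total),
      max_age = as.integer(max_age),
      n_attacks = as.integer(n_attacks),
      n_disturbances = as.integer(n_disturbances),
      beta = as.numeric(beta),
      p_capture_f = as.numeric(p_capture_f),
      p_capture_b = as.numeric(p_capture_b),
      energy_gain = as.numeric(energy_gain),
      energy_cost_escape = as.numeric(energy_cost_escape),
      repro_scale = as.numeric(repro_scale),
      repro_exponent = as.numeric(repro_exponent),
      risk_mode = risk_mode,
      competition = competition,
      init_freq_f = as.numeric(init_freq_f),
      init_age_distribution = init_age_distribution,
      max_seasons = as.integer(max_seasons),
      n_replicates = as.integer(n_replicates),
      base_seed = as.integer(base_seed),
      empty_group_renormalize = isTRUE(empty_group_renormalize)
    ),
    class = "model_params"
  )
  validate_params(p)
}

#' Lotka-Volterra competition coefficients for background fitness
#'
#' Background fitnesses are defined by analogy to Lotka-Volterra
#' interspecific competition:
#' `Phi_F = max(0, r_f - a_ff * n_f - a_fb * n_b)` and
#' `Phi_B = max(0, r_b - a_bf * n_f - a_bb * n_b)`.
#' Subscript convention: the FIRST index is the affected phenotype, the
#' SECOND the source phenotype, so `a_fb` is the effect of bold individuals
#' on fearful individuals.
#'
#' @param r_f,r_b Positive baseline background-fitness constants.
#' @param a_ff Effect of fearful individuals on fearful individuals.
#' @param a_fb Effect of bold individuals on fearful individuals.
#' @param a_bf Effect of fearful individuals on bold individuals.
#' @param a_bb Effect of bold individuals on bold individuals.
#' @return An object of class `competition_params`.
#' @export
competition_params <- function(r_f, r_b, a_ff, a_fb, a_bf, a_bb) {
  cp <- structure(
    list(r_f = as.numeric(r_f), r_b = as.numeric(r_b),
         a_ff = as.numeric(a_ff), a_fb = as.numeric(a_fb),
         a_bf = as.numeric(a_bf), a_bb = as.numeric(a_bb)),
    class = "competition_params"
  )
  for (nm in c("r_f", "r_b")) {
    if (!is.finite(cp[[nm]]) || cp[[nm]] <= 0)
      stop("competition_params: `", nm, "` must be a positive real", call. = FALSE)
  }
  for (nm in c("a_ff", "a_fb", "a_bf", "a_bb")) {
    if (!is.finite(cp[[nm]]) || cp[[nm]] < 0)
      stop("competition_params: `", nm, "` must be a non-negative real", call. = FALSE)
  }
  cp
}

#' Validate a set of model parameters
#'
#' Checks every invariant of a [model_params()] object and returns it
#' unchanged if all hold; otherwise fails with a message naming the
#' offending field.
#'
#' @param params A `model_params` object (or bare named list with the same
#'   fields).
#' @return `params`, invisibly unchanged, if valid.
#' @export
validate_params <- function(params) {
  chk <- function(cond, field, msg) {
    if (!cond) stop("invalid model parameters: `", field, "` ", msg, call. = FALSE)
  }
  int_pos <- function(x) length(x) == 1L && is.finite(x) && x == as.integer(x)
  chk(int_pos(params$n_total) && params$n_total >= 2L, "n_total",
      "must be an integer >= 2 (a two-phenotype contest needs at least 2 individuals)")
  chk(int_pos(params$max_age) && params$max_age >= 1L, "max_age",
      "must be an integer >= 1")
  chk(int_pos(params$n_attacks) && params$n_attacks >= 0L, "n_attacks",
      "must be a non-negative integer")
  chk(int_pos(params$n_disturbances) && params$n_disturbances >= 0L,
      "n_disturbances", "must be a non-negative integer")
  for (nm in c("beta", "p_capture_f", "p_capture_b", "init_freq_f")) {
    x <- params[[nm]]
    chk(length(x) == 1L && is.finite(x) && x >= 0 && x <= 1, nm,
        "must be a probability in [0, 1]")
  }
  for (nm in c("energy_gain", "energy_cost_escape")) {
    x <- params[[nm]]
    chk(length(x) == 1L && is.finite(x) && x >= 0, nm,
        "must be a non-negative real")
  }
  chk(is.finite(params$repro_scale) && params$repro_scale > 0, "repro_scale",
      "must be a positive real")
  chk(is.finite(params$repro_exponent) && params$repro_exponent > 0,
      "repro_exponent", "must be a positive real")
  chk(params$risk_mode %in% c("frequency_dependent", "frequency_independent"),
      "risk_mode", "must be 'frequency_dependent' or 'frequency_independent'")
  chk(params$init_age_distribution %in% c("uniform", "all_youngest"),
      "init_age_distribution", "must be 'uniform' or 'all_youngest'")
  chk(int_pos(params$max_seasons) && params$max_seasons >= 1L, "max_seasons",
      "must be a positive integer")
  chk(int_pos(params$n_replicates) && params$n_replicates >= 1L,
      "n_replicates", "must be a positive integer")
  chk(int_pos(params$base_seed), "base_seed", "must be an integer")
  if (!is.null(params$competition) &&
      !inherits(params$competition, "competition_params"))
    stop("invalid model parameters: `competition` must be NULL or a ",
         "competition_params object", call. = FALSE)
  invisible(params)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Fearfulness-boldness simulation parameters\n")
  cat(sprintf("  population: N = %d, max age A = %d, initial F proportion = %g (%s ages)\n",
              x$n_total, x$max_age, x$init_freq_f, x$init_age_distribution))
  cat(sprintf("  threats/season: a = %d attacks, d = %d disturbances (%s risk)\n",
              x$n_attacks, x$n_disturbances,
              sub("_", "-", x$risk_mode)))
  cat(sprintf("  predation: beta = %g, pF = %g, pB = %g\n",
              x$beta, x$p_capture_f, x$p_capture_b))
  cat(sprintf("  energy: e0 = %g, cost/escape c = %g  (F reserves %g, B reserves %g)\n",
              x$energy_gain, x$energy_cost_escape,
              energy_reserves("F", x), energy_reserves("B", x)))
  if (is.null(x$competition)) {
    cat("  background fitness: disabled (Phi = 1)\n")
  } else {
    cp <- x$competition
    cat(sprintf("  background fitness: r_f = %g, r_b = %g, a_ff = %g, a_fb = %g, a_bf = %g, a_bb = %g\n",
                cp$r_f, cp$r_b, cp$a_ff, cp$a_fb, cp$a_bf, cp$a_bb))
  }
  cat(sprintf("  protocol: %d replicates, max %d seasons, base seed %d\n",
              x$n_replicates, x$max_seasons, x$base_seed))
  invisible(x)
}

# round-half-up, so e.g. 2.5 -> 3; round() would go to even and make the
# initial F count depend on parity
round_half_up <- function(x) floor(x + 0.5)

#' Read model parameters from a JSON configuration file
#'
#' The configuration keys are exactly the argument names of
#' [model_params()]; `competition`, if present, is a nested object with the
#' argument names of [competition_params()].  Unknown keys are an error so
#' that typos cannot silently fall back to defaults.
#'
#' @param path Path to a JSON file.
#' @return A validated `model_params` object.
#' @export
read_params_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(model_params))
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0L)
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "),
         " (valid keys are the model_params() argument names)", call. = FALSE)
  if (!is.null(cfg$competition)) {
    ck <- names(formals(competition_params))
    cextra <- setdiff(names(cfg$competition), ck)
    if (length(cextra) > 0L)
      stop("unknown competition key(s): ", paste(cextra, collapse = ", "),
           call. = FALSE)
    cfg$competition <- do.call(competition_params, as.list(cfg$competition))
  }
  do.call(model_params, cfg)
}

#' Write model parameters to a JSON configuration file
#'
#' Inverse of [read_params_json()]: the written file round-trips through
#' [read_params_json()] to an identical parameter set.
#'
#' @param params A `model_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(params, path) {
  validate_params(params)
  x <- unclass(params)
  if (!is.null(x$competition)) x$competition <- unclass(x$competition)
  x <- Filter(Negate(is.null), x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
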