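#' Energy reserves of a surviving individual at reproduction
#'
#' Fearful individuals flee at every threat, real attack or mere
#' disturbance, so a survivor's reserves are
#' `max(0, e0 - (a + d) * c)`; bold individuals flee only at real attacks,
#' leaving `max(0, e0 - a * c)`.  Reserves are clipped at zero (the clip is
#' only a guard against pathological configurations; the usual parameter
#' regimes keep reserves positive).
#'
#' @param phenotype `"F"` or `"B"`.
#' @param params A `model_params` object.
#' @return Non-negative energy level.
#' @export
energy_reserves <- function(phenotype, params) {
  phenotype <- match.arg(phenotype, c("F", "B"))
  n_escapes <- if (phenotype == "F")
    params$n_attacks + params$n_disturbances else params$n_attacks
  max(0, params$energy_gain - n_escapes * params$energy_cost_escape)
}

#' Reproductive success from energy reserves
#'
#' Reproductive success is proportional to the level of energy reserves:
#' `f(x) = repro_scale * x^repro_exponent`, linear by default.  The scale
#' constant cancels in every offspring share, so only the exponent can
#' change the dynamics.
#'
#' @param x Non-negative energy level.
#' @param params A `model_params` object.
#' @return Non-negative reproductive success; `f(0) = 0`.
#' @export
reproductive_success <- function(x, params) {
  if (any(x < 0))
    stop("reproductive_success: negative energy reserves (reserves are ",
         "clipped at 0 upstream)", call. = FALSE)
  params$repro_scale * x^params$repro_exponent
}

#' Lotka-Volterra background fitness of the two phenotypes
#'
#' When competition is enabled, the reproductive output of each phenotype
#' is weighted by a background fitness declining linearly in the phenotype
#' counts, by analogy to Lotka-Volterra interspecific competition:
#' `Phi_F = max(0, r_f - a_ff * n_f - a_fb * n_b)` and
#' `Phi_B = max(0, r_b - a_bf * n_f - a_bb * n_b)`.  With competition
#' disabled both fitnesses are 1.
#'
#' @param n_f,n_b Phenotype counts (the post-attack survivor counts that
#'   enter the offspring expectations).
#' @param params A `model_params` object.
#' @return Named numeric vector `c(phi_f = , phi_b = )`.
#' @export
background_fitness <- function(n_f, n_b, params) {
  cp <- params$competition
  if (is.null(cp)) return(c(phi_f = 1, phi_b = 1))
  c(phi_f = max(0, cp$r_f - cp$a_ff * n_f - cp$a_fb * n_b),
    phi_b = max(0, cp$r_b - cp$a_bf * n_f - cp$a_bb * n_b))
}

#' Expected numbers of fearful and bold offspring
#'
#' All `deaths_total` dead individuals (predation kills plus max-age
#' removals) are replaced at season end; the expected fearful share is the
#' phenotype's fraction of total reproductive output, computed on the
#' post-attack survivor counts:
#' `W_F = D * n_f' * f(x_F) * Phi_F / (n_f' * f(x_F) * Phi_F + n_b' * f(x_B) * Phi_B)`
#' and `W_B = D - W_F`.  If both phenotypes have zero reproductive output
#' but survivors exist, the offspring are allocated proportionally to
#' survivor counts so the population never silently vanishes.
#'
#' @param n_f_post,n_b_post Post-attack survivor counts.
#' @param deaths_total Total deaths D to be replaced.
#' @param params A `model_params` object.
#' @return Named numeric vector `c(w_f = , w_b = )` summing to
#'   `deaths_total`.
#' @export
expected_offspring <- function(n_f_post, n_b_post, deaths_total, params) {
  if (deaths_total == 0) return(c(w_f = 0, w_b = 0))
  if (n_f_post + n_b_post < 1L)
    stop("expected_offspring: no survivors to reproduce (extinct population)",
         call. = FALSE)
  phi <- background_fitness(n_f_post, n_b_post, params)
  out_f <- n_f_post * reproductive_success(energy_reserves("F", params), params) * phi[["phi_f"]]
  out_b <- n_b_post * reproductive_success(energy_reserves("B", params), params) * phi[["phi_b"]]
  denom <- out_f + out_b
  share_f <- if (denom > 0) out_f / denom else n_f_post / (n_f_post + n_b_post)
  w_f <- deaths_total * share_f
  c(w_f = w_f, w_b = deaths_total - w_f)
}

#' Realize integer offspring counts around their expectations
#'
#' Draws `k_F ~ Binomial(deaths_total, W_F / deaths_total)` and sets
#' `k_B = deaths_total - k_F`: the simplest stochastic allocation whose
#' mean matches the expected offspring numbers exactly and whose total is
#' exactly the number of deaths.
#'
#' @param w_f Expected number of fearful offspring, in
#'   `[0, deaths_total]`.
#' @param deaths_total Total offspring to allocate.
#' @return Named integer vector `c(k_f = , k_b = )`.
#' @export
realize_offspring <- function(w_f, deaths_total) {
  deaths_total <- as.integer(deaths_total)
  if (deaths_total == 0L) return(c(k_f = 0L, k_b = 0L))
  if (w_f < 0 || w_f > deaths_total)
    stop("realize_offspring: w_f must lie in [0, deaths_total]", call. = FALSE)
  k_f <- stats::rbinom(1L, deaths_total, w_f / deaths_total)
  c(k_f = k_f, k_b = deaths_total - k_f)
}

#' Close a breeding season: reproduce, senesce, and age
#'
#' Given a state that has completed its attack sequence, computes
#' `D = kills + (post-attack individuals at age A)`; all survivors
#' (including those at age A) reproduce, then the age-A cohorts are
#' removed, every remaining survivor ages one year, and the `k_F` fearful
#' and `k_B` bold newborns enter at age 1 (offspring inherit the mother's
#' phenotype).  The returned state is a valid next-season start with total
#' population back at `n_total`.
#'
#' @param state A post-attack `population_state`.
#' @param params A `model_params` object.
#' @return The next season-start `population_state` (or the input flagged
#'   extinct when no survivors remain).
#' @export
advance_season <- function(state, params) {
  A <- params$max_age
  nf_post <- n_f(state)
  nb_post <- n_b(state)
  if (nf_post + nb_post == 0L) {
    state$extinct <- TRUE
    return(state)
  }
  seniors <- state$counts_f[A] + state$counts_b[A]
  deaths_total <- state$kills_this_season + seniors
  if (deaths_total > 0L) {
    w <- expected_offspring(nf_post, nb_post, deaths_total, params)
    k <- realize_offspring(w[["w_f"]], deaths_total)
  } else {
    k <- c(k_f = 0L, k_b = 0L)
  }
  cf <- c(k[["k_f"]], state$counts_f[-A])
  cb <- c(k[["k_b"]], state$counts_b[-A])
  population_state(cf, cb,
                   kills_this_season = 0L,
                   season_index = state$season_index + 1L)
}
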