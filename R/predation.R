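#' Probability that a phenotype group is selected at one attack
#'
#' At each attack the predator first selects one of the two phenotype
#' groups.  Under frequency-dependent risk sharing the selection weights
#' the groups by abundance, discounted by the relative selectability beta
#' of fearful individuals:
#' `P(F group) = beta * n_f / (beta * n_f + n_b)`,
#' `P(B group) = n_b / (beta * n_f + n_b)`.
#' Under frequency-independent sharing the split is fixed by beta alone,
#' regardless of population structure:
#' `P(F group) = beta / (1 + beta)`, `P(B group) = 1 / (1 + beta)`.
#'
#' @param phenotype `"F"` or `"B"`.
#' @param n_f,n_b Current phenotype counts (post previous attack).
#' @param params A `model_params` object (`beta`, `risk_mode`).
#' @return A probability in `[0, 1]`.
#' @export
group_selection_probability <- function(phenotype, n_f, n_b, params) {
  phenotype <- match.arg(phenotype, c("F", "B"))
  if (params$risk_mode == "frequency_independent") {
    pf <- params$beta / (1 + params$beta)
    return(if (phenotype == "F") pf else 1 - pf)
  }
  if (n_f + n_b < 1L)
    stop("group_selection_probability: empty population", call. = FALSE)
  denom <- params$beta * n_f + n_b
  if (denom == 0) {
    # beta = 0 with only F present: the fearful are never selected
    return(0)
  }
  if (phenotype == "F") params$beta * n_f / denom else n_b / denom
}

#' Per-capita probability that one individual is killed at one attack
#'
#' Selection of the group, uniform choice of a victim within it, and a
#' capture Bernoulli compose to the per-individual kill probability.
#' Frequency-dependent: `beta * pF / (beta * n_f + n_b)` for a fearful
#' individual, `pB / (beta * n_f + n_b)` for a bold one.
#' Frequency-independent: `(beta / (1 + beta)) * pF / n_f` and
#' `(1 / (1 + beta)) * pB / n_b`.  The two modes coincide exactly when
#' `n_f = n_b`; when one phenotype is rarer, frequency dependence shifts
#' its risk onto the commoner phenotype (risk sharing).
#'
#' @inheritParams group_selection_probability
#' @return A probability in `[0, 1]`.
#' @export
per_capita_kill_probability <- function(phenotype, n_f, n_b, params) {
  phenotype <- match.arg(phenotype, c("F", "B"))
  n_self <- if (phenotype == "F") n_f else n_b
  if (n_self < 1L)
    stop("per_capita_kill_probability: no ", phenotype,
         "-individuals present; the per-capita risk is undefined", call. = FALSE)
  p_cap <- if (phenotype == "F") params$p_capture_f else params$p_capture_b
  group_selection_probability(phenotype, n_f, n_b, params) * p_cap / n_self
}

# Group-level kill probabilities at one attack from counts (i, j) = (nF, nB).
# Vector c(P_F_kill, P_B_kill); the complement is no kill.  Shared by the
# single-attack realization and the exact DP oracle.
attack_kill_probs <- function(i, j, params) {
  if (i + j < 1L) stop("attack_kill_probs: empty population", call. = FALSE)
  if (params$risk_mode == "frequency_dependent") {
    denom <- params$beta * i + j
    if (denom == 0) return(c(0, 0))  # beta = 0, all-F population: no kills
    c(params$beta * i * params$p_capture_f / denom,
      j * params$p_capture_b / denom)
  } else {
    sel_f <- params$beta / (1 + params$beta)
    if (params$empty_group_renormalize) {
      # redirect a selection of an empty group to the other group
      if (i == 0L) sel_f <- 0
      if (j == 0L) sel_f <- 1
    }
    c(if (i > 0L) sel_f * params$p_capture_f else 0,
      if (j > 0L) (1 - sel_f) * params$p_capture_b else 0)
  }
}

# Remove one individual of `phenotype`, its age class chosen uniformly over
# that phenotype's individuals (multivariate-hypergeometric over age
# classes; the risk model is age-blind).  Consumes exactly one draw.
remove_random_individual <- function(state, phenotype) {
  counts <- if (phenotype == "F") state$counts_f else state$counts_b
  tot <- sum(counts)
  v <- runif_int(1L, tot)                 # victim index among the phenotype
  age <- findInterval(v - 1L, cumsum(counts)) + 1L
  counts[age] <- counts[age] - 1L
  if (phenotype == "F") state$counts_f <- counts else state$counts_b <- counts
  state
}

#' Simulate one predatory attack
#'
#' Realizes a single attack as (select group) -> (capture Bernoulli) ->
#' (choose victim uniformly within the group): at most one individual dies
#' per attack.  In frequency-independent mode a selection of an empty group
#' makes the attack fail (unless `empty_group_renormalize` is set).
#'
#' Consumes the global random stream in a fixed draw order (selection,
#' capture, victim) shared with the compiled engine.
#'
#' @param state A `population_state`.
#' @param params A `model_params` object.
#' @return The updated `population_state`.
#' @export
simulate_attack <- function(state, params) {
  i <- n_f(state)
  j <- n_b(state)
  if (i + j < 1L)
    stop("simulate_attack: empty population", call. = FALSE)
  p_sel_f <- if (params$risk_mode == "frequency_dependent") {
    d <- params$beta * i + j
    if (d == 0) 0 else params$beta * i / d
  } else {
    sf <- params$beta / (1 + params$beta)
    if (params$empty_group_renormalize) {
      if (i == 0L) sf <- 0
      if (j == 0L) sf <- 1
    }
    sf
  }
  u_sel <- stats::runif(1L)
  phenotype <- if (u_sel < p_sel_f) "F" else "B"
  n_sel <- if (phenotype == "F") i else j
  if (n_sel == 0L) return(state)          # empty group: the attack fails
  p_cap <- if (phenotype == "F") params$p_capture_f else params$p_capture_b
  u_cap <- stats::runif(1L)
  if (u_cap >= p_cap) return(state)       # escape
  state <- remove_random_individual(state, phenotype)
  state$kills_this_season <- state$kills_this_season + 1L
  state
}

#' Run the full attack sequence of one season
#'
#' Applies [simulate_attack()] `n_attacks` times in order; the selection
#' probabilities at attack k+1 use the counts left after attack k.  If the
#' population empties mid-sequence the remaining attacks are skipped and
#' the state is flagged extinct.
#'
#' @inheritParams simulate_attack
#' @return The post-attack `population_state`.
#' @export
run_attack_sequence <- function(state, params) {
  for (k in seq_len(params$n_attacks)) {
    if (n_f(state) + n_b(state) == 0L) {
      state$extinct <- TRUE
      return(state)
    }
    state <- simulate_attack(state, params)
  }
  if (n_f(state) + n_b(state) == 0L) state$extinct <- TRUE
  state
}
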