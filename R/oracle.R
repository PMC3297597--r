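#' Exact distribution of post-attack counts within one season
#'
#' Enumerates the sequential single-victim attack process by dynamic
#' programming: starting from counts `(n_f, n_b)`, each of the
#' `params$n_attacks` attacks kills one fearful individual, one bold
#' individual, or nobody, with the group-level probabilities implied by
#' the selection/capture model evaluated at the counts left by the
#' previous attack.
#'
#' @param n_f,n_b Season-start counts.
#' @param params A `model_params` object.
#' @return A numeric matrix of probabilities with rows indexed by
#'   `n_f' = 0..n_f` and columns by `n_b' = 0..n_b` (dimnames give the
#'   counts); entries sum to 1.
#' @export
attack_outcome_distribution <- function(n_f, n_b, params) {
  validate_params(params)
  if (n_f + n_b < 1L)
    stop("attack_outcome_distribution: empty population", call. = FALSE)
  # P[i+1, j+1] = probability of being at counts (i, j)
  P <- matrix(0, nrow = n_f + 1L, ncol = n_b + 1L,
              dimnames = list(n_f = 0:n_f, n_b = 0:n_b))
  P[n_f + 1L, n_b + 1L] <- 1
  for (k in seq_len(params$n_attacks)) {
    Q <- matrix(0, nrow = n_f + 1L, ncol = n_b + 1L, dimnames = dimnames(P))
    for (i in 0:n_f) for (j in 0:n_b) {
      p <- P[i + 1L, j + 1L]
      if (p == 0) next
      if (i + j == 0L) {           # empty: nothing more can happen
        Q[1L, 1L] <- Q[1L, 1L] + p
        next
      }
      kp <- attack_kill_probs(i, j, params)
      Q[i + 1L, j + 1L] <- Q[i + 1L, j + 1L] + p * (1 - kp[1L] - kp[2L])
      if (kp[1L] > 0) Q[i, j + 1L] <- Q[i, j + 1L] + p * kp[1L]
      if (kp[2L] > 0) Q[i + 1L, j] <- Q[i + 1L, j] + p * kp[2L]
    }
    P <- Q
  }
  P
}

#' Exact one-season transition kernel for the non-overlapping limit
#'
#' With `max_age = 1` every survivor reaches its maximum age at season end,
#' so all N individuals are replaced each season and the season-start state
#' is fully described by the fearful count `n_f`.  The kernel composes the
#' exact attack distribution ([attack_outcome_distribution()]) with the
#' binomial offspring realization: given post-attack counts `(i, j)`, the
#' next fearful count is `Binomial(N, W_F / N)` with `W_F` the
#' competition-weighted expected fearful offspring.
#'
#' If `n_attacks >= n_total` the population can empty mid-season; that
#' probability mass is returned in the `"p_extinct"` attribute (one entry
#' per row) and the corresponding rows sum to `1 - p_extinct`.
#'
#' @param params A `model_params` object with `max_age = 1`.
#' @return An `(N+1) x (N+1)` row-stochastic matrix over
#'   `n_f = 0..N`, with attribute `p_extinct`.
#' @export
season_transition_kernel <- function(params) {
  validate_params(params)
  if (params$max_age != 1L)
    stop("season_transition_kernel: exact kernel is defined only for max_age = 1",
         call. = FALSE)
  N <- params$n_total
  fx_f <- reproductive_success(energy_reserves("F", params), params)
  fx_b <- reproductive_success(energy_reserves("B", params), params)
  K <- matrix(0, nrow = N + 1L, ncol = N + 1L,
              dimnames = list(n_f = 0:N, n_f_next = 0:N))
  p_extinct <- numeric(N + 1L)
  for (nf0 in 0:N) {
    nb0 <- N - nf0
    dist <- attack_outcome_distribution(nf0, nb0, params)
    for (i in 0:nf0) for (j in 0:nb0) {
      q <- dist[i + 1L, j + 1L]
      if (q == 0) next
      if (i + j == 0L) {
        p_extinct[nf0 + 1L] <- p_extinct[nf0 + 1L] + q
        next
      }
      # D = kills + seniors = (N - i - j) + (i + j) = N: total replacement
      phi <- background_fitness(i, j, params)
      out_f <- i * fx_f * phi[["phi_f"]]
      out_b <- j * fx_b * phi[["phi_b"]]
      den <- out_f + out_b
      share <- if (den > 0) out_f / den else i / (i + j)
      K[nf0 + 1L, ] <- K[nf0 + 1L, ] + q * stats::dbinom(0:N, N, share)
    }
  }
  attr(K, "p_extinct") <- p_extinct
  K
}

#' Exact fixation probabilities for small non-overlapping populations
#'
#' Solves the absorbing-Markov-chain linear system on the exact one-season
#' kernel: `rho(n_f)` is the probability that a population started with
#' `n_f` fearful individuals eventually fixes to pure fearfulness.  States
#' 0 and N are absorbing (competition must be off); any extinction mass is
#' treated as an absorbing failure (a run that never reaches fearful
#' fixation).  This is the exact counterpart of the quantity the
#' run-to-fixation replicates estimate, and the simulator's primary
#' verification oracle.
#'
#' @param params A `model_params` object with `max_age = 1` and
#'   `competition = NULL`.
#' @return Numeric vector `rho` of length N+1, named by `n_f = 0..N`, with
#'   `rho[1] = 0` and `rho[N+1] = 1`.
#' @export
exact_fixation_probability <- function(params) {
  validate_params(params)
  if (!is.null(params$competition))
    stop("exact_fixation_probability: requires competition off (absorbing states)",
         call. = FALSE)
  if (params$max_age != 1L)
    stop("exact_fixation_probability: exact solve is defined only for max_age = 1",
         call. = FALSE)
  N <- params$n_total
  K <- season_transition_kernel(params)
  trans <- 2:N                    # interior states n_f = 1..N-1
  Q <- K[trans, trans, drop = FALSE]
  r <- K[trans, N + 1L]           # one-step absorption into n_f = N
  rho_int <- solve(diag(length(trans)) - Q, r)
  rho <- c(0, rho_int, 1)
  names(rho) <- 0:N
  rho
}
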