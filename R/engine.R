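#' Run one full breeding season
#'
#' Composition of the within-season steps: the sequential attack sequence
#' ([run_attack_sequence()]) followed by reproduction, senescence and
#' ageing ([advance_season()]).  Deterministic given the state, the
#' parameters and the position of the global random stream.
#'
#' @param state A season-start `population_state`.
#' @param params A `model_params` object.
#' @return The next season-start `population_state` (possibly flagged
#'   extinct).
#' @export
run_season <- function(state, params) {
  state <- run_attack_sequence(state, params)
  if (state$extinct) return(state)
  advance_season(state, params)
}

outcome_levels <- c("F_fixed", "B_fixed", "timeout", "extinct")

#' Run one replicate until fixation, timeout, or extinction
#'
#' Seeds its own random stream from `(base_seed, replicate_index)` via
#' [replicate_seed()], draws the initial state, and iterates seasons until
#' the population becomes a pure-strategy population (fearful fixation
#' `n_b = 0`, bold fixation `n_f = 0`), the `max_seasons` cap is hit
#' (timeout), or the population empties (extinct).
#'
#' The default engine is compiled; `engine = "r"` runs the season loop
#' through the R-level operations instead.  Both engines consume the
#' random stream identically, so the trajectories are bit-identical —
#' the R path is the readable reference, the compiled path the fast one.
#'
#' @param params A `model_params` object.
#' @param replicate_index 1-based replicate counter (seeds the stream).
#' @param engine `"cpp"` (default) or `"r"`.
#' @param record_trajectory If `TRUE`, record `(season, n_f, n_b)` each
#'   season (R engine only for the full per-season record).
#' @return A list of class `replicate_result`: `outcome` (one of
#'   `"F_fixed"`, `"B_fixed"`, `"timeout"`, `"extinct"`),
#'   `seasons_elapsed`, `n_f_final`, and optionally `trajectory`.
#' @export
run_replicate <- function(params, replicate_index = 1L,
                          engine = c("cpp", "r"),
                          record_trajectory = FALSE) {
  engine <- match.arg(engine)
  validate_params(params)
  set.seed(replicate_seed(params$base_seed, replicate_index))
  if (engine == "cpp" && !record_trajectory) {
    res <- cpp_run_replicate(params_for_cpp(params))
    out <- list(outcome = outcome_levels[res$outcome + 1L],
                seasons_elapsed = res$seasons,
                n_f_final = res$n_f_final)
    class(out) <- "replicate_result"
    return(out)
  }
  state <- initial_state(params)
  traj <- if (record_trajectory)
    list(c(state$season_index, n_f(state), n_b(state))) else NULL
  repeat {
    nf <- n_f(state)
    nb <- n_b(state)
    if (nf + nb == 0L || state$extinct) {
      outcome <- "extinct"
      break
    }
    if (nb == 0L) { outcome <- "F_fixed"; break }
    if (nf == 0L) { outcome <- "B_fixed"; break }
    if (state$season_index >= params$max_seasons) { outcome <- "timeout"; break }
    state <- run_season(state, params)
    if (record_trajectory)
      traj[[length(traj) + 1L]] <- c(state$season_index, n_f(state), n_b(state))
  }
  out <- list(outcome = outcome,
              seasons_elapsed = state$season_index,
              n_f_final = n_f(state))
  if (record_trajectory) {
    m <- do.call(rbind, traj)
    out$trajectory <- data.frame(season = m[, 1], n_f = m[, 2], n_b = m[, 3])
  }
  class(out) <- "replicate_result"
  out
}

#' @export
print.replicate_result <- function(x, ...) {
  cat(sprintf("Replicate outcome: %s after %d season(s) (final n_f = %d)\n",
              x$outcome, x$seasons_elapsed, x$n_f_final))
  invisible(x)
}

# Wilson 95% score interval for a binomial proportion
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0L) return(c(low = NA_real_, high = NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(low = max(0, ctr - hw), high = min(1, ctr + hw))
}

#' Estimate the fixation frequency of fearfulness
#'
#' Runs `n_replicates` independent run-to-fixation replicates and reports
#' `rho_f`, the fraction of replicates in which the population fixes to
#' pure fearfulness, with a 95% Wilson binomial confidence interval.
#' Timed-out and extinct replicates are counted and reported separately;
#' they are never folded into `rho_f` (which keeps `rho_f` the fraction of
#' all replicates that reached fearful fixation).
#'
#' @param params A `model_params` object (`base_seed` roots the replicate
#'   streams).
#' @param n_replicates Number of replicates; defaults to
#'   `params$n_replicates` (protocol default 1000).
#' @param engine `"cpp"` (default) or `"r"`.
#' @return An object of class `fixation_estimate`.
#' @export
estimate_fixation_frequency <- function(params,
                                        n_replicates = params$n_replicates,
                                        engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  validate_params(params)
  n_replicates <- as.integer(n_replicates)
  tallies <- c(F_fixed = 0L, B_fixed = 0L, timeout = 0L, extinct = 0L)
  seasons <- numeric(n_replicates)
  if (engine == "cpp") {
    cp <- params_for_cpp(params)
    for (i in seq_len(n_replicates)) {
      set.seed(replicate_seed(params$base_seed, i))
      res <- cpp_run_replicate(cp)
      oc <- outcome_levels[res$outcome + 1L]
      tallies[[oc]] <- tallies[[oc]] + 1L
      seasons[i] <- res$seasons
    }
  } else {
    for (i in seq_len(n_replicates)) {
      res <- run_replicate(params, i, engine = "r")
      tallies[[res$outcome]] <- tallies[[res$outcome]] + 1L
      seasons[i] <- res$seasons_elapsed
    }
  }
  rho_f <- tallies[["F_fixed"]] / n_replicates
  ci <- wilson_ci(tallies[["F_fixed"]], n_replicates)
  structure(
    list(n_replicates = n_replicates,
         n_f_fixed = tallies[["F_fixed"]],
         n_b_fixed = tallies[["B_fixed"]],
         n_timeout = tallies[["timeout"]],
         n_extinct = tallies[["extinct"]],
         rho_f = rho_f,
         ci_low = ci[["low"]],
         ci_high = ci[["high"]],
         mean_seasons = mean(seasons),
         params = params),
    class = "fixation_estimate"
  )
}

#' @export
print.fixation_estimate <- function(x, ...) {
  cat("Fixation-frequency estimate (fearfulness)\n")
  cat(sprintf("  rho_F = %.4f  [95%% Wilson CI %.4f, %.4f]  from %d replicates\n",
              x$rho_f, x$ci_low, x$ci_high, x$n_replicates))
  cat(sprintf("  outcomes: %d F-fixed, %d B-fixed, %d timeout, %d extinct; mean %.1f seasons\n",
              x$n_f_fixed, x$n_b_fixed, x$n_timeout, x$n_extinct,
              x$mean_seasons))
  invisible(x)
}

#' @export
summary.fixation_estimate <- function(object, ...) {
  print(object)
  cat("\nScenario:\n")
  print(object$params)
  invisible(object)
}

#' Run a fixed-length coexistence trajectory experiment
#'
#' With background fitness enabled, runs exactly `n_seasons` seasons
#' without stopping at fixation (if one phenotype fixes, the run continues
#' with its frequency pegged) and records the fearful frequency each
#' season.  Reports the mean and standard deviation of the fearful
#' frequency over the trailing `window` seasons — the fluctuation
#' strength — and whether both phenotypes are still present at the end
#' (`persisted`).  An extinct population terminates the trajectory early
#' with `persisted = FALSE`.
#'
#' @param params A `model_params` object with `competition` set.
#' @param n_seasons Number of seasons to run (`>= window`).
#' @param window Trailing window length for the summary statistics
#'   (default 100 seasons).
#' @param replicate_index Seeds the stream via [replicate_seed()].
#' @param engine `"cpp"` (default) or `"r"`.
#' @return An object of class `coexistence_experiment` with elements
#'   `trajectory` (data frame `season`, `n_f`, `n_b`, `freq_f`) and the
#'   summary fields `mean_freq_f_window`, `sd_freq_f_window`, `window`,
#'   `persisted`, `seasons_run`.
#' @export
run_coexistence_experiment <- function(params, n_seasons, window = 100L,
                                       replicate_index = 1L,
                                       engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  validate_params(params)
  if (is.null(params$competition))
    stop("run_coexistence_experiment: competition (background fitness) must be enabled",
         call. = FALSE)
  n_seasons <- as.integer(n_seasons)
  window <- as.integer(window)
  if (window < 1L || window > n_seasons)
    stop("run_coexistence_experiment: need 1 <= window <= n_seasons", call. = FALSE)
  set.seed(replicate_seed(params$base_seed, replicate_index))
  if (engine == "cpp") {
    res <- cpp_run_trajectory(params_for_cpp(params), n_seasons)
    nf <- res$n_f
    nb <- res$n_b
  } else {
    state <- initial_state(params)
    nf <- integer(0)
    nb <- integer(0)
    for (t in seq_len(n_seasons)) {
      state <- run_season(state, params)
      if (state$extinct) break
      nf <- c(nf, n_f(state))
      nb <- c(nb, n_b(state))
    }
  }
  seasons_run <- length(nf)
  freq <- if (seasons_run > 0L) nf / (nf + nb) else numeric(0)
  extinct <- seasons_run < n_seasons
  persisted <- !extinct && seasons_run > 0L &&
    nf[seasons_run] > 0L && nb[seasons_run] > 0L
  w <- min(window, max(seasons_run, 1L))
  tail_idx <- if (seasons_run > 0L) seq(seasons_run - w + 1L, seasons_run) else integer(0)
  structure(
    list(trajectory = data.frame(season = seq_len(seasons_run),
                                 n_f = nf, n_b = nb, freq_f = freq),
         mean_freq_f_window = if (length(tail_idx)) mean(freq[tail_idx]) else NA_real_,
         sd_freq_f_window = if (length(tail_idx) > 1L) stats::sd(freq[tail_idx]) else NA_real_,
         window = window,
         persisted = persisted,
         seasons_run = seasons_run,
         params = params),
    class = "coexistence_experiment"
  )
}

#' @export
print.coexistence_experiment <- function(x, ...) {
  cat("Coexistence trajectory experiment\n")
  cat(sprintf("  %d season(s) run; persisted (both phenotypes at end): %s\n",
              x$seasons_run, x$persisted))
  cat(sprintf("  fearful frequency over last %d season(s): mean %.4f, sd %.4f\n",
              min(x$window, x$seasons_run), x$mean_freq_f_window,
              x$sd_freq_f_window))
  invisible(x)
}

#' @export
plot.coexistence_experiment <- function(x, ...) {
  plot(x$trajectory$season, x$trajectory$freq_f, type = "l",
       xlab = "season", ylab = "fearful frequency", ylim = c(0, 1), ...)
  graphics::abline(h = x$mean_freq_f_window, lty = 2, col = "grey40")
  invisible(x)
}

#' Simulate replicates from a parameter set
#'
#' `simulate()` method for `model_params`: runs `nsim` run-to-fixation
#' replicates and returns their outcomes as a data frame.
#'
#' @param object A `model_params` object.
#' @param nsim Number of replicates.
#' @param seed Optional override of `object$base_seed`.
#' @param ... Unused.
#' @return A data frame with one row per replicate: `replicate`, `outcome`,
#'   `seasons_elapsed`, `n_f_final`.
#' @export
simulate.model_params <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) object$base_seed <- as.integer(seed)
  rows <- lapply(seq_len(nsim), function(i) {
    r <- run_replicate(object, i)
    data.frame(replicate = i, outcome = r$outcome,
               seasons_elapsed = r$seasons_elapsed, n_f_final = r$n_f_final)
  })
  do.call(rbind, rows)
}

# Flatten params to the plain list the compiled engine expects.
params_for_cpp <- function(params) {
  cp <- params$competition
  list(
    n_total = params$n_total,
    max_age = params$max_age,
    n_attacks = params$n_attacks,
    beta = params$beta,
    p_capture_f = params$p_capture_f,
    p_capture_b = params$p_capture_b,
    x_f = energy_reserves("F", params),
    x_b = energy_reserves("B", params),
    repro_scale = params$repro_scale,
    repro_exponent = params$repro_exponent,
    freq_dependent = params$risk_mode == "frequency_dependent",
    empty_group_renormalize = params$empty_group_renormalize,
    has_competition = !is.null(cp),
    r_f = if (is.null(cp)) 1 else cp$r_f,
    r_b = if (is.null(cp)) 1 else cp$r_b,
    a_ff = if (is.null(cp)) 0 else cp$a_ff,
    a_fb = if (is.null(cp)) 0 else cp$a_fb,
    a_bf = if (is.null(cp)) 0 else cp$a_bf,
    a_bb = if (is.null(cp)) 0 else cp$a_bb,
    init_freq_f = params$init_freq_f,
    ages_uniform = params$init_age_distribution == "uniform",
    max_seasons = params$max_seasons
  )
}
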