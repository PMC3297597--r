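test_that("replicates at absorbing starts terminate immediately", {
  r0 <- run_replicate(tpar(init_freq_f = 0), 1)
  expect_identical(r0$outcome, "B_fixed")
  expect_identical(r0$seasons_elapsed, 0L)
  r1 <- run_replicate(tpar(init_freq_f = 1), 1)
  expect_identical(r1$outcome, "F_fixed")
  expect_identical(r1$seasons_elapsed, 0L)
})

test_that("replicates are deterministic in (base_seed, replicate_index)", {
  p <- tpar(n_total = 20L, base_seed = 77L)
  a <- run_replicate(p, 3)
  b <- run_replicate(p, 3)
  expect_identical(a, b)
  # distinct replicate indices get distinct derived seeds
  seeds <- vapply(1:500, function(i) replicate_seed(77L, i), integer(1))
  expect_identical(anyDuplicated(seeds), 0L)
  expect_true(all(seeds >= 0 & seeds < 2^31))
})

test_that("compiled and R reference engines are bit-identical", {
  configs <- list(
    tpar(n_total = 12L, max_age = 1L),
    tpar(n_total = 15L, max_age = 4L, n_attacks = 5L),
    tpar(n_total = 9L, risk_mode = "frequency_independent", beta = 0.2),
    tpar(n_total = 14L, init_age_distribution = "all_youngest",
         p_capture_b = 1, beta = 1),
    tpar(n_total = 20L, max_age = 2L,
         competition = competition_params(2, 2, .004, .005, .001, .007),
         max_seasons = 200L)
  )
  for (p in configs) for (i in 1:10) {
    a <- run_replicate(p, i, engine = "r")
    b <- run_replicate(p, i, engine = "cpp")
    expect_identical(a$outcome, b$outcome)
    expect_identical(a$seasons_elapsed, b$seasons_elapsed)
    expect_equal(a$n_f_final, b$n_f_final)
  }
})

test_that("fixation states are absorbing without competition", {
  p <- tpar(n_total = 8L, max_age = 3L, n_attacks = 4L)
  for (i in 1:20) {
    r <- run_replicate(p, i, engine = "r", record_trajectory = TRUE)
    tr <- r$trajectory
    hitF <- which(tr$n_b == 0)
    hitB <- which(tr$n_f == 0)
    if (length(hitF)) expect_true(all(tr$n_b[seq(min(hitF), nrow(tr))] == 0))
    if (length(hitB)) expect_true(all(tr$n_f[seq(min(hitB), nrow(tr))] == 0))
  }
})

test_that("timeouts are reported separately, never as fixations", {
  p <- tpar(n_total = 40L, max_seasons = 2L, energy_cost_escape = 0,
            beta = 1, p_capture_f = 0.05, p_capture_b = 0.05)
  est <- estimate_fixation_frequency(p, n_replicates = 50)
  expect_identical(est$n_timeout, 50L)
  expect_identical(est$rho_f, 0)
  expect_identical(est$n_f_fixed + est$n_b_fixed + est$n_timeout +
                   est$n_extinct, est$n_replicates)
})

test_that("fixation estimates recover trivial and neutral expectations", {
  est1 <- estimate_fixation_frequency(tpar(init_freq_f = 1), n_replicates = 20)
  expect_identical(est1$rho_f, 1)
  expect_lte(est1$ci_high, 1)
  expect_gte(1, est1$ci_low)

  # the protocol default replicate count
  expect_identical(tpar()$n_replicates, 1000L)

  # exchangeable phenotypes: fixation frequency equals the initial proportion
  pn <- tpar(n_total = 10L, max_age = 1L, n_attacks = 3L, beta = 1,
             p_capture_f = 0.3, p_capture_b = 0.3, energy_cost_escape = 0,
             init_freq_f = 0.5, base_seed = 2025L)
  est <- estimate_fixation_frequency(pn, n_replicates = 2000)
  sigma <- sqrt(0.25 / 2000)
  expect_lt(abs(est$rho_f - 0.5), 4 * sigma)
})

test_that("one-season fearful-count distribution matches the exact kernel", {
  p <- tpar(n_total = 4L, max_age = 1L, n_attacks = 2L, beta = 0.5,
            p_capture_f = 0.2, p_capture_b = 0.6, init_freq_f = 0.5,
            init_age_distribution = "all_youngest")
  K <- season_transition_kernel(p)
  expected <- K[3L, ]  # row n_f = 2
  n <- 50000L
  counts <- integer(5)
  cp <- fearbold:::params_for_cpp(p)
  for (i in seq_len(n)) {
    set.seed(replicate_seed(880L, i))
    s <- initial_state(p)
    s <- run_season(s, p)
    counts[n_f(s) + 1L] <- counts[n_f(s) + 1L] + 1L
  }
  for (k in 1:5) {
    sigma <- sqrt(n * expected[k] * (1 - expected[k]))
    expect_lt(abs(counts[k] - n * expected[k]), 4 * sigma + 1e-9)
  }
})

test_that("coexistence runs have fixed length, windowed statistics and a persistence flag", {
  cp <- competition_params(2, 2, .005, .006, .0005, .008)
  p <- tpar(n_total = 60L, max_age = 5L, n_attacks = 10L,
            n_disturbances = 10L, beta = 0.1, p_capture_f = 0.2,
            p_capture_b = 0.9, energy_gain = 8, energy_cost_escape = 0.05,
            competition = cp, base_seed = 5L)
  cx <- run_coexistence_experiment(p, n_seasons = 120, window = 40)
  expect_identical(nrow(cx$trajectory), cx$seasons_run)
  expect_true(cx$seasons_run <= 120L)
  expect_true(all(cx$trajectory$n_f + cx$trajectory$n_b == 60L))

  # degenerate window covers the whole trajectory
  cx2 <- run_coexistence_experiment(p, n_seasons = 50, window = 50)
  expect_equal(cx2$mean_freq_f_window, mean(cx2$trajectory$freq_f))

  expect_error(run_coexistence_experiment(p, n_seasons = 10, window = 20),
               "window")
  expect_error(run_coexistence_experiment(tpar(), n_seasons = 50),
               "competition")

  # all-zero coefficients with r_f = r_b reduce to a constant rescaling:
  # same seed, same trajectory as a plain competition-off run
  cp0 <- competition_params(2, 2, 0, 0, 0, 0)
  pa <- tpar(n_total = 30L, competition = cp0, base_seed = 9L)
  cxa <- run_coexistence_experiment(pa, n_seasons = 60, window = 10)
  pb <- tpar(n_total = 30L, base_seed = 9L)
  set.seed(replicate_seed(9L, 1L))
  sb <- initial_state(pb)
  nfb <- integer(0)
  for (t in 1:60) {
    sb <- run_season(sb, pb)
    if (sb$extinct) break
    nfb <- c(nfb, n_f(sb))
  }
  expect_identical(cxa$trajectory$n_f, nfb)
})

test_that("simulate() returns one outcome row per replicate", {
  d <- simulate(tpar(n_total = 8L), nsim = 5, seed = 123)
  expect_identical(nrow(d), 5L)
  expect_true(all(d$outcome %in% c("F_fixed", "B_fixed", "timeout", "extinct")))
})
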