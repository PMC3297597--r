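test_that("group selection probabilities follow the risk-sharing model", {
  p <- tpar(beta = 0.5)
  expect_equal(group_selection_probability("F", 10, 20, p), 5 / 25)
  expect_equal(group_selection_probability("B", 10, 20, p), 20 / 25)
  expect_equal(group_selection_probability("F", 0, 20, p), 0)

  pi <- tpar(beta = 1, risk_mode = "frequency_independent")
  expect_equal(group_selection_probability("F", 3, 97, pi), 0.5)
  expect_equal(group_selection_probability("B", 97, 3, pi), 0.5)

  expect_error(group_selection_probability("F", 0, 0, p), "empty")
})

test_that("per-capita kill probabilities match the closed forms", {
  p1 <- tpar(beta = 1, p_capture_f = 0.5)
  expect_equal(per_capita_kill_probability("F", 10, 10, p1), 0.5 / 20)

  # the two risk modes coincide exactly at n_f = n_b
  pd <- tpar(beta = 0.5, p_capture_b = 0.8)
  pi <- tpar(beta = 0.5, p_capture_b = 0.8, risk_mode = "frequency_independent")
  expect_equal(per_capita_kill_probability("B", 5, 5, pd), 0.8 / 7.5)
  expect_equal(per_capita_kill_probability("B", 5, 5, pi),
               per_capita_kill_probability("B", 5, 5, pd))

  expect_error(per_capita_kill_probability("F", 0, 5, p1), "no F")
})

test_that("risk sharing shifts risk onto the commoner phenotype", {
  # frequency-dependent F risk < frequency-independent F risk iff n_f < n_b,
  # brute-forced over all small-count combinations and a parameter grid
  for (beta in c(0.1, 0.5, 1)) for (pf in c(0.3, 0.9)) {
    pd <- tpar(beta = beta, p_capture_f = pf)
    pi <- tpar(beta = beta, p_capture_f = pf,
               risk_mode = "frequency_independent")
    for (nf in 1:12) for (nb in 0:12) {
      dep <- per_capita_kill_probability("F", nf, nb, pd)
      ind <- per_capita_kill_probability("F", nf, nb, pi)
      if (nf < nb) expect_lt(dep, ind)
      else if (nf == nb) expect_equal(dep, ind)
      else expect_gt(dep, ind)
    }
  }
})

test_that("per-attack outcome probabilities normalize and dilution holds", {
  for (mode in c("frequency_dependent", "frequency_independent")) {
    p <- tpar(beta = 0.4, p_capture_f = 0.7, p_capture_b = 0.9,
              risk_mode = mode)
    for (nf in 0:6) for (nb in 0:6) {
      if (nf + nb == 0) next
      kp <- fearbold:::attack_kill_probs(nf, nb, p)
      expect_true(all(kp >= 0))
      expect_lte(sum(kp), 1 + 1e-12)
    }
  }
  # frequency-dependent per-capita F risk is non-increasing in n_b
  p <- tpar(beta = 0.3, p_capture_f = 0.6)
  risks <- sapply(0:20, function(nb) per_capita_kill_probability("F", 4, nb, p))
  expect_true(all(diff(risks) <= 0))
})

test_that("single attacks realize the analytic trinomial distribution", {
  p <- tpar(n_total = 5L, max_age = 1L, beta = 0.5,
            p_capture_f = 0.2, p_capture_b = 0.6)
  s0 <- population_state(counts_f = 3L, counts_b = 2L)
  # analytic: P(F kill) = 0.5*3*0.2/3.5, P(B kill) = 2*0.6/3.5
  pF <- 0.3 / 3.5
  pB <- 1.2 / 3.5
  n <- 100000L
  set.seed(2024)
  tally <- c(none = 0L, f = 0L, b = 0L)
  for (k in seq_len(n)) {
    s1 <- simulate_attack(s0, p)
    d <- c(n_f(s0) - n_f(s1), n_b(s0) - n_b(s1))
    idx <- if (d[1] == 1L) "f" else if (d[2] == 1L) "b" else "none"
    tally[idx] <- tally[idx] + 1L
  }
  for (pair in list(c(tally[["f"]], pF), c(tally[["b"]], pB),
                    c(tally[["none"]], 1 - pF - pB))) {
    sigma <- sqrt(pair[2] * (1 - pair[2]) * n)
    expect_lt(abs(pair[1] - n * pair[2]), 4 * sigma)
  }
})

test_that("attack sequences respect boundary cases", {
  p0 <- tpar(n_attacks = 0L)
  set.seed(5)
  s <- initial_state(p0)
  expect_identical(run_attack_sequence(s, p0), s)

  # zero capture probability: counts never change
  pz <- tpar(p_capture_f = 0, p_capture_b = 0, n_attacks = 6L)
  set.seed(6)
  s <- initial_state(pz)
  s2 <- run_attack_sequence(s, pz)
  expect_identical(s2$counts_f, s$counts_f)
  expect_identical(s2$counts_b, s$counts_b)

  # certain capture with only F present: one death per attack
  pc <- tpar(n_total = 4L, init_freq_f = 1, p_capture_f = 1, p_capture_b = 1,
             n_attacks = 3L, init_age_distribution = "all_youngest")
  set.seed(7)
  s3 <- run_attack_sequence(initial_state(pc), pc)
  expect_identical(n_f(s3), 1L)
  expect_identical(s3$kills_this_season, 3L)

  # attacks exceeding the population: extinction is flagged, not an error
  pe <- tpar(n_total = 2L, max_age = 1L, p_capture_f = 1, p_capture_b = 1,
             beta = 1, n_attacks = 5L)
  set.seed(8)
  s4 <- run_attack_sequence(initial_state(pe), pe)
  expect_true(s4$extinct)
  expect_identical(n_f(s4) + n_b(s4), 0L)
})
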