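test_that("energy reserves reflect escapes from attacks and disturbances", {
  p <- tpar(energy_gain = 10, energy_cost_escape = 1, n_attacks = 3L,
            n_disturbances = 2L)
  expect_equal(energy_reserves("F", p), 5)   # e0 - (a + d) c
  expect_equal(energy_reserves("B", p), 7)   # e0 - a c

  p0 <- tpar(energy_cost_escape = 0)
  expect_equal(energy_reserves("F", p0), energy_reserves("B", p0))

  # clipping at zero
  pc <- tpar(energy_gain = 3, energy_cost_escape = 1, n_attacks = 2L,
             n_disturbances = 2L)
  expect_equal(energy_reserves("F", pc), 0)
})

test_that("reproductive success is proportional to reserves and rejects negatives", {
  p <- tpar(repro_scale = 1)
  expect_equal(reproductive_success(5, p), 5)
  expect_equal(reproductive_success(0, p), 0)
  expect_error(reproductive_success(-1, p), "negative")
})

test_that("background fitness follows the Lotka-Volterra form", {
  expect_equal(background_fitness(17, 29, tpar()), c(phi_f = 1, phi_b = 1))

  cp <- competition_params(r_f = 2, r_b = 2, a_ff = 0.01, a_fb = 0.01,
                           a_bf = 0.005, a_bb = 0.02)
  p <- tpar(competition = cp)
  expect_equal(background_fitness(50, 50, p)[["phi_f"]], 2 - 1)
  # clipping at zero
  cp2 <- competition_params(r_f = 1, r_b = 1, a_ff = 0.1, a_fb = 0,
                            a_bf = 0, a_bb = 0)
  expect_equal(background_fitness(20, 0, tpar(competition = cp2))[["phi_f"]], 0)
})

test_that("expected offspring split deaths by reproductive output", {
  # full symmetry: equal counts, equal reserves -> half each
  p <- tpar(energy_cost_escape = 0)
  expect_equal(expected_offspring(7, 7, 4, p), c(w_f = 2, w_b = 2))

  # boundary: one phenotype absent
  expect_equal(expected_offspring(5, 0, 3, p)[["w_f"]], 3)

  # direct substitution: f(x_F) = 5, f(x_B) = 7, counts 10/30, D = 8
  ps <- tpar(energy_gain = 7.5, energy_cost_escape = 0.5, n_attacks = 1L,
             n_disturbances = 4L)  # x_F = 7.5 - 5*0.5 = 5, x_B = 7
  expect_equal(expected_offspring(10, 30, 8, ps)[["w_f"]], 8 * 50 / 260)

  # shares invariant to repro_scale
  ps2 <- tpar(energy_gain = 7.5, energy_cost_escape = 0.5, n_attacks = 1L,
              n_disturbances = 4L, repro_scale = 17)
  expect_equal(expected_offspring(10, 30, 8, ps2), expected_offspring(10, 30, 8, ps))

  expect_error(expected_offspring(0, 0, 3, p), "extinct")
})

test_that("offspring realization is an exact-total binomial around W_F", {
  expect_identical(realize_offspring(0, 0), c(k_f = 0L, k_b = 0L))
  set.seed(31)
  expect_equal(realize_offspring(5, 5), c(k_f = 5, k_b = 0))
  set.seed(31)
  draws <- replicate(100000, realize_offspring(1.5385, 8)[["k_f"]])
  expect_true(all(draws >= 0 & draws <= 8))
  sigma <- sqrt(8 * (1.5385 / 8) * (1 - 1.5385 / 8))
  expect_lt(abs(mean(draws) - 1.5385), 4 * sigma / sqrt(100000))
  expect_error(realize_offspring(9, 8), "w_f")
})

test_that("advance_season bookkeeping matches hand enumeration", {
  # A = 2; post-attack F = (0, 2) after one kill of an age-2 F, B absent:
  # D = 1 kill + 2 seniors = 3; all newborns fearful; totals conserved
  p <- tpar(n_total = 3L, max_age = 2L)
  s <- population_state(counts_f = c(0L, 2L), counts_b = c(0L, 0L),
                        kills_this_season = 1L, season_index = 4L)
  set.seed(11)
  nxt <- advance_season(s, p)
  expect_identical(nxt$counts_f, c(3L, 0L))
  expect_identical(sum(nxt$counts_b), 0L)
  expect_identical(n_f(nxt) + n_b(nxt), 3L)
  expect_identical(nxt$season_index, 5L)
  expect_identical(nxt$kills_this_season, 0L)

  # quiescent season: no kills, no seniors -> the population merely ages
  pq <- tpar(n_total = 4L, max_age = 3L)
  sq <- population_state(counts_f = c(1L, 1L, 0L), counts_b = c(2L, 0L, 0L))
  set.seed(12)
  nq <- advance_season(sq, pq)
  expect_identical(nq$counts_f, c(0L, 1L, 1L))
  expect_identical(nq$counts_b, c(0L, 2L, 0L))

  # max_age = 1: everyone is replaced every season
  p1 <- tpar(n_total = 6L, max_age = 1L, init_age_distribution = "all_youngest")
  set.seed(13)
  s1 <- initial_state(p1)
  n1 <- advance_season(s1, p1)
  expect_identical(n_f(n1) + n_b(n1), 6L)
  expect_identical(sum(n1$counts_f + n1$counts_b), 6L)
})

test_that("population size is conserved across random configurations", {
  set.seed(424242)
  for (rep in 1:60) {
    p <- random_params()
    s <- initial_state(p)
    for (t in 1:12) {
      s <- run_season(s, p)
      if (s$extinct) break
      expect_identical(n_f(s) + n_b(s), p$n_total)
      expect_length(s$counts_f, p$max_age)
    }
  }
})
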