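test_that("exact lottery distribution matches hand-computed closed forms", {
  # two competitors with fitness (1, 3): direct evaluation of the formula
  # P(i) = f_i / f_tot * (1 - exp(-f_tot)), P(none) = exp(-f_tot)
  # f_tot = 4: P1 = 0.25 * (1 - e^-4), P2 = 0.75 * (1 - e^-4)
  # An isolated individual with p and cost 0 has f = p * b / 9.
  pars <- sim_params(width = 7, height = 7, b = 9, cost = 0)
  w <- place_individuals(world_state(7, 7), rbind(c(3, 3), c(5, 5)),
                         p = c(1, 3))
  lot <- exact_lottery_distribution(w, pars, c(4, 4))
  expect_equal(lot$competitors$fitness, c(1, 3))
  expect_equal(lot$competitors$prob,
               c(0.25, 0.75) * (1 - exp(-4)), tolerance = 1e-12)
  expect_equal(lot$competitors$prob[1], 0.2454, tolerance = 1e-4)
  expect_equal(lot$competitors$prob[2], 0.7362, tolerance = 1e-4)
  expect_equal(lot$none, exp(-4))

  # zero competitors
  lot0 <- exact_lottery_distribution(world_state(5, 5), pars, c(2, 2))
  expect_equal(lot0$none, 1)
  expect_equal(nrow(lot0$competitors), 0)

  # one competitor with f = ln 2 -> {competitor: 1/2, none: 1/2}
  p2 <- sim_params(width = 5, height = 5, b = 9 * log(2), cost = 0)
  w1 <- place_individuals(world_state(5, 5), cbind(3, 3), p = 1)
  lot1 <- exact_lottery_distribution(w1, p2, c(3, 4))
  expect_equal(lot1$competitors$prob, 0.5)
  expect_equal(lot1$none, 0.5)
})

test_that("lottery probabilities sum to one for all competitor counts 0..8", {
  # build worlds with m occupied neighbours around an empty centre
  pars <- sim_params(width = 5, height = 5, b = 10, cost = 3)
  ring <- rbind(c(2, 2), c(2, 3), c(2, 4), c(3, 2), c(3, 4),
                c(4, 2), c(4, 3), c(4, 4))
  for (m in 0:8) {
    w <- world_state(5, 5)
    if (m > 0)
      w <- place_individuals(w, ring[seq_len(m), , drop = FALSE],
                             p = seq(0.5, 4, length.out = m))
    lot <- exact_lottery_distribution(w, pars, c(3, 3))
    expect_equal(sum(lot$competitors$prob) + lot$none, 1, tolerance = 1e-12)
  }
})

test_that("engine lottery frequencies match the exact distribution (chi-squared)", {
  pars <- sim_params(width = 5, height = 5, b = 10, cost = 3)
  w <- fixture_world("ring_3x3", p = 2)
  # heterogeneous competitor fitness: vary p around the ring
  sites <- which(w$occupancy == 1L, arr.ind = TRUE)
  w <- place_individuals(w, sites, p = seq(0.2, 3, length.out = 8))
  p3 <- params_3x3(b = 1.5, cost = 1)
  lot <- exact_lottery_distribution(w, p3, c(2, 2))
  expect_gt(lot$none, 1e-3)  # the "none" cell is testable

  rng <- rng_stream(77)
  n <- 200000L
  cnt <- goodwave:::cpp_lottery_counts(w$occupancy, w$production, p3,
                                       1L, 1L, n, rng$ptr)
  # align engine sites with oracle rows; the engine omits zero-fitness
  # competitors (they can never win the lottery)
  winnable <- lot$competitors$prob > 0
  expect_true(any(!winnable))  # the fixture exercises clamped fitness too
  lot$competitors <- lot$competitors[winnable, ]
  key_engine <- paste(cnt$sites %% 3 + 1, cnt$sites %/% 3 + 1)
  key_oracle <- paste(lot$competitors$row, lot$competitors$col)
  expect_setequal(key_engine, key_oracle)
  probs <- lot$competitors$prob[match(key_engine, key_oracle)]
  observed <- c(cnt$counts, cnt$none)
  expected <- c(probs, lot$none) * n
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1
  expect_lt(chi2, qchisq(1 - 1e-4, df))
})

test_that("markov oracle closed forms match engine event frequencies", {
  # isolated individual, movement off: dies with probability k_death
  pars <- sim_params(width = 5, height = 5, k_move = 0, k_death = 0.3,
                     b = 0)
  orc <- single_site_markov_oracle(pars, "isolated")
  expect_equal(orc$p_death, 0.3)
  expect_equal(orc$p_replicate_any, 0)  # b = 0 -> zero fitness

  rng <- rng_stream(13)
  deaths <- 0L
  n <- 3000L
  for (i in seq_len(n)) {
    w <- monte_carlo_step(orc$world, pars, rng)
    if (population_size(w) == 0L) deaths <- deaths + 1L
  }
  expect_binomial_3sigma(deaths, n, orc$p_death)

  # full 3x3, movement off: deaths in one step are Binomial(9, k_death)
  p3 <- params_3x3(k_move = 0, k_death = 0.2, b = 0)
  orc3 <- single_site_markov_oracle(p3, "full_3x3")
  expect_equal(orc3$expected_deaths, 1.8)
  tot_deaths <- 0L
  for (i in seq_len(n)) {
    w <- monte_carlo_step(orc3$world, p3, rng)
    tot_deaths <- tot_deaths + 9L - population_size(w)
  }
  expect_binomial_3sigma(tot_deaths, 9L * n, 0.2)

  # ring 3x3 with death and movement off: centre fills w.p. 1 - exp(-f_tot)
  pr <- params_3x3(k_move = 0, k_death = 0, mu = 0, b = 1, cost = 0.5)
  orc_r <- single_site_markov_oracle(pr, "ring_3x3", p = 0.1)
  f1 <- 0.1 * (8 * 1 / 9 - 0.5)  # each competitor: p (8b/9 - c) on the torus
  expect_equal(orc_r$f_tot, 8 * f1, tolerance = 1e-12)
  expect_equal(orc_r$p_fill, 1 - exp(-8 * f1), tolerance = 1e-12)
  fills <- 0L
  for (i in seq_len(n)) {
    w <- monte_carlo_step(orc_r$world, pr, rng)
    if (w$occupancy[2, 2] == 1L) fills <- fills + 1L
  }
  expect_binomial_3sigma(fills, n, orc_r$p_fill)

  # the oracle refuses configurations outside its catalogue
  expect_error(single_site_markov_oracle(sim_params(k_move = 0.1),
                                         "isolated"), "k_move")
  expect_error(single_site_markov_oracle(params_3x3(k_move = 0,
                                                    k_death = 0.2),
                                         "ring_3x3"), "k_death")
})
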