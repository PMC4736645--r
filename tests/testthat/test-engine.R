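test_that("Moore neighbourhood wraps on a torus and truncates under no-flux", {
  w4 <- world_state(4, 4)
  tor <- sim_params(width = 4, height = 4, boundary = "toroidal")
  nfx <- sim_params(width = 4, height = 4, boundary = "no_flux")

  corner <- neighbor_sites(w4, tor, c(1, 1))
  expect_equal(nrow(corner), 8)
  expect_equal(nrow(unique(corner)), 8)  # wrapped neighbours all distinct
  expect_true(all(corner >= 1 & corner <= 4))

  expect_equal(nrow(neighbor_sites(w4, nfx, c(1, 1))), 3)
  expect_equal(nrow(neighbor_sites(w4, nfx, c(2, 2))), 8)

  interior <- neighbor_sites(w4, tor, c(2, 2))
  expect_setequal(paste(interior[, 1], interior[, 2]),
                  paste(rep(1:3, times = 3), rep(1:3, each = 3))[-5])

  expect_error(neighbor_sites(w4, tor, c(0, 1)), "out of range")
  expect_error(neighbor_sites(w4, tor, c(1, 5)), "out of range")
})

test_that("benefit implements ninth-part sharing of the local public good", {
  pars <- params_3x3(b = 10, cost = 4)

  # homogeneous full neighbourhood: B = b * p
  full <- fixture_world("full_3x3", p = 6)
  expect_equal(benefit(full, pars, c(2, 2)), 60)

  # isolated producer keeps only its own share: B = b * p / 9
  pars5 <- sim_params(width = 5, height = 5, b = 10)
  iso <- fixture_world("isolated", p = 9)
  expect_equal(benefit(iso, pars5, c(3, 3)), 10)

  # non-producer with a single producing neighbour
  w <- place_individuals(world_state(5, 5), rbind(c(3, 3), c(3, 4)),
                         p = c(0, 9))
  expect_equal(benefit(w, pars5, c(3, 3)), 10)

  expect_error(benefit(world_state(5, 5), pars5, c(2, 2)), "empty")
})

test_that("strong altruism excludes the self share", {
  iso <- fixture_world("isolated", p = 9)
  strong <- sim_params(width = 5, height = 5, b = 10, altruism = "strong")
  expect_equal(benefit(iso, strong, c(3, 3)), 0)

  # neighbours' goods split /8 under the default sharing rule
  full <- fixture_world("full_3x3", p = 6)
  s3 <- params_3x3(b = 10, altruism = "strong")
  expect_equal(benefit(full, s3, c(2, 2)), 10 * 8 * 6 / 8)
  s3d <- params_3x3(b = 10, altruism = "strong",
                    strong_share = "discard_self")
  expect_equal(benefit(full, s3d, c(2, 2)), 10 * 8 * 6 / 9)
})

test_that("fitness is benefit minus cost, clamped at zero", {
  pars <- params_3x3(b = 10, cost = 4)
  full <- fixture_world("full_3x3", p = 6)
  expect_equal(fitness(full, pars, c(2, 2)), 60 - 24)

  pars5 <- sim_params(width = 5, height = 5, b = 10, cost = 4)
  iso <- fixture_world("isolated", p = 9)   # B = 10, C = 36 -> clamp
  expect_equal(fitness(iso, pars5, c(3, 3)), 0)

  # zero producer pays no cost: f = B >= 0
  w <- place_individuals(world_state(5, 5), rbind(c(3, 3), c(3, 4)),
                         p = c(0, 9))
  expect_equal(fitness(w, pars5, c(3, 3)), benefit(w, pars5, c(3, 3)))

  expect_error(fitness(world_state(5, 5), pars5, c(1, 1)), "empty")
})

test_that("select_replicator honours the lottery edge cases", {
  pars5 <- sim_params(width = 5, height = 5)
  rng <- rng_stream(11)

  # no occupied neighbours -> nobody replicates
  w <- fixture_world("isolated", p = 6)
  expect_null(select_replicator(w, pars5, c(1, 1), rng))

  # one competitor with f = ln 2 is chosen with probability 1/2
  pars <- sim_params(width = 5, height = 5, b = 9 * log(2), cost = 0)
  w1 <- place_individuals(world_state(5, 5), cbind(3, 3), p = 1)
  expect_equal(fitness(w1, pars, c(3, 3)), log(2))
  hits <- 0L
  n <- 20000L
  for (i in seq_len(n)) {
    if (!is.null(select_replicator(w1, pars, c(3, 4), rng))) hits <- hits + 1L
  }
  expect_binomial_3sigma(hits, n, 0.5)

  expect_error(select_replicator(w1, pars, c(3, 3), rng), "occupied")
})

test_that("mutate_production mutates with probability mu and clips to [0, p_max]", {
  pars <- sim_params()
  always <- update_params(pars, mu = 1, delta = 0.1)
  never <- update_params(pars, mu = 0)
  rng <- rng_stream(5)

  expect_equal(mutate_production(c(5, 0, 10), never, rng), c(5, 0, 10))

  out <- mutate_production(rep(5, 5000), always, rng)
  expect_true(all(abs(out - 5) <= 0.05))
  expect_gt(sd(out), 0)  # draws actually vary

  # clipping at both bounds with a wide mutation kernel
  wide <- update_params(pars, mu = 1, delta = 50)
  lo <- mutate_production(rep(0.02, 2000), wide, rng)
  hi <- mutate_production(rep(9.99, 2000), wide, rng)
  expect_true(all(lo >= 0 & lo <= 10))
  expect_true(all(hi >= 0 & hi <= 10))
  expect_true(any(lo == 0))    # atom at the lower clip
  expect_true(any(hi == 10))   # atom at the cap

  # mutation frequency matches mu
  half <- update_params(pars, mu = 0.3, delta = 0.1)
  out <- mutate_production(rep(5, 10000), half, rng)
  expect_binomial_3sigma(sum(out != 5), 10000, 0.3)
})

test_that("apply_move swaps content, conserves the population, and absorbs at no-flux edges", {
  pars5 <- sim_params(width = 5, height = 5, k_move = 0)
  w <- fixture_world("isolated", p = 6)
  rng <- rng_stream(3)

  # k_move = 0: nothing happens
  out <- apply_move(w, pars5, c(3, 3), rng)
  expect_identical(out$occupancy, w$occupancy)
  expect_false(attr(out, "moved"))

  # forced move on a torus: relocated, count conserved
  pars1 <- update_params(pars5, k_move = 1)
  for (i in 1:50) {
    out <- apply_move(w, pars1, c(3, 3), rng)
    expect_equal(population_size(out), 1)
    expect_true(attr(out, "moved"))
  }

  # forced move from beside the absorbing ring eventually removes
  nfx <- sim_params(width = 5, height = 5, k_move = 1, boundary = "no_flux")
  wn <- place_individuals(world_state(5, 5), cbind(2, 2), p = 6)
  removed <- 0L
  for (i in 1:200) {
    out <- apply_move(wn, nfx, c(2, 2), rng)
    expect_true(population_size(out) %in% c(0L, 1L))
    if (attr(out, "removed")) removed <- removed + 1L
  }
  # 5 of 8 targets of (2,2) lie on the ring
  expect_binomial_3sigma(removed, 200, 5 / 8)

  expect_error(apply_move(world_state(5, 5), pars5, c(3, 3), rng), "empty")
})

test_that("apply_death empties the node with probability k_death", {
  w <- fixture_world("isolated", p = 6)
  rng <- rng_stream(9)
  certain <- sim_params(width = 5, height = 5, k_death = 1)
  never <- sim_params(width = 5, height = 5, k_death = 0)

  expect_equal(population_size(apply_death(w, certain, c(3, 3), rng)), 0)
  expect_equal(population_size(apply_death(w, never, c(3, 3), rng)), 1)

  some <- sim_params(width = 5, height = 5, k_death = 0.2)
  deaths <- 0L
  n <- 5000L
  for (i in seq_len(n)) {
    out <- apply_death(w, some, c(3, 3), rng)
    if (attr(out, "died")) deaths <- deaths + 1L
  }
  expect_binomial_3sigma(deaths, n, 0.2)
})

test_that("monte_carlo_step preserves the state invariants", {
  pars <- sim_params(width = 8, height = 8, cost = 2)
  rng <- rng_stream(21)

  # all-empty lattice stays empty
  empty <- world_state(8, 8)
  out <- monte_carlo_step(empty, pars, rng)
  expect_equal(population_size(out), 0)
  expect_equal(out$t, 1L)

  # production stays within [0, p_max]; occupancy is 0/1
  w <- random_world(8, 8, density = 0.7, seed = 2)
  for (i in 1:30) {
    w <- monte_carlo_step(w, pars, rng)
    expect_true(all(w$occupancy %in% c(0L, 1L)))
    pv <- production_values(w)
    expect_true(all(pv >= 0 & pv <= pars$p_max))
  }
  expect_equal(w$t, 30L)
})

test_that("an isolated zero-fitness individual never replicates and dies at rate k_death", {
  # b = 0 makes every fitness zero; k_move = 0 keeps it in place
  pars <- sim_params(width = 5, height = 5, b = 0, k_move = 0, k_death = 0.2)
  rng <- rng_stream(33)
  survived <- 0L
  n <- 3000L
  for (i in seq_len(n)) {
    w <- monte_carlo_step(fixture_world("isolated", p = 6), pars, rng)
    np <- population_size(w)
    expect_lte(np, 1L)
    if (np == 1L) survived <- survived + 1L
  }
  expect_binomial_3sigma(survived, n, 0.8)
})

test_that("run_simulation records trajectories, flags extinction, and is seed-deterministic", {
  pars <- sim_params(width = 12, height = 12, cost = 1)
  w <- seed_world(world_state(12, 12), 1, pars$p_max, rng_stream(1))

  # n_steps = 0: single record of the initial state
  res0 <- run_simulation(w, pars, 0, rng_stream(1))
  expect_equal(nrow(res0$trajectory), 1)
  expect_equal(res0$trajectory$population_size, 144)
  expect_equal(res0$trajectory$mean_p, 10)

  # certain death, no movement escape, no possible births -> extinction
  # after exactly one step
  doom <- sim_params(width = 12, height = 12, b = 0, k_death = 1,
                     k_move = 0)
  resd <- run_simulation(w, doom, 5, rng_stream(1))
  expect_true(resd$extinct)
  expect_equal(resd$extinction_step, 1L)
  expect_equal(extinction_time(resd), 1L)

  # identical seed => bit-identical trajectories and final state
  r1 <- run_simulation(w, pars, 40, rng_stream(99), sample_every = 10)
  r2 <- run_simulation(w, pars, 40, rng_stream(99), sample_every = 10)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$world, r2$world)
  r3 <- run_simulation(w, pars, 40, rng_stream(100), sample_every = 10)
  expect_false(identical(r1$trajectory, r3$trajectory))
})

test_that("population changes only through births and deaths", {
  # no deaths and no births possible (b = 0): movement alone conserves count
  pars <- sim_params(width = 10, height = 10, b = 0, k_death = 0,
                     k_move = 0.5)
  w <- random_world(10, 10, density = 0.5, seed = 4)
  n0 <- population_size(w)
  rng <- rng_stream(8)
  for (i in 1:20) {
    w <- monte_carlo_step(w, pars, rng)
    expect_equal(population_size(w), n0)
  }
  # the multiset of production values is untouched by movement
  expect_equal(sort(production_values(w)),
               sort(production_values(random_world(10, 10, density = 0.5,
                                                   seed = 4))))
})
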